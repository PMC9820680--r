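test_that("ortholog mapping keeps only one-to-one pairs and accounts for the rest", {
  map <- tibble::tibble(
    study_gene_id = c("a", "b", "c"),
    reference_gene_id = c("a", "b", "c")
  )
  res <- map_orthologs(c("a", "b", "c"), map)
  expect_equal(nrow(res$pairs), 3)
  expect_length(res$unmapped, 0)
  expect_length(res$ambiguous, 0)

  res2 <- map_orthologs(c("a", "d"), map)
  expect_equal(res2$unmapped, "d")

  # two study ids -> one reference id: both dropped
  fork <- tibble::tibble(
    study_gene_id = c("x", "y", "z"),
    reference_gene_id = c("M", "M", "Z")
  )
  res3 <- map_orthologs(c("x", "y", "z"), fork)
  expect_equal(res3$ambiguous, c("x", "y"))
  expect_equal(res3$pairs$study_gene_id, "z")

  # one study id -> two reference ids: dropped too
  split <- tibble::tibble(
    study_gene_id = c("x", "x"),
    reference_gene_id = c("M", "N")
  )
  expect_equal(map_orthologs("x", split)$ambiguous, "x")
})

test_that("the Venn partition matches exhaustive hand enumeration", {
  v <- classify_venn(
    study_expressed = c("a", "b", "c", "d"),
    study_significant = c("a", "b"),
    ref_expressed = c("b", "c", "e"),
    ref_significant = c("b", "c")
  )
  expect_equal(v$genes$both_expr_sig_both, "b")
  expect_equal(v$genes$both_expr_sig_ref_only, "c")
  expect_equal(v$genes$both_expr_sig_study_only, character(0))
  expect_equal(v$genes$study_only_sig, "a")
  expect_equal(v$genes$study_only_nonsig, "d")
  expect_equal(v$genes$ref_only_nonsig, "e")
  expect_equal(sum(v$regions$n), 5)
  expect_equal(carried_genes(v), "b")

  empty <- classify_venn(character(0), character(0), character(0), character(0))
  expect_equal(sum(empty$regions$n), 0)

  expect_error(
    classify_venn("a", "b", character(0), character(0)),
    "not in the expressed set.*b"
  )
})

test_that("Venn regions form a partition agreeing with a per-gene classifier", {
  set.seed(61)
  pool <- sprintf("g%02d", 1:40)
  for (i in 1:15) {
    se <- sample(pool, sample(0:30, 1))
    re <- sample(pool, sample(0:30, 1))
    ss <- sample(se, min(length(se), sample(0:10, 1)))
    rs <- sample(re, min(length(re), sample(0:10, 1)))
    v <- classify_venn(se, ss, re, rs)
    universe <- union(se, re)
    # disjoint and exhaustive
    all_assigned <- unlist(v$genes, use.names = FALSE)
    expect_equal(sort(all_assigned), sort(universe))
    expect_equal(anyDuplicated(all_assigned), 0)
    # every gene lands where the brute-force classifier puts it
    for (g in universe) {
      expect_true(g %in% v$genes[[oracle_venn_region(g, se, ss, re, rs)]])
    }
  }
})

test_that("Venn bookkeeping recovers the carried-forward count", {
  expect_equal(count_sig_in_both(4914, 2870, 1400), 644L)
  expect_equal(count_sig_in_both(10, 0, 0), 10L)
  expect_error(count_sig_in_both(10, 8, 5), "inconsistent")
})

test_that("unique-marker extraction applies the single-population rule", {
  ref <- validate_marker_reference(tibble::tibble(
    gene_id = c("u", "m", "m", "n"),
    population = c("anagen_hf", "anagen_hf", "permanent_epidermis", "immune"),
    subpopulation = "",
    significant = c(TRUE, TRUE, TRUE, FALSE)
  ))
  ms <- extract_unique_markers(c("u", "m", "n"), ref)
  expect_equal(ms$gene_id, "u")
  expect_equal(ms$population, "anagen_hf")
  expect_equal(attr(ms, "n_excluded_multi"), 1)

  expect_error(extract_unique_markers("ghost", ref), "absent.*ghost")
})

test_that("no marker is ever assigned to two populations", {
  set.seed(71)
  pops <- c("p1", "p2", "p3")
  for (i in 1:10) {
    rows <- tibble::tibble(
      gene_id = sample(sprintf("g%d", 1:15), 25, replace = TRUE),
      population = sample(pops, 25, replace = TRUE),
      significant = sample(c(TRUE, FALSE), 25, replace = TRUE)
    )
    rows <- rows[!duplicated(rows[, c("gene_id", "population")]), ]
    rows$subpopulation <- ""
    ref <- validate_marker_reference(rows, populations = pops)
    ms <- extract_unique_markers(unique(rows$gene_id), ref)
    expect_equal(anyDuplicated(ms$gene_id), 0)
    # brute-force uniqueness check
    for (g in ms$gene_id) {
      sig_pops <- unique(rows$population[rows$gene_id == g & rows$significant])
      expect_length(sig_pops, 1)
    }
  }
})

test_that("enrichment calls reproduce the majority rule and its edge cases", {
  counts_per_pop <- c(anagen_hf = 9, permanent_epidermis = 5, neural_crest = 5)
  ref <- reference_with_counts(counts_per_pop)
  ms <- extract_unique_markers(ref$gene_id, ref)
  wanted <- list(
    anagen_hf = c(rep("plucked_higher", 8), "biopsy_higher"),          # 8/9
    permanent_epidermis = rep("biopsy_higher", 5),                     # 5/5
    neural_crest = c(rep("biopsy_higher", 3), rep("plucked_higher", 2)) # 3/5
  )
  genes <- unlist(lapply(names(wanted), function(p) ms$gene_id[ms$population == p]))
  de <- de_table_with(genes, unlist(wanted, use.names = FALSE))
  calls <- call_enrichment(ms, de)
  get <- function(p) calls[calls$population == p, ]
  expect_equal(get("anagen_hf")$call, "plucked_enriched")
  expect_equal(get("anagen_hf")$concordance, 8 / 9)
  expect_equal(get("permanent_epidermis")$call, "biopsy_enriched")
  expect_equal(get("permanent_epidermis")$concordance, 1)
  expect_equal(get("neural_crest")$call, "inconclusive")
  expect_equal(get("neural_crest")$concordance, 3 / 5)

  # a population with no markers is reported as no_call
  calls_all <- call_enrichment(ms, de, populations = c(names(counts_per_pop), "immune"))
  expect_equal(calls_all$call[calls_all$population == "immune"], "no_call")
  expect_equal(calls_all$n_markers[calls_all$population == "immune"], 0)

  # a marker missing from the DE table is an error naming the gene
  expect_error(call_enrichment(ms, de[-1, ]), "missing from the DE results")
  # a marker without a direction is a precondition failure
  de_bad <- de
  de_bad$direction[1] <- "none"
  expect_error(call_enrichment(ms, de_bad), "without a significant DE direction")
})

test_that("enrichment calls are order-invariant and flip under relabelling", {
  ref <- reference_with_counts(c(a_pop = 4, b_pop = 6))
  ms <- extract_unique_markers(ref$gene_id, ref)
  set.seed(3)
  dirs <- sample(c("biopsy_higher", "plucked_higher"), nrow(ms), replace = TRUE)
  de <- de_table_with(ms$gene_id, dirs)
  base <- call_enrichment(ms, de)

  perm <- sample(nrow(ms))
  shuffled <- call_enrichment(ms[perm, ], de[sample(nrow(de)), ])
  expect_equal(
    shuffled[order(shuffled$population), ],
    base[order(base$population), ]
  )

  flip <- c(biopsy_higher = "plucked_higher", plucked_higher = "biopsy_higher")
  de_flip <- de_table_with(ms$gene_id, unname(flip[dirs]))
  flipped <- call_enrichment(ms, de_flip)
  expect_equal(flipped$n_biopsy_higher, base$n_plucked_higher)
  expect_equal(flipped$concordance, base$concordance)
  swap <- c(
    biopsy_enriched = "plucked_enriched", plucked_enriched = "biopsy_enriched",
    inconclusive = "inconclusive", no_call = "no_call"
  )
  expect_equal(flipped$call, unname(swap[base$call]))
})

test_that("subpopulation refinement partitions markers and flags weak majorities", {
  ref <- validate_marker_reference(tibble::tibble(
    gene_id = c("CNP", "MPZ", "ATP6V1G1", "NPY", "PMEL"),
    population = "neural_crest",
    subpopulation = c("schwann", "schwann", "melanocyte", "melanocyte", "melanocyte"),
    significant = TRUE
  ))
  ms <- extract_unique_markers(ref$gene_id, ref)
  de <- de_table_with(
    c("CNP", "MPZ", "ATP6V1G1", "NPY", "PMEL"),
    c("biopsy_higher", "biopsy_higher",
      "plucked_higher", "plucked_higher", "biopsy_higher")
  )
  sub <- refine_subpopulations("neural_crest", ms, ref, de)
  schwann <- sub[sub$subpopulation == "schwann", ]
  melano <- sub[sub$subpopulation == "melanocyte", ]
  expect_equal(schwann$call, "biopsy_enriched")
  expect_equal(schwann$concordance, 1)
  expect_false(schwann$predominant)
  # 2 of 3: the majority call is kept but flagged as predominant (< 0.75)
  expect_equal(melano$call, "plucked_enriched")
  expect_true(melano$predominant)
  expect_equal(melano$concordance, 2 / 3, tolerance = 1e-12)
  # subpopulation tallies sum to the parent tally when fully annotated
  expect_equal(sum(sub$n_markers), nrow(ms))

  # single-marker subpopulation follows its marker with concordance 1
  solo_ref <- validate_marker_reference(tibble::tibble(
    gene_id = "CNP", population = "neural_crest",
    subpopulation = "schwann", significant = TRUE
  ))
  solo_ms <- extract_unique_markers("CNP", solo_ref)
  solo <- refine_subpopulations("neural_crest", solo_ms, solo_ref,
                                de_table_with("CNP", "plucked_higher"))
  expect_equal(solo$call, "plucked_enriched")
  expect_equal(solo$concordance, 1)

  # markers without annotation land in an explicit unassigned bucket
  part_ref <- validate_marker_reference(tibble::tibble(
    gene_id = c("CNP", "X1"), population = "neural_crest",
    subpopulation = c("schwann", ""), significant = TRUE
  ))
  part_ms <- extract_unique_markers(c("CNP", "X1"), part_ref)
  part <- refine_subpopulations(
    "neural_crest", part_ms, part_ref,
    de_table_with(c("CNP", "X1"), rep("biopsy_higher", 2))
  )
  expect_setequal(part$subpopulation, c("schwann", "unassigned"))

  expect_error(
    refine_subpopulations("immune", ms, ref, de),
    "no subpopulation annotation"
  )
})

test_that("a minimal projection runs end to end", {
  ref <- validate_marker_reference(tibble::tibble(
    gene_id = "KRT84", population = "anagen_hf", subpopulation = "", significant = TRUE
  ))
  de <- de_table_with(c("KRT84", "OTHER"), c("plucked_higher", "none"))
  map <- tibble::tibble(
    study_gene_id = c("KRT84", "OTHER"),
    reference_gene_id = c("KRT84", "OTHER")
  )
  proj <- project_markers(de, map, ref,
                          ref_expressed = c("KRT84", "OTHER"),
                          ref_significant = "KRT84")
  calls <- tidy(proj)
  expect_equal(calls$call[calls$population == "anagen_hf"], "plucked_enriched")
  expect_equal(nrow(proj$markers), 1)
  expect_equal(glance(proj)$n_conclusive, 1)

  # with nothing significant in the study, every population is no_call
  de_null <- de_table_with(c("KRT84", "OTHER"), c("none", "none"))
  proj_null <- project_markers(de_null, map, ref,
                               ref_expressed = c("KRT84", "OTHER"),
                               ref_significant = "KRT84")
  expect_true(all(tidy(proj_null)$call == "no_call"))
})
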