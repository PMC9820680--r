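test_that("generators are bit-reproducible and validate their configuration", {
  cfg <- simulation_config(n_genes = 400, seed = 9)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$reference, b$reference)
  expect_identical(a$orthologs, b$orthologs)
  expect_identical(a$truth$markers, b$truth$markers)

  expect_error(simulation_config(n_genes = 50, markers_per_population = 10),
               "exceeds n_genes")
  bad_comp <- default_compositions()
  bad_comp[1, 1] <- bad_comp[1, 1] + 0.01
  expect_error(simulation_config(compositions = bad_comp), "sum to 1")
  expect_error(simulation_config(marker_fold = 0), "positive")
})

test_that("marker fold shapes the profiles as specified", {
  cfg1 <- simulation_config(n_genes = 300, marker_fold = 1, seed = 5)
  p1 <- generate_profiles(cfg1)
  expect_true(all(p1$profiles == p1$profiles[, 1])) # null effect: identical columns

  cfg8 <- simulation_config(n_genes = 3000, marker_fold = 8, seed = 5)
  p8 <- generate_profiles(cfg8)
  m <- p8$truth$markers
  own <- p8$profiles[cbind(m$gene_id, m$component)]
  other <- vapply(seq_len(nrow(m)), function(i) {
    cols <- setdiff(colnames(p8$profiles), m$component[i])
    mean(p8$profiles[m$gene_id[i], cols])
  }, numeric(1))
  expect_equal(mean(own / other), 8, tolerance = 1e-6)
})

test_that("default design matches the study: 7 + 7 samples over two sites", {
  sheet <- simulation_config()$samples
  expect_equal(nrow(sheet), 14)
  expect_equal(as.integer(table(sheet$source)), c(7L, 7L))
  expect_equal(sum(sheet$site == "forelock" & sheet$source == "biopsy"), 4)
  expect_equal(sum(sheet$site == "mane" & sheet$source == "biopsy"), 3)
})

test_that("one-hot compositions collapse the mixture onto one profile", {
  comps <- default_components()
  one_hot <- matrix(0, nrow(comps), 2,
                    dimnames = list(comps$component, c("plucked", "biopsy")))
  one_hot["anagen_hf", ] <- 1
  cfg <- simulation_config(n_genes = 500, compositions = one_hot,
                           dispersion = 0, seed = 21,
                           library_size_range = c(2e6, 2e6))
  prof <- generate_profiles(cfg)
  bulk <- generate_bulk_counts(prof, cfg)
  expected <- prof$profiles[, "anagen_hf"] / sum(prof$profiles[, "anagen_hf"]) * 2e6
  observed <- rowMeans(bulk$counts$counts)
  # Poisson draws around the one-hot mixture mean: compare where counts are high
  hi <- expected > 200
  expect_equal(unname(observed[hi] / expected[hi]), rep(1, sum(hi)),
               tolerance = 0.1)
})

test_that("dispersion zero gives Poisson mean-variance behaviour", {
  reps <- tibble::tibble(
    sample_id = sprintf("p%d", 1:40),
    source = rep(c("plucked", "biopsy"), each = 20),
    site = "forelock",
    subject_id = sprintf("h%d", 1:40)
  )
  comp_equal <- default_compositions()
  comp_equal[, "biopsy"] <- comp_equal[, "plucked"]
  cfg <- simulation_config(
    n_genes = 400, dispersion = 0, samples = reps,
    compositions = comp_equal, library_size_range = c(5e5, 5e5), seed = 33
  )
  bulk <- generate_bulk_counts(generate_profiles(cfg), cfg)
  m <- rowMeans(bulk$counts$counts)
  v <- apply(bulk$counts$counts, 1, var)
  keep <- m > 20
  ratio <- v[keep] / m[keep]
  # var/mean ratios concentrate around 1; their average is within 3 SE
  se <- sqrt(2 / (ncol(bulk$counts$counts) - 1)) / sqrt(sum(keep))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("reference tables mirror the truth under clean settings", {
  cfg <- simulation_config(
    n_genes = 600, seed = 13,
    fraction_multi_population_markers = 0,
    fraction_unmapped_orthologs = 0
  )
  prof <- generate_profiles(cfg)
  tabs <- generate_reference_tables(prof$truth, cfg)
  expect_setequal(tabs$reference$gene_id, prof$truth$markers$gene_id)
  expect_equal(nrow(tabs$orthologs), 600)
  expect_identical(tabs$orthologs$study_gene_id, tabs$orthologs$reference_gene_id)
  expect_setequal(tabs$ref_significant, prof$truth$markers$gene_id)
})

test_that("multi-population reference genes are exactly the ones excluded", {
  cfg <- simulation_config(n_genes = 500, seed = 29,
                           fraction_multi_population_markers = 0.2,
                           fraction_unmapped_orthologs = 0)
  prof <- generate_profiles(cfg)
  tabs <- generate_reference_tables(prof$truth, cfg)
  multi_genes <- setdiff(tabs$ref_significant, prof$truth$markers$gene_id)
  expect_equal(length(multi_genes), 100)
  ms <- extract_unique_markers(tabs$ref_significant, tabs$reference)
  expect_setequal(ms$gene_id, prof$truth$markers$gene_id)
  expect_equal(attr(ms, "n_excluded_multi"), length(multi_genes))
})

test_that("a fully unmapped ortholog table produces only no_call populations", {
  cfg <- simulation_config(n_genes = 400, seed = 37,
                           fraction_unmapped_orthologs = 1)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$orthologs), 0)
  norm <- tmm_normalize(sim$counts)
  de <- run_contrast(norm$counts, sim$sheet, factors = norm$factors)
  proj <- project_markers(de, sim$orthologs, sim$reference,
                          ref_expressed = sim$ref_expressed,
                          ref_significant = sim$ref_significant)
  expect_true(all(tidy(proj)$call == "no_call"))
})

test_that("simulation truth encodes the expected enrichment pattern", {
  truth <- generate_profiles(simulation_config(n_genes = 300, seed = 3))$truth
  calls <- truth$population_calls
  expect_equal(calls$expected_call[calls$population == "anagen_hf"], "plucked_enriched")
  expect_equal(calls$expected_call[calls$population == "neural_crest"], "inconclusive")
  biopsy_side <- c("permanent_epidermis", "fibroblast", "vascular", "immune", "miscellaneous")
  expect_true(all(calls$expected_call[calls$population %in% biopsy_side] == "biopsy_enriched"))
  sub <- truth$subpopulation_calls
  expect_equal(sub$expected_call[sub$subpopulation == "schwann"], "biopsy_enriched")
  expect_equal(sub$expected_call[sub$subpopulation == "melanocyte"], "plucked_enriched")
})
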