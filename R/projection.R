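venn_region_names <- c(
  "study_only_nonsig", "ref_only_nonsig", "both_nonsig",
  "study_only_sig", "ref_only_sig",
  "both_expr_sig_study_only", "both_expr_sig_ref_only", "both_expr_sig_both"
)

#' Map study genes onto the reference namespace
#'
#' Restricts an ortholog map to the study genes of interest and keeps only
#' the correspondences that are one-to-one in both directions within that
#' restriction; genes involved in many-to-one or one-to-many relations are
#' dropped and reported rather than silently resolved.
#'
#' @param study_genes Character vector of study-species gene ids.
#' @param map Ortholog map tibble (`study_gene_id`, `reference_gene_id`), as
#'   from [read_ortholog_map()].
#' @return A list with `pairs` (tibble of retained one-to-one pairs),
#'   `unmapped` (study ids with no map row), and `ambiguous` (study ids
#'   dropped by the one-to-one rule).
#' @export
map_orthologs <- function(study_genes, map) {
  study_genes <- unique(study_genes)
  hit <- map[map$study_gene_id %in% study_genes, c("study_gene_id", "reference_gene_id")]
  hit <- dplyr::distinct(hit)
  multi_study <- unique(hit$study_gene_id[duplicated(hit$study_gene_id)])
  multi_ref <- unique(hit$reference_gene_id[duplicated(hit$reference_gene_id)])
  ambiguous_rows <- hit$study_gene_id %in% multi_study |
    hit$reference_gene_id %in% multi_ref
  pairs <- hit[!ambiguous_rows, ]
  list(
    pairs = as_tibble(pairs),
    unmapped = setdiff(study_genes, hit$study_gene_id),
    ambiguous = sort(unique(hit$study_gene_id[ambiguous_rows]))
  )
}

#' Partition genes by expression and significance across two datasets
#'
#' Classifies every gene of the universe (union of study-mapped and reference
#' genes, all in the reference namespace) into exactly one of eight regions
#' according to where it is expressed and where it is statistically
#' significant. The genes carried forward to marker extraction are those of
#' the `both_expr_sig_both` region: expressed and significant in both the
#' study and the reference dataset.
#'
#' @param study_expressed,study_significant Study gene sets (reference
#'   namespace after ortholog mapping); `study_significant` must be a subset
#'   of `study_expressed`.
#' @param ref_expressed,ref_significant Reference gene sets;
#'   `ref_significant` must be a subset of `ref_expressed`.
#' @return A `venn_partition` object: list with `regions` (tibble of region
#'   counts) and `genes` (named list of per-region gene vectors).
#' @export
classify_venn <- function(study_expressed, study_significant,
                          ref_expressed, ref_significant) {
  study_expressed <- unique(study_expressed)
  study_significant <- unique(study_significant)
  ref_expressed <- unique(ref_expressed)
  ref_significant <- unique(ref_significant)
  bad <- setdiff(study_significant, study_expressed)
  if (length(bad)) {
    abort(paste0(
      "Significant study gene(s) not in the expressed set: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  bad <- setdiff(ref_significant, ref_expressed)
  if (length(bad)) {
    abort(paste0(
      "Significant reference gene(s) not in the expressed set: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  universe <- union(study_expressed, ref_expressed)
  se <- universe %in% study_expressed
  re <- universe %in% ref_expressed
  ss <- universe %in% study_significant
  rs <- universe %in% ref_significant
  region <- character(length(universe))
  region[se & !re] <- ifelse(ss[se & !re], "study_only_sig", "study_only_nonsig")
  region[!se & re] <- ifelse(rs[!se & re], "ref_only_sig", "ref_only_nonsig")
  both <- se & re
  region[both & ss & rs] <- "both_expr_sig_both"
  region[both & ss & !rs] <- "both_expr_sig_study_only"
  region[both & !ss & rs] <- "both_expr_sig_ref_only"
  region[both & !ss & !rs] <- "both_nonsig"
  genes <- lapply(venn_region_names, function(r) sort(universe[region == r]))
  names(genes) <- venn_region_names
  structure(
    list(
      regions = tibble(
        region = venn_region_names,
        n = vapply(genes, length, integer(1))
      ),
      genes = genes
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  print(x$regions)
  invisible(x)
}

#' @rdname classify_venn
#' @param x A `venn_partition`.
#' @export
carried_genes <- function(x) x$genes$both_expr_sig_both

#' Venn bookkeeping: significant-in-both from printed region counts
#'
#' Among the genes expressed in both datasets and significant in at least one
#' of them, subtracting those significant only in the study and those
#' significant only in the reference leaves the genes significant in both —
#' the set carried into marker extraction.
#'
#' @param n_both_expressed_sig_any Genes expressed in both datasets and
#'   significant in at least one.
#' @param n_sig_study_only Of those, significant in the study only.
#' @param n_sig_ref_only Of those, significant in the reference only.
#' @return Integer count of genes significant in both datasets.
#' @export
#' @examples
#' count_sig_in_both(4914, 2870, 1400)
count_sig_in_both <- function(n_both_expressed_sig_any, n_sig_study_only, n_sig_ref_only) {
  stopifnot(
    n_both_expressed_sig_any >= 0, n_sig_study_only >= 0, n_sig_ref_only >= 0
  )
  n <- n_both_expressed_sig_any - n_sig_study_only - n_sig_ref_only
  if (n < 0) abort("Region counts are inconsistent: excluded genes exceed the candidate set.")
  as.integer(n)
}

#' Extract population-unique markers
#'
#' A carried gene becomes a cell marker of population P if and only if its
#' significant reference entries name exactly one population, P. Genes
#' significantly expressed in two or more populations are excluded (and
#' counted); genes with no significant entry contribute nothing.
#'
#' @param carried Genes carried forward from the Venn partition (reference
#'   namespace); must all be present in the reference table.
#' @param reference Validated marker reference tibble.
#' @return A `marker_set`: tibble (`gene_id`, `population`) with attributes
#'   `n_excluded_multi` (genes dropped for multi-population significance) and
#'   `populations` (the reference's declared population set).
#' @export
extract_unique_markers <- function(carried, reference) {
  carried <- unique(carried)
  outside <- setdiff(carried, reference$gene_id)
  if (length(outside)) {
    abort(paste0(
      "Carried gene(s) absent from the marker reference: ",
      paste(head(outside, 5), collapse = ", ")
    ))
  }
  sig <- reference[reference$significant & reference$gene_id %in% carried, ]
  per_gene <- dplyr::summarise(
    dplyr::group_by(sig, .data$gene_id),
    n_pop = dplyr::n_distinct(.data$population),
    population = .data$population[1],
    .groups = "drop"
  )
  markers <- per_gene[per_gene$n_pop == 1, c("gene_id", "population")]
  markers <- dplyr::arrange(markers, .data$population, .data$gene_id)
  structure(
    as_tibble(markers),
    n_excluded_multi = sum(per_gene$n_pop > 1),
    populations = attr(reference, "populations") %||% sort(unique(reference$population)),
    class = c("marker_set", class(markers))
  )
}

direction_call <- function(n_biopsy, n_plucked, threshold) {
  n <- n_biopsy + n_plucked
  if (n == 0) return("no_call")
  if (n_biopsy / n >= threshold) return("biopsy_enriched")
  if (n_plucked / n >= threshold) return("plucked_enriched")
  "inconclusive"
}

tally_markers <- function(genes, de_table) {
  missing_genes <- setdiff(genes, de_table$gene_id)
  if (length(missing_genes)) {
    abort(paste0(
      "Marker gene(s) missing from the DE results: ",
      paste(head(missing_genes, 5), collapse = ", ")
    ))
  }
  dirs <- de_table$direction[match(genes, de_table$gene_id)]
  undirected <- genes[dirs == "none"]
  if (length(undirected)) {
    abort(paste0(
      "Marker gene(s) without a significant DE direction: ",
      paste(head(undirected, 5), collapse = ", ")
    ))
  }
  c(biopsy = sum(dirs == "biopsy_higher"), plucked = sum(dirs == "plucked_higher"))
}

#' Call per-population enrichment from marker directions
#'
#' For each population, tallies how many of its markers have higher abundance
#' in each source and calls the population `biopsy_enriched` or
#' `plucked_enriched` when the majority fraction (concordance) reaches
#' `conclusive_threshold`, `inconclusive` otherwise, and `no_call` when the
#' population has no markers.
#'
#' @param markers A `marker_set` from [extract_unique_markers()].
#' @param de A `de_result` or its tidied per-gene table, keyed by the same
#'   gene namespace as `markers`.
#' @param conclusive_threshold Majority fraction needed for a conclusive call
#'   (default 0.75).
#' @param populations Populations to report; defaults to the marker set's
#'   declared population vocabulary so that marker-free populations appear as
#'   `no_call` rows.
#' @return Tibble with columns `population`, `n_markers`, `n_biopsy_higher`,
#'   `n_plucked_higher`, `concordance`, `call`.
#' @export
call_enrichment <- function(markers, de, conclusive_threshold = 0.75,
                            populations = NULL) {
  de_table <- if (inherits(de, "de_result")) de$table else as_tibble(de)
  populations <- populations %||% attr(markers, "populations") %||%
    sort(unique(markers$population))
  rows <- lapply(populations, function(pop) {
    genes <- markers$gene_id[markers$population == pop]
    tal <- if (length(genes)) tally_markers(genes, de_table) else c(biopsy = 0L, plucked = 0L)
    n <- length(genes)
    tibble(
      population = pop,
      n_markers = n,
      n_biopsy_higher = unname(tal["biopsy"]),
      n_plucked_higher = unname(tal["plucked"]),
      concordance = if (n > 0) max(tal) / n else NA_real_,
      call = direction_call(tal["biopsy"], tal["plucked"], conclusive_threshold)
    )
  })
  dplyr::bind_rows(rows)
}

#' Refine a population's call by subpopulation
#'
#' Partitions one population's markers by the subpopulation annotation of the
#' reference and re-applies the direction tally per subpopulation with a
#' simple majority: the call follows the majority direction, and a majority
#' below `conclusive_threshold` keeps the call but sets the `predominant`
#' flag (the population is "predominantly" rather than conclusively
#' enriched). Markers without a subpopulation annotation are reported under
#' an `"unassigned"` bucket.
#'
#' @param population The parent population to refine; must have at least one
#'   subpopulation in the reference.
#' @param markers A `marker_set`.
#' @param reference Validated marker reference.
#' @param de A `de_result` or tidy DE table.
#' @param conclusive_threshold Majority fraction below which the
#'   `predominant` flag is set (default 0.75).
#' @return Tibble with columns `population`, `subpopulation`, `n_markers`,
#'   `n_biopsy_higher`, `n_plucked_higher`, `concordance`, `call`,
#'   `predominant`.
#' @export
refine_subpopulations <- function(population, markers, reference, de,
                                  conclusive_threshold = 0.75) {
  de_table <- if (inherits(de, "de_result")) de$table else as_tibble(de)
  pop_rows <- reference[reference$population == population & reference$significant, ]
  if (!any(pop_rows$subpopulation != "")) {
    abort(sprintf("Population '%s' has no subpopulation annotation.", population))
  }
  genes <- markers$gene_id[markers$population == population]
  sub_of <- setNames(pop_rows$subpopulation, pop_rows$gene_id)[genes]
  sub_of[is.na(sub_of) | sub_of == ""] <- "unassigned"
  subpops <- sort(unique(sub_of))
  rows <- lapply(subpops, function(sp) {
    g <- genes[sub_of == sp]
    tal <- tally_markers(g, de_table)
    n <- length(g)
    call <- if (tal["biopsy"] > tal["plucked"]) {
      "biopsy_enriched"
    } else if (tal["plucked"] > tal["biopsy"]) {
      "plucked_enriched"
    } else {
      "inconclusive"
    }
    concordance <- max(tal) / n
    tibble(
      population = population,
      subpopulation = sp,
      n_markers = n,
      n_biopsy_higher = unname(tal["biopsy"]),
      n_plucked_higher = unname(tal["plucked"]),
      concordance = concordance,
      call = call,
      predominant = call != "inconclusive" & concordance < conclusive_threshold
    )
  })
  dplyr::bind_rows(rows)
}

#' Project differential-abundance results onto a cell-population reference
#'
#' The full cell-type identification procedure: map study genes onto the
#' reference namespace ([map_orthologs()]), partition genes by expression and
#' significance in the two datasets ([classify_venn()]), keep the genes
#' expressed and significant in both, reduce them to population-unique
#' markers ([extract_unique_markers()]), tally the markers' differential
#' directions into per-population enrichment calls ([call_enrichment()]), and
#' refine every population that carries subpopulation annotation
#' ([refine_subpopulations()]).
#'
#' @param de A `de_result` from [run_contrast()] (or its tidy table).
#' @param ortholog_map Ortholog map tibble.
#' @param reference Validated marker reference.
#' @param ref_expressed Reference-species expressed set; defaults to every
#'   gene with an entry in `reference`.
#' @param ref_significant Reference-species significant set; defaults to
#'   every gene with at least one `significant = TRUE` entry.
#' @param conclusive_threshold Majority fraction for conclusive calls
#'   (default 0.75).
#' @return A `cell_enrichment` object with elements `venn`, `markers`,
#'   `calls`, `subpopulation_calls`, `mapping` (unmapped/ambiguous
#'   accounting), and `contrast`. [tidy()] returns the calls; [glance()] a
#'   one-row summary.
#' @export
project_markers <- function(de, ortholog_map, reference,
                            ref_expressed = NULL, ref_significant = NULL,
                            conclusive_threshold = 0.75) {
  de_table <- if (inherits(de, "de_result")) de$table else as_tibble(de)
  ref_expressed <- ref_expressed %||% unique(reference$gene_id)
  ref_significant <- ref_significant %||%
    unique(reference$gene_id[reference$significant])
  mapping <- map_orthologs(de_table$gene_id, ortholog_map)
  to_ref <- setNames(mapping$pairs$reference_gene_id, mapping$pairs$study_gene_id)
  study_expressed <- unname(to_ref[de_table$gene_id[de_table$gene_id %in% names(to_ref)]])
  sig_ids <- de_table$gene_id[de_table$significant]
  study_significant <- unname(to_ref[sig_ids[sig_ids %in% names(to_ref)]])
  venn <- classify_venn(study_expressed, study_significant, ref_expressed, ref_significant)
  carried <- intersect(carried_genes(venn), reference$gene_id)
  markers <- extract_unique_markers(carried, reference)
  # vote with the study-side DE directions, re-keyed to the reference namespace
  de_ref <- de_table[de_table$gene_id %in% names(to_ref), ]
  de_ref$gene_id <- unname(to_ref[de_ref$gene_id])
  calls <- call_enrichment(markers, de_ref, conclusive_threshold,
                           populations = attr(markers, "populations"))
  with_sub <- unique(reference$population[reference$significant &
                                            reference$subpopulation != ""])
  with_sub <- intersect(with_sub, markers$population)
  sub_template <- tibble(
    population = character(), subpopulation = character(),
    n_markers = integer(), n_biopsy_higher = integer(),
    n_plucked_higher = integer(), concordance = double(),
    call = character(), predominant = logical()
  )
  sub_calls <- dplyr::bind_rows(sub_template, lapply(with_sub, function(pop) {
    refine_subpopulations(pop, markers, reference, de_ref, conclusive_threshold)
  }))
  structure(
    list(
      venn = venn,
      markers = markers,
      calls = calls,
      subpopulation_calls = sub_calls,
      mapping = tibble(
        n_study_genes = nrow(de_table),
        n_mapped = nrow(mapping$pairs),
        n_unmapped = length(mapping$unmapped),
        n_ambiguous = length(mapping$ambiguous)
      ),
      unmapped = mapping$unmapped,
      ambiguous = mapping$ambiguous,
      n_excluded_multi = attr(markers, "n_excluded_multi"),
      conclusive_threshold = conclusive_threshold,
      contrast = if (inherits(de, "de_result")) de$contrast else NA_character_
    ),
    class = "cell_enrichment"
  )
}

#' @export
print.cell_enrichment <- function(x, ...) {
  cat(sprintf(
    "<cell_enrichment> %d carried genes -> %d unique markers (%d excluded as multi-population)\n",
    length(carried_genes(x$venn)), nrow(x$markers), x$n_excluded_multi
  ))
  print(x$calls)
  invisible(x)
}

#' @rdname project_markers
#' @param x A `cell_enrichment`.
#' @param ... Unused.
#' @export
tidy.cell_enrichment <- function(x, ...) x$calls

#' @rdname project_markers
#' @export
glance.cell_enrichment <- function(x, ...) {
  tibble(
    contrast = x$contrast,
    n_carried = length(carried_genes(x$venn)),
    n_markers = nrow(x$markers),
    n_excluded_multi = x$n_excluded_multi,
    n_populations = nrow(x$calls),
    n_conclusive = sum(x$calls$call %in% c("biopsy_enriched", "plucked_enriched")),
    n_inconclusive = sum(x$calls$call == "inconclusive"),
    n_no_call = sum(x$calls$call == "no_call"),
    conclusive_threshold = x$conclusive_threshold
  )
}
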