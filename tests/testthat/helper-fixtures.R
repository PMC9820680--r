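# small programmatic fixtures shared across test files

make_cm <- function(mat, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(mat)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, samples)
  count_matrix(mat)
}

# equal-effective-size normalization factors, for tests that want the
# common-library rescaling to be the identity
unit_factors <- function(cm, eff = 1e6) {
  tibble::tibble(
    sample_id = sample_ids(cm),
    lib_size = as.numeric(library_sizes(cm)),
    norm_factor = 1,
    effective_lib_size = eff
  )
}

# a DE table with prescribed directions for projection tests
de_table_with <- function(genes, directions) {
  tibble::tibble(
    gene_id = genes,
    log2_fc = ifelse(directions == "biopsy_higher", 1,
                     ifelse(directions == "plucked_higher", -1, 0)),
    p_value = ifelse(directions == "none", 0.9, 1e-4),
    fdr = ifelse(directions == "none", 0.9, 1e-3),
    significant = directions != "none",
    direction = directions
  )
}

# a marker reference with a prescribed number of unique markers per
# population; gene ids are generated deterministically
reference_with_counts <- function(counts_per_pop) {
  rows <- lapply(names(counts_per_pop), function(pop) {
    n <- counts_per_pop[[pop]]
    if (n == 0) return(NULL)
    tibble::tibble(
      gene_id = sprintf("%s_m%d", pop, seq_len(n)),
      population = pop,
      subpopulation = "",
      significant = TRUE
    )
  })
  validate_marker_reference(dplyr::bind_rows(rows),
                            populations = names(counts_per_pop))
}
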