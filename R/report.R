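#' Summarize gene detection against the genome annotation
#'
#' Counts the detected (filter-surviving) genes overall and per biotype, and
#' reports what percentage of the annotated protein-coding genes was
#' detected, rounded to the nearest integer percent.
#'
#' @param detected Either a filtered [count_matrix()] or a character vector
#'   of detected gene ids.
#' @param biotype Mapping from gene id to biotype: a tibble with columns
#'   `gene_id` and `biotype`. Detected genes absent from the mapping are
#'   counted under `"other"`.
#' @param n_annotated_protein_coding Number of protein-coding genes annotated
#'   in the genome assembly; must be positive.
#' @return A list with `by_biotype` (tibble of detected counts per biotype),
#'   `n_detected` (total), and `pct_protein_coding_detected` (integer
#'   percent).
#' @export
#' @examples
#' detection_summary(
#'   sprintf("g%d", 1:5),
#'   tibble::tibble(gene_id = sprintf("g%d", 1:5),
#'                  biotype = c(rep("protein_coding", 4), "lncRNA")),
#'   n_annotated_protein_coding = 6
#' )
detection_summary <- function(detected, biotype, n_annotated_protein_coding) {
  if (n_annotated_protein_coding <= 0) {
    abort("`n_annotated_protein_coding` must be positive.")
  }
  ids <- if (inherits(detected, "count_matrix")) gene_ids(detected) else unique(detected)
  bt <- setNames(biotype$biotype, biotype$gene_id)[ids]
  bt[is.na(bt)] <- "other"
  by_biotype <- tibble(biotype = bt) |>
    count(.data$biotype, name = "n_detected") |>
    arrange(dplyr::desc(.data$n_detected))
  n_pc <- sum(bt == "protein_coding")
  list(
    by_biotype = by_biotype,
    n_detected = length(ids),
    n_protein_coding_detected = n_pc,
    n_annotated_protein_coding = as.integer(n_annotated_protein_coding),
    pct_protein_coding_detected = as.integer(round(100 * n_pc / n_annotated_protein_coding))
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline and write its artifacts
#'
#' Orchestrates filter, normalize, the three study contrasts (all samples,
#' forelock only, mane only — skipping site contrasts without two samples per
#' group), and the marker projection of the all-samples contrast. Every
#' stage's output is written under `out_dir`: `filter_report.json`,
#' `normalization_factors.tsv`, `de_<contrast>.tsv`, `venn.json`,
#' `markers.tsv`, `calls.tsv`, and a human-readable `report.md` rendered
#' *from those artifacts* (single source of truth: the renderer re-reads the
#' files rather than recomputing).
#'
#' Per-site contrasts reuse the full-matrix TMM factors rather than
#' renormalizing per subset (set `renormalize_per_contrast = TRUE` for a
#' sensitivity analysis).
#'
#' @param counts A [count_matrix()] or path to a count TSV.
#' @param sheet Sample sheet tibble or path.
#' @param reference Marker reference tibble or path.
#' @param orthologs Ortholog map tibble or path.
#' @param out_dir Output directory (created if missing).
#' @param dialect Count-file dialect when `counts` is a path.
#' @param min_rpm,min_samples Low-expression filter parameters.
#' @param alpha FDR threshold.
#' @param conclusive_threshold Majority fraction for conclusive enrichment
#'   calls.
#' @param reference_sample Optional TMM reference sample id.
#' @param ref_expressed,ref_significant Optional reference-side gene sets
#'   (defaults derived from `reference`).
#' @param renormalize_per_contrast Recompute TMM factors within each site
#'   subset (default `FALSE`).
#' @return Invisibly, a list with the in-memory results (`filtered`,
#'   `factors`, `contrasts`, `projection`, `paths`).
#' @export
run_pipeline <- function(counts, sheet, reference, orthologs, out_dir,
                         dialect = "plain", min_rpm = 1, min_samples = 2,
                         alpha = 0.05, conclusive_threshold = 0.75,
                         reference_sample = NULL,
                         ref_expressed = NULL, ref_significant = NULL,
                         renormalize_per_contrast = FALSE) {
  if (is.character(counts)) counts <- read_count_matrix(counts, dialect = dialect)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  sheet <- validate_sample_sheet(sheet)
  if (is.character(reference)) reference <- read_marker_reference(reference)
  if (is.character(orthologs)) orthologs <- read_ortholog_map(orthologs)
  check_sheet_covers(sheet, counts)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  filtered <- filter_low_expression(counts, min_rpm = min_rpm, min_samples = min_samples)
  factors <- compute_tmm_factors(filtered, reference = reference_sample)
  write_json_file(as.list(filter_report(filtered)), file.path(out_dir, "filter_report.json"))
  readr::write_tsv(factors, file.path(out_dir, "normalization_factors.tsv"), progress = FALSE)

  specs <- list(all = contrast_spec())
  for (s in intersect(c("forelock", "mane"), unique(sheet$site))) {
    n_per <- table(sheet$source[sheet$site == s])
    if (length(n_per) == 2 && all(n_per >= 2)) specs[[s]] <- contrast_spec(site = s)
  }
  contrasts <- lapply(specs, function(sp) {
    f <- if (renormalize_per_contrast) {
      ids <- unlist(resolve_contrast(sheet, sp, filtered))
      compute_tmm_factors(subset_samples(filtered, ids))
    } else {
      factors
    }
    run_contrast(filtered, sheet, sp, factors = f, alpha = alpha)
  })
  for (nm in names(contrasts)) {
    readr::write_tsv(tidy(contrasts[[nm]]), file.path(out_dir, sprintf("de_%s.tsv", nm)),
                     progress = FALSE)
  }

  projection <- project_markers(
    contrasts$all, orthologs, reference,
    ref_expressed = ref_expressed, ref_significant = ref_significant,
    conclusive_threshold = conclusive_threshold
  )
  write_json_file(
    list(
      regions = setNames(as.list(projection$venn$regions$n), projection$venn$regions$region),
      genes = projection$venn$genes,
      n_unmapped = length(projection$unmapped),
      n_ambiguous = length(projection$ambiguous),
      n_excluded_multi = projection$n_excluded_multi
    ),
    file.path(out_dir, "venn.json")
  )
  readr::write_tsv(projection$markers, file.path(out_dir, "markers.tsv"), progress = FALSE)
  calls <- dplyr::bind_rows(
    mutate(projection$calls, subpopulation = "", predominant = FALSE),
    projection$subpopulation_calls
  ) |>
    select("population", "subpopulation", "n_markers", "n_biopsy_higher",
           "n_plucked_higher", "concordance", "call", "predominant")
  readr::write_tsv(calls, file.path(out_dir, "calls.tsv"), progress = FALSE)

  de_summaries <- dplyr::bind_rows(lapply(contrasts, glance))
  readr::write_tsv(de_summaries, file.path(out_dir, "de_summary.tsv"), progress = FALSE)
  render_report(out_dir)

  invisible(list(
    filtered = filtered,
    factors = factors,
    contrasts = contrasts,
    projection = projection,
    paths = file.path(out_dir, c(
      "filter_report.json", "normalization_factors.tsv", "de_summary.tsv",
      "venn.json", "markers.tsv", "calls.tsv", "report.md"
    ))
  ))
}

# report.md is rendered from the written artifacts only, never from the
# in-memory objects, so its numbers cannot drift from the machine-readable
# outputs
render_report <- function(out_dir) {
  fr <- jsonlite::read_json(file.path(out_dir, "filter_report.json"))
  de <- readr::read_tsv(file.path(out_dir, "de_summary.tsv"), show_col_types = FALSE,
                        progress = FALSE)
  venn <- jsonlite::read_json(file.path(out_dir, "venn.json"))
  calls <- readr::read_tsv(file.path(out_dir, "calls.tsv"), show_col_types = FALSE,
                           progress = FALSE)
  lines <- c(
    "# Plucked hair vs skin biopsy: pipeline report",
    "",
    "## Low-expression filter",
    sprintf(
      "Retained %s of %s genes (RPM >= %s in >= %s samples).",
      fr$n_retained_genes, fr$n_input_genes, fr$min_rpm, fr$min_samples
    ),
    "",
    "## Differential abundance (higher = skin biopsy)",
    "",
    "| Contrast | Lower abundance | Higher abundance |",
    "| --- | --- | --- |",
    sprintf("| %s | %d | %d |", de$contrast, de$n_plucked_higher, de$n_biopsy_higher),
    "",
    "## Venn partition (reference namespace)",
    "",
    "| Region | Genes |",
    "| --- | --- |",
    sprintf("| %s | %d |", names(venn$regions), unlist(venn$regions)),
    "",
    sprintf(
      "Genes lost in ortholog mapping: %d unmapped, %d ambiguous. Markers excluded as multi-population: %d.",
      venn$n_unmapped, venn$n_ambiguous, venn$n_excluded_multi
    ),
    "",
    "## Enrichment calls",
    "",
    "| Population | Subpopulation | Markers | Biopsy higher | Plucked higher | Call | Predominant |",
    "| --- | --- | --- | --- | --- | --- | --- |",
    sprintf(
      "| %s | %s | %d | %d | %d | %s | %s |",
      calls$population, dplyr::coalesce(calls$subpopulation, ""), calls$n_markers,
      calls$n_biopsy_higher, calls$n_plucked_higher, calls$call,
      ifelse(calls$predominant, "yes", "")
    )
  )
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(file.path(out_dir, "report.md"))
}

# subset a count matrix's samples, keeping load-time library sizes
subset_samples <- function(x, keep) {
  count_matrix(x$counts[, keep, drop = FALSE], library_sizes(x)[keep])
}
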