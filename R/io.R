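#' The seven main skin cell populations
#'
#' The closed default vocabulary for marker references: permanent epidermis
#' keratinocytes, skin fibroblasts and fibroblast-like cells, anagen
#' hair-follicle keratinocytes, vascular cells, neural-crest-derived cells,
#' immune cells, and miscellaneous (red blood and muscle) cells.
#'
#' @return Character vector of population identifiers.
#' @export
skin_populations <- function() {
  c(
    "permanent_epidermis", "fibroblast", "anagen_hf", "vascular",
    "neural_crest", "immune", "miscellaneous"
  )
}

read_delim_quiet <- function(path, delim, col_types = NULL, comment = "") {
  readr::read_delim(
    path,
    delim = delim, col_types = col_types, comment = comment,
    progress = FALSE, show_col_types = FALSE, trim_ws = TRUE
  )
}

# strip directory components and common alignment-file extensions from
# featureCounts sample headers ("/path/to/s1.bam" -> "s1")
strip_sample_name <- function(x) {
  sub("\\.(bam|sam|cram)$", "", basename(x), ignore.case = TRUE)
}

fc_annotation_cols <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")

#' Read a gene-by-sample count matrix
#'
#' Two dialects are supported. `"featurecounts"` expects the Subread
#' featureCounts layout: an optional leading `#` program line, then a header
#' `Geneid Chr Start End Strand Length` followed by one column per sample
#' (sample names are stripped of directory paths and `.bam`/`.sam`/`.cram`
#' extensions). `"plain"` expects a gene-id column followed by sample columns.
#' Library sizes are fixed at load time as the column sums over all genes.
#'
#' @param path Path to a tab-separated file.
#' @param dialect `"plain"` (default) or `"featurecounts"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, dialect = c("plain", "featurecounts")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- read_delim_quiet(path, "\t", comment = if (dialect == "featurecounts") "#" else "")
  if (dialect == "featurecounts") {
    missing_cols <- setdiff(fc_annotation_cols, names(tab))
    if (length(missing_cols)) {
      abort(paste0(
        "Not a featureCounts table; missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ))
    }
    gene <- as.character(tab$Geneid)
    tab <- tab[, setdiff(names(tab), fc_annotation_cols), drop = FALSE]
    stripped <- strip_sample_name(names(tab))
    if (anyDuplicated(stripped)) {
      abort(paste0(
        "Sample names collide after basename-stripping: ",
        paste(unique(stripped[duplicated(stripped)]), collapse = ", ")
      ))
    }
    names(tab) <- stripped
  } else {
    if (ncol(tab) < 2) abort("Plain count table needs a gene-id column plus sample columns.")
    gene <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
  }
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      abort(sprintf("Column '%s' contains non-numeric counts.", names(tab)[j]))
    }
    bad <- which(is.na(col) | col != round(col) | col < 0)
    if (length(bad)) {
      abort(sprintf(
        "Count for gene '%s' in sample '%s' is not a non-negative integer (value: %s).",
        gene[bad[1]], names(tab)[j], format(col[bad[1]])
      ))
    }
  }
  m <- as.matrix(tab)
  rownames(m) <- gene
  count_matrix(m)
}

#' Write a count matrix as plain TSV
#'
#' Writes the `"plain"` dialect: a `gene_id` column followed by one column per
#' sample. Reading the file back with [read_count_matrix()] reproduces the
#' object exactly (library sizes are recomputed as column sums, which is how
#' they were defined at load time).
#'
#' @param x A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  df <- as.data.frame(x$counts)
  df <- cbind(gene_id = rownames(x$counts), df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' A comma- or tab-separated table with columns `sample_id`, `source`
#' (`plucked` or `biopsy`), `site` (`forelock` or `mane`), and `subject_id`.
#'
#' @param path Path to the sheet; the delimiter is sniffed from the header.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- read_delim_quiet(path, delim, col_types = readr::cols(.default = readr::col_character()))
  validate_sample_sheet(tab)
}

#' @rdname read_sample_sheet
#' @param sheet A data frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "source", "site", "subject_id")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols)) {
    abort(paste0("Sample sheet missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  sheet <- as_tibble(sheet)[, required]
  if (anyDuplicated(sheet$sample_id)) {
    abort(paste0(
      "Duplicate sample_id(s): ",
      paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", ")
    ))
  }
  bad_source <- setdiff(unique(sheet$source), c("plucked", "biopsy"))
  if (length(bad_source)) {
    abort(sprintf(
      "Unknown source level(s) %s; allowed: plucked, biopsy.",
      paste(sQuote(bad_source), collapse = ", ")
    ))
  }
  bad_site <- setdiff(unique(sheet$site), c("forelock", "mane"))
  if (length(bad_site)) {
    abort(sprintf(
      "Unknown site level(s) %s; allowed: forelock, mane.",
      paste(sQuote(bad_site), collapse = ", ")
    ))
  }
  sheet
}

# every count-matrix sample must be described by the sheet
check_sheet_covers <- function(sheet, counts) {
  missing_samples <- setdiff(sample_ids(counts), sheet$sample_id)
  if (length(missing_samples)) {
    abort(paste0(
      "Sample sheet does not describe sample(s): ",
      paste(missing_samples, collapse = ", ")
    ))
  }
  invisible(sheet)
}

#' Read and validate a cell-population marker reference
#'
#' A tab-separated table with columns `gene_id`, `population`, `subpopulation`
#' (may be empty), and `significant` (logical), derived from a single-cell
#' study of the reference species. A gene may appear under several
#' populations; `(gene_id, population)` pairs must be unique and each
#' subpopulation must belong to exactly one parent population.
#'
#' @param path Path to the TSV.
#' @param populations Closed set of allowed population labels; defaults to the
#'   seven main skin populations of [skin_populations()]. Pass a longer vector
#'   to extend the vocabulary.
#' @return A validated tibble with columns `gene_id`, `population`,
#'   `subpopulation`, `significant`.
#' @export
read_marker_reference <- function(path, populations = skin_populations()) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- read_delim_quiet(path, "\t", col_types = readr::cols(
    gene_id = readr::col_character(),
    population = readr::col_character(),
    subpopulation = readr::col_character(),
    significant = readr::col_logical()
  ))
  validate_marker_reference(tab, populations = populations)
}

#' @rdname read_marker_reference
#' @param reference A data frame to validate in place.
#' @export
validate_marker_reference <- function(reference, populations = skin_populations()) {
  required <- c("gene_id", "population", "subpopulation", "significant")
  missing_cols <- setdiff(required, names(reference))
  if (length(missing_cols)) {
    abort(paste0("Marker reference missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  reference <- as_tibble(reference)[, required]
  reference$subpopulation[is.na(reference$subpopulation)] <- ""
  unknown <- setdiff(unique(reference$population), populations)
  if (length(unknown)) {
    abort(sprintf(
      "Unknown population(s) %s; allowed: %s. Pass `populations = ` to extend the set.",
      paste(sQuote(unknown), collapse = ", "),
      paste(populations, collapse = ", ")
    ))
  }
  key <- paste(reference$gene_id, reference$population)
  if (anyDuplicated(key)) {
    abort(paste0(
      "Duplicate (gene_id, population) row(s): ",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    ))
  }
  sub <- reference[reference$subpopulation != "", c("subpopulation", "population")]
  sub <- unique(sub)
  if (anyDuplicated(sub$subpopulation)) {
    dup <- unique(sub$subpopulation[duplicated(sub$subpopulation)])
    abort(paste0(
      "Subpopulation(s) mapped to more than one parent population: ",
      paste(dup, collapse = ", ")
    ))
  }
  attr(reference, "populations") <- populations
  reference
}

#' Write a marker reference as TSV
#'
#' @param reference A validated marker reference tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_reference <- function(reference, path) {
  readr::write_tsv(reference, path, progress = FALSE)
  invisible(path)
}

#' Read an ortholog map
#'
#' A two-column TSV (`study_gene_id`, `reference_gene_id`) giving candidate
#' correspondences between study-species and reference-species gene
#' identifiers. The map may be many-to-many here; [map_orthologs()] retains
#' only the pairs that are one-to-one in both directions.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `study_gene_id`, `reference_gene_id`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- read_delim_quiet(path, "\t", col_types = readr::cols(.default = readr::col_character()))
  required <- c("study_gene_id", "reference_gene_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("Ortholog map missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  as_tibble(tab)[, required]
}

#' Standardize gene identifiers for matching
#'
#' Accession-style identifiers (Ensembl `ENS...` accessions) are matched
#' case-sensitively; symbol-style identifiers (e.g. `KRT84`) are folded to
#' upper case so that symbol capitalization conventions, which differ between
#' species, do not break joins.
#'
#' @param ids Character vector of gene identifiers.
#' @param symbols_case_insensitive Fold non-accession ids to upper case
#'   (default `TRUE`).
#' @return Character vector of the same length.
#' @export
standardize_gene_ids <- function(ids, symbols_case_insensitive = TRUE) {
  if (!symbols_case_insensitive) return(ids)
  accession <- grepl("^ENS[A-Z]*[0-9]{6,}", ids)
  ids[!accession] <- toupper(ids[!accession])
  ids
}
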