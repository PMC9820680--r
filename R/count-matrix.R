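#' Construct a count matrix
#'
#' The pipeline's sole experimental input: a genes-by-samples matrix of
#' non-negative integer read counts together with the per-sample library
#' sizes. Library sizes are fixed when the object is created (the column sums
#' over *all* genes) and are deliberately preserved unchanged through
#' low-expression filtering, so that reads-per-million always refers to
#' sequencing depth rather than to the post-filter subtotal.
#'
#' @param counts Integer matrix, genes in rows, samples in columns. Must have
#'   unique, non-empty row and column names.
#' @param library_sizes Optional named numeric vector of per-sample library
#'   sizes. Defaults to the column sums of `counts`. Must be positive when the
#'   corresponding column has any use downstream.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `library_sizes` (named numeric).
#' @export
#' @examples
#' m <- matrix(c(1L, 3L, 2L, 4L), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cm <- count_matrix(m)
#' library_sizes(cm)
count_matrix <- function(counts, library_sizes = NULL) {
  if (!is.matrix(counts)) {
    abort("`counts` must be a matrix.")
  }
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (nrow(counts) > 0 && is.null(gene_ids)) {
    abort("`counts` must have row (gene) names.")
  }
  if (ncol(counts) > 0 && is.null(sample_ids)) {
    abort("`counts` must have column (sample) names.")
  }
  if (is.null(gene_ids)) gene_ids <- character(0)
  if (anyDuplicated(gene_ids)) {
    abort(paste0(
      "Duplicate gene id(s): ",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0(
      "Duplicate sample id(s): ",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ))
  }
  if (anyNA(counts)) abort("`counts` must not contain missing values.")
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-integer count at gene '%s', sample '%s'.",
      gene_ids[bad[1]], sample_ids[bad[2]]
    ))
  }
  storage.mode(counts) <- "integer"
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts)
  } else {
    library_sizes <- library_sizes[sample_ids]
    if (anyNA(library_sizes)) {
      abort("`library_sizes` must be named for every sample in `counts`.")
    }
  }
  structure(
    list(counts = counts, library_sizes = as.numeric(setNames(library_sizes, sample_ids))),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d samples (library sizes %s..%s)\n",
    nrow(x$counts), ncol(x$counts),
    format(min(x$library_sizes)), format(max(x$library_sizes))
  ))
  invisible(x)
}

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname count_matrix
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname count_matrix
#' @export
library_sizes <- function(x) setNames(x$library_sizes, colnames(x$counts))

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tidy a count matrix into long format
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `count`.
#' @export
as_tibble.count_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
}

# subset genes, keeping the load-time library sizes
subset_genes <- function(x, keep) {
  count_matrix(x$counts[keep, , drop = FALSE], library_sizes(x))
}
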