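#' Reads per million
#'
#' Scales each count by one-millionth of its sample's library size. Library
#' sizes are the load-time column sums of the unfiltered matrix, so RPM always
#' refers to sequencing depth even after low-expression filtering.
#'
#' @param counts A [count_matrix()].
#' @return Numeric matrix, genes by samples.
#' @export
compute_rpm <- function(counts) {
  ls <- library_sizes(counts)
  if (any(ls <= 0)) {
    abort(paste0(
      "Zero or negative library size for sample(s): ",
      paste(names(ls)[ls <= 0], collapse = ", ")
    ))
  }
  sweep(counts$counts, 2, ls, "/") * 1e6
}

#' Filter genes with low expression
#'
#' Retains the genes with at least `min_rpm` reads per million in at least
#' `min_samples` samples; everything else is removed before normalization and
#' testing. Library sizes are deliberately left at their load-time values.
#'
#' @param counts A [count_matrix()].
#' @param min_rpm Minimum reads-per-million threshold (default 1).
#' @param min_samples Minimum number of samples meeting the threshold
#'   (default 2).
#' @return The filtered [count_matrix()], carrying a `filter_report`
#'   attribute; retrieve it with [filter_report()].
#' @export
#' @examples
#' m <- matrix(c(10L, 0L, 12L, 1L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' filtered <- filter_low_expression(count_matrix(m), min_rpm = 1, min_samples = 2)
#' filter_report(filtered)
filter_low_expression <- function(counts, min_rpm = 1, min_samples = 2) {
  n_samples <- ncol(counts$counts)
  if (min_samples > n_samples) {
    abort(sprintf(
      "`min_samples` (%d) exceeds the number of samples (%d).",
      min_samples, n_samples
    ))
  }
  rpm <- compute_rpm(counts)
  keep <- rowSums(rpm >= min_rpm) >= min_samples
  out <- subset_genes(counts, keep)
  attr(out, "filter_report") <- tibble(
    n_input_genes = nrow(counts$counts),
    n_retained_genes = sum(keep),
    min_rpm = min_rpm,
    min_samples = as.integer(min_samples)
  )
  out
}

#' @rdname filter_low_expression
#' @param x A filtered count matrix.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report") %||%
    abort("No filter report attached; was this produced by filter_low_expression()?")
}

#' Choose the TMM reference sample
#'
#' The reference column is the sample whose 75th percentile of RPM (over its
#' genes with nonzero count) is closest to the mean of that statistic across
#' samples; ties break to the lowest sample index. This mirrors common
#' practice for trimmed-mean normalization, where an "average" library makes
#' the most stable anchor for pairwise log-ratios.
#'
#' @param counts A [count_matrix()].
#' @return A sample id.
#' @export
select_reference_sample <- function(counts) {
  rpm <- compute_rpm(counts)
  uq <- vapply(seq_len(ncol(rpm)), function(j) {
    nz <- counts$counts[, j] > 0
    if (!any(nz)) return(NA_real_)
    quantile(rpm[nz, j], 0.75, names = FALSE)
  }, numeric(1))
  if (all(is.na(uq))) abort("All-zero count matrix; cannot choose a reference sample.")
  target <- mean(uq, na.rm = TRUE)
  sample_ids(counts)[which.min(abs(uq - target))]
}

# one pairwise TMM factor: sample k against reference r
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a, min_genes = 10) {
  nz <- obs > 0 & ref > 0
  obs <- obs[nz]
  ref <- ref[nz]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  n <- length(m)
  if (n > 0) {
    # rank-based double trim with average ranks on ties, the convention of
    # the reference implementation of this estimator
    lo_m <- floor(n * trim_m) + 1
    lo_a <- floor(n * trim_a) + 1
    rm_ <- rank(m)
    ra_ <- rank(a)
    keep <- rm_ >= lo_m & rm_ <= n + 1 - lo_m & ra_ >= lo_a & ra_ <= n + 1 - lo_a
  } else {
    keep <- logical(0)
  }
  if (sum(keep) < min_genes) {
    warn(sprintf(
      "Fewer than %d genes survive TMM trimming for this sample; using factor 1.",
      min_genes
    ))
    return(1)
  }
  2^(sum(w[keep] * m[keep]) / sum(w[keep]))
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample scaling factors by the trimmed-mean-of-M-values
#' estimator. For each sample against the reference, over genes with nonzero
#' count in both columns, the per-gene log-ratio
#' \eqn{M_g = \log_2((y_{gk}/N_k)/(y_{gr}/N_r))} and average log-expression
#' \eqn{A_g = \tfrac12\log_2((y_{gk}/N_k)(y_{gr}/N_r))} are formed; the top and
#' bottom `trim_m` fraction of genes by M and `trim_a` fraction by A are
#' dropped (union of drops), and the factor is the inverse-variance-weighted
#' mean of the surviving M values, back-transformed from log2. Factors are
#' finally rescaled so their geometric mean is exactly 1; effective library
#' sizes are \eqn{N_j f_j}.
#'
#' @param counts A (typically filtered) [count_matrix()].
#' @param reference Reference sample id; defaults to
#'   [select_reference_sample()].
#' @param trim_m Two-sided trim fraction on M (default 0.30, the estimator's
#'   published default).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return A tibble of class `tmm_factors` with columns `sample_id`,
#'   `lib_size`, `norm_factor`, `effective_lib_size`, and a
#'   `reference_sample` attribute.
#' @export
compute_tmm_factors <- function(counts, reference = NULL, trim_m = 0.30, trim_a = 0.05) {
  ids <- sample_ids(counts)
  reference <- reference %||% select_reference_sample(counts)
  if (!reference %in% ids) {
    abort(sprintf("Reference sample '%s' is not a column of `counts`.", reference))
  }
  ls <- library_sizes(counts)
  r <- match(reference, ids)
  f <- vapply(seq_along(ids), function(k) {
    if (k == r) return(1)
    tmm_pair_factor(
      counts$counts[, k], counts$counts[, r], ls[k], ls[r],
      trim_m = trim_m, trim_a = trim_a
    )
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  out <- tibble(
    sample_id = ids,
    lib_size = as.numeric(ls),
    norm_factor = f,
    effective_lib_size = as.numeric(ls) * f
  )
  attr(out, "reference_sample") <- reference
  class(out) <- c("tmm_factors", class(out))
  out
}

#' @rdname compute_tmm_factors
#' @param x A `tmm_factors` object.
#' @export
reference_sample <- function(x) attr(x, "reference_sample")

#' Filter and TMM-normalize in one step
#'
#' Convenience wrapper: [filter_low_expression()] followed by
#' [compute_tmm_factors()].
#'
#' @inheritParams filter_low_expression
#' @inheritParams compute_tmm_factors
#' @return A list with elements `counts` (filtered matrix) and `factors`
#'   (`tmm_factors` tibble).
#' @export
tmm_normalize <- function(counts, min_rpm = 1, min_samples = 2,
                          reference = NULL, trim_m = 0.30, trim_a = 0.05) {
  filtered <- filter_low_expression(counts, min_rpm = min_rpm, min_samples = min_samples)
  list(
    counts = filtered,
    factors = compute_tmm_factors(filtered, reference = reference,
                                  trim_m = trim_m, trim_a = trim_a)
  )
}
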