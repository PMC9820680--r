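#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Hand-rolled step-up procedure: with the p-values in increasing order
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, the adjusted value of \eqn{p_{(i)}} is
#' \eqn{\min_{j \ge i} \min(1, m\,p_{(j)}/j)}. Adjusted values are monotone
#' non-decreasing in p-value rank and capped at 1.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  adj[order(o)]
}

# log-sum-exp, guarding against -Inf-only input
logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

exact_p_one <- function(s_a, s_b, n_a, n_b, dispersion) {
  t <- s_a + s_b
  if (t == 0) return(1)
  x <- 0:t
  if (dispersion == 0) {
    # Poisson limit: conditional on the total, the group-A sum is binomial
    logp <- dbinom(x, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    # sums of n i.i.d. NB(mu, phi) are NB(n*mu, phi/n); conditioning on the
    # total gives a law free of mu because both sums share the same
    # probability parameter
    mu_a <- t * n_a / (n_a + n_b)
    mu_b <- t * n_b / (n_a + n_b)
    logp <- dnbinom(x, size = n_a / dispersion, mu = mu_a, log = TRUE) +
      dnbinom(t - x, size = n_b / dispersion, mu = mu_b, log = TRUE)
    logp <- logp - logsumexp(logp)
  }
  p_obs <- logp[s_a + 1]
  min(1, sum(exp(logp[logp <= p_obs + 1e-10])))
}

#' Conditional negative-binomial exact test
#'
#' Two-group exact test for count data. Group sums are modelled as independent
#' negative binomials with means proportional to group size (counts must
#' already be scaled to a common effective library size); conditioning on the
#' per-gene total \eqn{t = s_a + s_b} gives a discrete law over the splits
#' \eqn{(x, t - x)}, and the two-sided p-value is the sum of the probabilities
#' of all splits no more likely than the observed one (minimum-likelihood
#' rule). At dispersion 0 the conditional law reduces to a binomial; a total
#' of 0 yields p = 1.
#'
#' @param s_a,s_b Per-gene group sums (non-negative integers); vectors of
#'   equal length.
#' @param n_a,n_b Number of samples in each group.
#' @param dispersion Common NB dispersion \eqn{\phi \ge 0} (variance
#'   \eqn{\mu + \phi\mu^2}).
#' @return Vector of p-values in (0, 1].
#' @export
#' @examples
#' nb_exact_test(0, 20, 1, 1, dispersion = 0) # = 2 * 2^-20
nb_exact_test <- function(s_a, s_b, n_a, n_b, dispersion) {
  if (length(s_a) != length(s_b)) abort("`s_a` and `s_b` must have equal length.")
  if (dispersion < 0) abort("`dispersion` must be non-negative.")
  if (any(s_a < 0) || any(s_b < 0)) abort("Group sums must be non-negative.")
  vapply(
    seq_along(s_a),
    function(i) exact_p_one(s_a[i], s_b[i], n_a, n_b, dispersion),
    numeric(1)
  )
}

# geometric mean of the effective library sizes of `samples`
common_library_size <- function(factors, samples) {
  eff <- factors$effective_lib_size[match(samples, factors$sample_id)]
  if (anyNA(eff)) abort("Normalization factors missing for some samples.")
  exp(mean(log(eff)))
}

# counts rescaled to a shared effective library size (optionally rounded to
# integer pseudo-counts for the exact test)
scale_to_common <- function(counts, factors, samples, round = FALSE) {
  eff <- factors$effective_lib_size[match(samples, factors$sample_id)]
  lbar <- exp(mean(log(eff)))
  m <- sweep(counts$counts[, samples, drop = FALSE], 2, lbar / eff, "*")
  if (round) round(m) else m
}

#' Specify a plucked-versus-biopsy contrast
#'
#' Defines which samples enter the test: all plucked versus all biopsy
#' samples, optionally restricted to one sampling site. Group A is always
#' `plucked` and group B `biopsy`, so positive log2 fold changes mean higher
#' abundance in the biopsies.
#'
#' @param site `NULL` for all sites, or one of `"forelock"`, `"mane"`.
#' @param label Optional human-readable label.
#' @return A `contrast_spec` object.
#' @export
contrast_spec <- function(site = NULL, label = NULL) {
  if (!is.null(site)) {
    site <- match.arg(site, c("forelock", "mane"))
  }
  label <- label %||% if (is.null(site)) {
    "all plucked vs all biopsy"
  } else {
    sprintf("%s plucked vs %s biopsy", site, site)
  }
  structure(list(site = site, label = label), class = "contrast_spec")
}

# resolve a contrast to the two sample-id groups, enforcing replication
resolve_contrast <- function(sheet, contrast, counts = NULL) {
  sheet <- validate_sample_sheet(sheet)
  if (!is.null(counts)) check_sheet_covers(sheet, counts)
  keep <- if (is.null(contrast$site)) rep(TRUE, nrow(sheet)) else sheet$site == contrast$site
  a <- sheet$sample_id[keep & sheet$source == "plucked"]
  b <- sheet$sample_id[keep & sheet$source == "biopsy"]
  if (length(intersect(a, b))) abort("Contrast groups overlap.")
  if (length(a) < 2 || length(b) < 2) {
    abort(sprintf(
      "Each contrast group needs at least 2 samples (got %d plucked, %d biopsy for %s).",
      length(a), length(b), contrast$label
    ))
  }
  list(a = a, b = b)
}

#' Estimate a common negative-binomial dispersion
#'
#' Pooled method-of-moments estimate. Counts are rescaled to a common
#' effective library size; per gene, the within-group means and variances are
#' pooled (df-weighted variance, size-weighted mean) and converted to a
#' per-gene moment estimate \eqn{\hat\phi_g = (s^2 - m)/m^2}. The common
#' dispersion is the median over genes with pooled mean at least 1, divided by
#' the median of \eqn{\chi^2_{df}/df} (df = n - 2) to undo the downward bias
#' of the median of right-skewed variance estimates, then floored at 0.
#'
#' @param counts A filtered [count_matrix()].
#' @param group_a,group_b Sample-id vectors of the two groups (each length
#'   at least 2).
#' @param factors `tmm_factors` for the samples involved.
#' @return A one-row tibble with `common_dispersion` and `n_genes_used`.
#' @export
estimate_common_dispersion <- function(counts, group_a, group_b, factors) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 samples to estimate dispersion.")
  }
  scaled <- scale_to_common(counts, factors, c(group_a, group_b))
  a <- scaled[, group_a, drop = FALSE]
  b <- scaled[, group_b, drop = FALSE]
  n_a <- length(group_a)
  n_b <- length(group_b)
  m_a <- rowMeans(a)
  m_b <- rowMeans(b)
  v_a <- rowSums((a - m_a)^2) / (n_a - 1)
  v_b <- rowSums((b - m_b)^2) / (n_b - 1)
  m_pool <- (n_a * m_a + n_b * m_b) / (n_a + n_b)
  s2_pool <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
  use <- m_pool >= 1
  if (!any(use)) abort("Matrix too sparse: no gene with pooled mean >= 1.")
  phi_g <- (s2_pool - m_pool) / m_pool^2
  df <- n_a + n_b - 2
  phi <- median(phi_g[use]) / (qchisq(0.5, df) / df)
  tibble(
    common_dispersion = max(phi, 0),
    n_genes_used = sum(use)
  )
}

#' Run a two-group differential-abundance contrast
#'
#' The full per-gene test: counts (already low-expression filtered) are
#' rescaled to a common effective library size and rounded to integer
#' pseudo-counts; a common dispersion is estimated by
#' [estimate_common_dispersion()] unless supplied; each gene's group sums are
#' compared with [nb_exact_test()]; p-values are adjusted with [bh_fdr()].
#' Log2 fold changes are `log2((mean_biopsy + c) / (mean_plucked + c))` on the
#' normalized (pseudo-count) scale with pseudo-count `c = 0.125`, so positive
#' values mean higher abundance in the skin biopsies.
#'
#' @param counts A filtered [count_matrix()].
#' @param sheet Sample sheet covering the samples of `counts`.
#' @param contrast A [contrast_spec()].
#' @param factors Optional `tmm_factors`; computed from `counts` when absent.
#' @param alpha FDR significance threshold (default 0.05).
#' @param dispersion Optional fixed common dispersion; estimated when `NULL`.
#' @param log_pseudo Pseudo-count added to group means in the fold change
#'   (default 0.125).
#' @return A `de_result` object. [tidy()] returns the per-gene table
#'   (`gene_id`, `log2_fc`, `p_value`, `fdr`, `significant`, `direction`);
#'   [glance()] returns a one-row summary with the higher/lower significant
#'   tallies (higher = biopsy).
#' @export
run_contrast <- function(counts, sheet, contrast = contrast_spec(),
                         factors = NULL, alpha = 0.05, dispersion = NULL,
                         log_pseudo = 0.125) {
  groups <- resolve_contrast(sheet, contrast, counts)
  factors <- factors %||% compute_tmm_factors(counts)
  if (is.null(dispersion)) {
    disp <- estimate_common_dispersion(counts, groups$a, groups$b, factors)
    dispersion <- disp$common_dispersion
  }
  pseudo <- scale_to_common(counts, factors, c(groups$a, groups$b), round = TRUE)
  s_a <- rowSums(pseudo[, groups$a, drop = FALSE])
  s_b <- rowSums(pseudo[, groups$b, drop = FALSE])
  n_a <- length(groups$a)
  n_b <- length(groups$b)
  p <- nb_exact_test(s_a, s_b, n_a, n_b, dispersion)
  fdr <- bh_fdr(p)
  log2_fc <- log2((s_b / n_b + log_pseudo) / (s_a / n_a + log_pseudo))
  significant <- fdr < alpha
  direction <- dplyr::case_when(
    significant & log2_fc > 0 ~ "biopsy_higher",
    significant & log2_fc < 0 ~ "plucked_higher",
    .default = "none"
  )
  table <- tibble(
    gene_id = gene_ids(counts),
    log2_fc = unname(log2_fc),
    p_value = unname(p),
    fdr = unname(fdr),
    significant = unname(significant),
    direction = direction
  )
  structure(
    list(
      table = table,
      contrast = contrast$label,
      site = contrast$site,
      n_plucked = n_a,
      n_biopsy = n_b,
      alpha = alpha,
      dispersion = dispersion
    ),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<de_result> %s: %d genes, %d significant at FDR < %g (%d higher in biopsy, %d higher in plucked); common dispersion %.4g\n",
    x$contrast, g$n_genes, g$n_significant, x$alpha,
    g$n_biopsy_higher, g$n_plucked_higher, x$dispersion
  ))
  invisible(x)
}

#' @rdname run_contrast
#' @param x A `de_result`.
#' @param ... Unused.
#' @export
tidy.de_result <- function(x, ...) x$table

#' @rdname run_contrast
#' @export
glance.de_result <- function(x, ...) {
  tibble(
    contrast = x$contrast,
    n_plucked = x$n_plucked,
    n_biopsy = x$n_biopsy,
    n_genes = nrow(x$table),
    n_significant = sum(x$table$significant),
    n_biopsy_higher = sum(x$table$direction == "biopsy_higher"),
    n_plucked_higher = sum(x$table$direction == "plucked_higher"),
    common_dispersion = x$dispersion,
    alpha = x$alpha
  )
}
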