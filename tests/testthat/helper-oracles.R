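# Independent straight-line oracles, written before the implementations they
# check and kept deliberately naive: explicit loops, sort-based trimming, no
# shared code with the package internals.

# Weighted doubly-trimmed mean-of-M-values factor for one sample against a
# reference, spelled out step by step.
oracle_tmm_factor <- function(obs, ref, n_obs, n_ref, trim_m = 0.30, trim_a = 0.05) {
  keep_genes <- which(obs > 0 & ref > 0)
  m <- a <- w <- numeric(0)
  for (g in keep_genes) {
    po <- obs[g] / n_obs
    pr <- ref[g] / n_ref
    m <- c(m, log2(po / pr))
    a <- c(a, 0.5 * log2(po * pr))
    w <- c(w, 1 / ((n_obs - obs[g]) / (n_obs * obs[g]) +
                     (n_ref - ref[g]) / (n_ref * ref[g])))
  }
  n <- length(m)
  if (n == 0) return(1)
  # average ranks computed by explicit counting
  avg_rank <- function(x) {
    r <- numeric(length(x))
    for (i in seq_along(x)) {
      n_less <- sum(x < x[i])
      n_tied <- sum(x == x[i])
      r[i] <- n_less + (n_tied + 1) / 2
    }
    r
  }
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- avg_rank(m)
  ra_ <- avg_rank(a)
  kept <- which(rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a)
  if (length(kept) < 10) return(1)
  2^(sum(w[kept] * m[kept]) / sum(w[kept]))
}

# Full oracle: factors for every column against a fixed reference column,
# rescaled to geometric mean 1.
oracle_tmm_factors <- function(mat, lib_sizes, ref_col, trim_m = 0.30, trim_a = 0.05) {
  f <- numeric(ncol(mat))
  for (k in seq_len(ncol(mat))) {
    f[k] <- if (k == ref_col) 1 else {
      oracle_tmm_factor(mat[, k], mat[, ref_col], lib_sizes[k], lib_sizes[ref_col],
                        trim_m, trim_a)
    }
  }
  f / exp(mean(log(f)))
}

# Exact conditional test at dispersion 0: enumerate the binomial law of the
# group-A sum given the total and sum the probabilities of all splits no more
# likely than the observed one.
oracle_binomial_exact <- function(s_a, s_b, n_a, n_b) {
  t <- s_a + s_b
  if (t == 0) return(1)
  pr <- n_a / (n_a + n_b)
  probs <- numeric(t + 1)
  for (x in 0:t) probs[x + 1] <- dbinom(x, t, pr)
  p_obs <- probs[s_a + 1]
  total <- 0
  for (x in 0:t) {
    if (probs[x + 1] <= p_obs * (1 + 1e-8)) total <- total + probs[x + 1]
  }
  min(1, total)
}

# Literal step-up definition: adjusted p for rank i is the smallest
# min(1, m*p_(j)/j) over j >= i.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, min(1, m * sorted[j] / j))
    adj_sorted[i] <- min(vals)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Per-gene brute-force region classifier for the Venn partition.
oracle_venn_region <- function(gene, se, ss, re, rs) {
  in_se <- gene %in% se
  in_re <- gene %in% re
  in_ss <- gene %in% ss
  in_rs <- gene %in% rs
  if (in_se && !in_re) {
    if (in_ss) "study_only_sig" else "study_only_nonsig"
  } else if (!in_se && in_re) {
    if (in_rs) "ref_only_sig" else "ref_only_nonsig"
  } else {
    if (in_ss && in_rs) "both_expr_sig_both"
    else if (in_ss) "both_expr_sig_study_only"
    else if (in_rs) "both_expr_sig_ref_only"
    else "both_nonsig"
  }
}
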