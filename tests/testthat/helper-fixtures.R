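# Small fixtures used across test files.

# deterministic random expression matrix
random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples, 6, 2), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  x
}

# small synthetic cohort (fast defaults for unit tests)
small_cohort <- function(seed = 1, n_samples = 160, n_genes = 500,
                         markers = 20) {
  simulate_cohort(cohort_spec(n_samples = n_samples, n_genes = n_genes,
                              markers_per_subtype = markers, seed = seed))
}

# strictly increasing random warp applied to one sample (column) vector
random_monotone_warp <- function(v, seed) {
  set.seed(seed)
  fns <- list(
    function(z) exp(z / max(abs(z) + 1)),
    function(z) z^3 + 2 * z,
    function(z) runif(1, 0.5, 3) * z + rnorm(1),
    function(z) (z - min(z) + 1)^runif(1, 0.5, 2),
    function(z) log(z - min(z) + 1) + runif(1) * z
  )
  fns[[sample.int(length(fns), 1L)]](v)
}

# brute-force two-sided Fisher p by enumerating all tables with the observed
# margins, using choose() products (independent of the dhyper-based path)
fisher_p_enum <- function(f11, f12, f21, f22) {
  m1 <- f11 + f12; m2 <- f21 + f22; c1 <- f11 + f21
  t <- m1 + m2
  ks <- max(0, c1 - m2):min(c1, m1)
  probs <- choose(m1, ks) * choose(m2, c1 - ks) / choose(t, c1)
  p_obs <- probs[ks == f11]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random valid 2x2 contingency table with total <= max_t
random_table <- function(max_t = 40) {
  repeat {
    f <- as.integer(rmultinom(1, sample(4:max_t, 1), rep(0.25, 4)))
    if (f[1] + f[2] > 0 && f[3] + f[4] > 0) return(f)
  }
}

# naive nearest-centroid classifier on absolute expression
naive_centroid <- function(x_train, labels_train, x_test) {
  classes <- unique(labels_train)
  cent <- vapply(classes, function(s) {
    rowMeans(x_train[, labels_train == s, drop = FALSE])
  }, numeric(nrow(x_train)))
  d <- vapply(seq_len(ncol(x_test)), function(k) {
    colSums((x_test[, k] - cent)^2)
  }, numeric(length(classes)))
  classes[apply(d, 2L, which.min)]
}
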