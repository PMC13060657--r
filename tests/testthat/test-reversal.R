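test_that("enumerate_pairs produces all unordered pairs deterministically", {
  p <- enumerate_pairs(c("b", "a", "c"))
  expect_equal(nrow(p), 3)
  expect_identical(p[1, ], c(gene_i = "a", gene_j = "b"))
  expect_identical(p[3, ], c(gene_i = "b", gene_j = "c"))
  expect_equal(nrow(enumerate_pairs(c("x", "y"))), 1)
  expect_error(enumerate_pairs("x"), ">= 2")
  expect_error(enumerate_pairs(c("x", "x")), "duplicate")
  # published signature sizes map to their candidate pair counts
  expect_equal(nrow(enumerate_pairs(sprintf("g%03d", 1:710))), 251695)
  expect_equal(nrow(enumerate_pairs(sprintf("g%03d", 1:346))), 59685)
})

test_that("ger_indicator follows the strict-greater rule with ties as 0", {
  expect_identical(ger_indicator(5, 3), 1L)
  expect_identical(ger_indicator(3, 5), 0L)
  expect_identical(ger_indicator(2.5, 2.5), 0L)
  # complement identity: sums to 1 unless tied, 0 when tied
  set.seed(1)
  a <- sample(10, 50, replace = TRUE); b <- sample(10, 50, replace = TRUE)
  s <- ger_indicator(a, b) + ger_indicator(b, a)
  expect_true(all(s[a != b] == 1L))
  expect_true(all(s[a == b] == 0L))
})

test_that("reversal_ratio matches the defining formula and complements", {
  expect_equal(reversal_ratio(10, 0, 0, 10), 1.0)
  expect_equal(reversal_ratio(5, 5, 5, 5), 0.5)
  expect_equal(reversal_ratio(90, 10, 5, 95), 0.925)
  expect_error(reversal_ratio(0, 0, 0, 0), "empty")
  # orientation complement: flipping the indicator columns sums to 1 exactly
  set.seed(2)
  for (i in 1:50) {
    f <- random_table()
    expect_identical(reversal_ratio(f[1], f[2], f[3], f[4]) +
                       reversal_ratio(f[2], f[1], f[4], f[3]), 1)
  }
})

test_that("fisher_p reproduces hand-enumerated and analytic values", {
  expect_equal(fisher_p(1, 1, 1, 1), 1.0)
  expect_equal(fisher_p(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_p(10, 0, 0, 10), 2 / choose(20, 10), tolerance = 1e-12)
  # vectorised call agrees with scalar calls
  expect_equal(fisher_p(c(1, 3, 10), c(1, 1, 0), c(1, 1, 0), c(1, 3, 10)),
               c(1.0, 34 / 70, 2 / choose(20, 10)), tolerance = 1e-12)
})

test_that("fisher_p equals brute-force enumeration and fisher.test", {
  set.seed(7)
  for (i in 1:300) {
    f <- random_table(40)
    p <- fisher_p(f[1], f[2], f[3], f[4])
    expect_lt(abs(p - fisher_p_enum(f[1], f[2], f[3], f[4])), 1e-12)
    ft <- fisher.test(matrix(f, 2, byrow = TRUE))$p.value
    expect_equal(p, ft, tolerance = 1e-9)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("screen_gers retains planted pairs with consistent orientation", {
  co <- small_cohort(seed = 4, n_samples = 160, n_genes = 500, markers = 20)
  ranks <- rank_transform(co$x)
  s <- "SHH"
  genes <- unlist(co$truth$markers[[s]])
  res <- screen_gers(ranks, co$labels, s, genes)
  expect_gt(nrow(res), 0)
  # retained features recomputed by an independent brute-force pass
  others <- setdiff(unique(co$labels), s)
  th <- reversal_thresholds(subtype_set(co$labels))
  for (k in seq_len(min(nrow(res), 25))) {
    hi <- res$gene_hi[k]; lo <- res$gene_lo[k]
    ind <- as.integer(ranks[hi, ] > ranks[lo, ])
    for (o in others) {
      f11 <- sum(ind[co$labels == s]); f12 <- sum(co$labels == s) - f11
      f21 <- sum(ind[co$labels == o]); f22 <- sum(co$labels == o) - f21
      rr <- (f11 + f22) / (f11 + f12 + f21 + f22)
      expect_gte(rr, th[s, o])
      expect_lt(fisher.test(matrix(c(f11, f12, f21, f22), 2,
                                   byrow = TRUE))$p.value, 0.05)
      expect_equal(res[[paste0("ratio_", o)]][k], rr, tolerance = 1e-12)
    }
  }
  # planted orientation: up-marker outranks down-marker in the subtype
  planted <- co$truth$pairs[[s]]
  key <- paste(res$gene_hi, res$gene_lo)
  expect_gt(sum(paste(planted$gene_hi, planted$gene_lo) %in% key), 0)
  expect_equal(sum(paste(planted$gene_lo, planted$gene_hi) %in% key), 0)
})

test_that("a pair failing any single comparison is discarded", {
  # two subtype-like groups plus two more; pair separates S from A and B
  # perfectly but is uninformative against C
  set.seed(11)
  n_per <- 10
  labels <- setNames(rep(c("S", "A", "B", "C"), each = n_per),
                     sprintf("s%02d", 1:(4 * n_per)))
  x <- random_expr(30, 4 * n_per, seed = 12)
  colnames(x) <- names(labels)
  # g001 > g002 in all S samples; reversed in A and B; half-half in C
  x["g001", ] <- 1; x["g002", ] <- 2
  x["g001", labels == "S"] <- 2; x["g002", labels == "S"] <- 1
  cidx <- which(labels == "C")[1:(n_per / 2)]
  x["g001", cidx] <- 3
  ranks <- rank_transform(x)
  th <- reversal_thresholds(c("S", "A", "B", "C"), default = 0.9)
  res <- screen_gers(ranks, labels, "S", c("g001", "g002"), thresholds = th)
  expect_equal(nrow(res), 0)
  # relaxing the failing comparison admits the pair (monotone in thresholds)
  th2 <- th; th2["S", "C"] <- 0.51
  res2 <- screen_gers(ranks, labels, "S", c("g001", "g002"),
                      thresholds = th2)
  expect_equal(nrow(res2), 1)
  expect_identical(res2$gene_hi, "g001")
})

test_that("raising thresholds never enlarges the screened set", {
  co <- small_cohort(seed = 6, n_samples = 120, n_genes = 400, markers = 20)
  ranks <- rank_transform(co$x)
  genes <- unlist(co$truth$markers[["Group3"]])
  subtypes <- subtype_set(co$labels)
  pair_key <- function(res) paste(res$gene_hi, res$gene_lo)
  prev <- NULL
  for (d in c(0.8, 0.9, 0.95)) {
    th <- reversal_thresholds(subtypes)
    th[!is.na(th)] <- d
    res <- suppressWarnings(
      screen_gers(ranks, co$labels, "Group3", genes, thresholds = th))
    if (!is.null(prev)) expect_true(all(pair_key(res) %in% prev))
    prev <- pair_key(res)
  }
})

test_that("screening output is invariant to per-sample monotone distortion", {
  co <- small_cohort(seed = 8, n_samples = 100, n_genes = 400, markers = 16)
  genes <- unlist(co$truth$markers[["Group4"]])
  xw <- co$x
  for (j in seq_len(ncol(xw))) xw[, j] <- random_monotone_warp(xw[, j], j)
  r1 <- screen_gers(rank_transform(co$x), co$labels, "Group4", genes)
  r2 <- screen_gers(rank_transform(xw), co$labels, "Group4", genes)
  expect_identical(r1, r2)
})

test_that("chunked iteration equals full enumeration", {
  co <- small_cohort(seed = 10, n_samples = 100, n_genes = 400, markers = 16)
  ranks <- rank_transform(co$x)
  genes <- unlist(co$truth$markers[["WNT"]])
  full <- screen_gers(ranks, co$labels, "WNT", genes)
  chunked <- screen_gers(ranks, co$labels, "WNT", genes, chunk_size = 7L)
  expect_identical(full, chunked)
})
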