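make_scores <- function(scores, subtypes, pred = NULL) {
  pred <- pred %||% subtypes[apply(scores, 1, which.max)]
  structure(list(scores = scores,
                 prediction = setNames(pred, rownames(scores)),
                 tie = setNames(rep(FALSE, nrow(scores)), rownames(scores)),
                 subtypes = subtypes),
            class = "ger_scores")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("perfect predictions give all-1 metrics", {
  subtypes <- c("A", "B")
  sc <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), subtypes))
  r <- make_scores(sc, subtypes)
  m <- compute_metrics(c(s1 = "A", s2 = "B"), r)
  expect_equal(m$overall_accuracy, 1)
  expect_true(all(m$per_subtype == 1))
})

test_that("hand-computed one-vs-rest table values are reproduced", {
  # TP=8, FP=2, FN=2, TN=88
  subtypes <- c("P", "N")
  truth <- c(rep("P", 10), rep("N", 90))
  pred <- truth
  pred[1:2] <- "N"            # 2 FN
  pred[11:12] <- "P"          # 2 FP
  ids <- sprintf("s%03d", 1:100)
  sc <- matrix(runif(200), 100, 2, dimnames = list(ids, subtypes))
  r <- make_scores(sc, subtypes, pred = pred)
  m <- compute_metrics(setNames(truth, ids), r)
  expect_equal(unname(m$per_subtype["P", "precision"]), 0.8)
  expect_equal(unname(m$per_subtype["P", "sensitivity"]), 0.8)
  expect_equal(unname(m$per_subtype["P", "jaccard"]), 8 / 12)
  expect_equal(unname(m$per_subtype["P", "mcc"]), 700 / 900)
  expect_equal(unname(m$per_subtype["P", "gmeasure"]), 0.8)
  expect_equal(unname(m$per_subtype["P", "f1"]), 0.8)
  expect_equal(unname(m$per_subtype["P", "accuracy"]), 0.96)
})

test_that("metric identities hold on random confusion outcomes", {
  set.seed(55)
  subtypes <- c("A", "B", "C")
  for (i in 1:200) {
    n <- sample(20:60, 1)
    ids <- sprintf("s%02d", seq_len(n))
    truth <- sample(subtypes, n, replace = TRUE)
    pred <- sample(subtypes, n, replace = TRUE)
    sc <- matrix(runif(3 * n), n, 3, dimnames = list(ids, subtypes))
    m <- suppressWarnings(
      compute_metrics(setNames(truth, ids), make_scores(sc, subtypes, pred)))
    expect_equal(sum(m$confusion), n)
    expect_equal(m$overall_accuracy, sum(diag(m$confusion)) / n)
    for (s in subtypes) {
      tp <- sum(truth == s & pred == s); fp <- sum(truth != s & pred == s)
      fn <- sum(truth == s & pred != s); tn <- sum(truth != s & pred != s)
      pm <- m$per_subtype[s, ]
      if (!any(truth == s)) { expect_true(all(is.na(pm))); next }
      pr <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      se <- tp / (tp + fn)
      expect_equal(unname(pm["precision"]), pr)
      expect_equal(unname(pm["f1"]),
                   if (is.na(pr) || pr + se == 0) NA_real_ else
                     2 * pr * se / (pr + se))
      expect_equal(unname(pm["gmeasure"]), sqrt(pr * se))
      expect_equal(unname(pm["jaccard"]), tp / (tp + fp + fn))
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den > 0) {
        expect_equal(unname(pm["mcc"]), (tp * tn - fp * fn) / den)
      }
    }
  }
})

test_that("midrank AUC equals the exhaustive pair-counting oracle", {
  set.seed(56)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    score <- sample(seq_len(10), n, replace = TRUE) / 10  # force ties
    auc <- gersub:::midrank_auc(score, pos)
    # oracle: fraction of (pos, neg) pairs ordered correctly, ties 1/2
    sp <- score[pos]; sn <- score[!pos]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
  }
  # all-identical scores: AUC 0.5 by the midrank convention
  expect_equal(gersub:::midrank_auc(rep(0.3, 40), rep(c(TRUE, FALSE), 20)),
               0.5)
})

test_that("a subtype absent from truth yields NA metrics with a warning", {
  subtypes <- c("A", "B", "C")
  ids <- c("s1", "s2")
  sc <- matrix(c(0.9, 0.1, 0, 0.2, 0.8, 0), 2, byrow = TRUE,
               dimnames = list(ids, subtypes))
  r <- make_scores(sc, subtypes)
  expect_warning(m <- compute_metrics(c(s1 = "A", s2 = "B"), r),
                 "absent from truth")
  expect_true(all(is.na(m$per_subtype["C", ])))
})

test_that("visualization matrix concatenates scores with a one-hot block", {
  subtypes <- c("A", "B", "C", "D")
  sc <- matrix(c(0.9, 0.1, 0.2, 0.3,
                 0.2, 0.6, 0.6, 0.1), 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), subtypes))
  r <- make_scores(sc, subtypes)
  v <- visualization_matrix(r)
  expect_equal(dim(v), c(2, 8))
  expect_equal(unname(v["s1", ]), c(0.9, 0.1, 0.2, 0.3, 1, 0, 0, 0))
  expect_equal(unname(rowSums(v[, 5:8])), c(1, 1))   # one-hot sums to 1
  # tie resolved by subtype order: s2 tie between B and C -> B
  expect_equal(unname(v["s2", 5:8]), c(0, 1, 0, 0))
})

test_that("embedding is seeded-deterministic and separates planted clusters", {
  set.seed(60)
  n <- 60
  m <- rbind(matrix(rnorm(n * 4, 0, 0.05), n, 4),
             matrix(rnorm(n * 4, 2, 0.05), n, 4))
  rownames(m) <- sprintf("s%03d", seq_len(2 * n))
  c1 <- embed_2d(m, perplexity = 10, seed = 4)
  c2 <- embed_2d(m, perplexity = 10, seed = 4)
  expect_identical(c1, c2)
  expect_true(all(is.finite(c1)))
  grp <- rep(1:2, each = n)
  sil <- cluster::silhouette(grp, dist(c1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  expect_error(embed_2d(m[1:10, ], perplexity = 10), "too few samples")
  expect_error(embed_2d(matrix(1, 100, 4), perplexity = 5), "constant")
})
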