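#' Intrasample rank transform
#'
#' Converts absolute expression to within-sample ascending ranks: in every
#' sample (column) the lowest-expressed gene gets rank 1 and the highest gets
#' rank n. Ties receive the mean of the positions they span, so every column
#' sums to n(n+1)/2 exactly. Ranks are invariant under any strictly
#' increasing per-sample transformation, which is what makes everything
#' downstream robust to sample-level batch distortion.
#'
#' @param x Numeric genes x samples matrix (>= 2 genes).
#' @return Matrix of ranks, same shape and dimnames.
#' @export
rank_transform <- function(x) {
  check_expression_matrix(x)
  if (nrow(x) < 2L) {
    stop("rank transform needs >= 2 genes (no gene pairs otherwise)",
         call. = FALSE)
  }
  r <- apply(x, 2L, rank, ties.method = "average")
  dimnames(r) <- dimnames(x)
  r
}

#' Differentially ranked genes between two subtypes
#'
#' For each gene, compares its mean intrasample rank in subtype `a` against
#' subtype `b`. A gene is called "up" in `a` when the mean-rank difference
#' exceeds `round(rank_frac * n)` rank positions (n = number of genes) with a
#' two-sided Welch t-test p below `alpha`, and "down" symmetrically. The
#' default `rank_frac = 0.11` makes the rank-difference cut 11% of the gene
#' count on any platform.
#'
#' @param ranks Rank matrix from [rank_transform()].
#' @param labels Named character vector, sample -> subtype.
#' @param a,b Subtype names; the difference is mean rank in `a` minus mean
#'   rank in `b`.
#' @param rank_frac Rank-difference threshold as a fraction of the gene
#'   count, in (0, 1).
#' @param alpha t-test significance level.
#' @param var_equal Use pooled-variance t-test instead of Welch.
#' @return Object of class `"diff_rank"`: a list with the comparison, the
#'   per-gene `difference` and `p` vectors, the threshold used, and the
#'   `up_genes` / `down_genes` character vectors.
#' @export
diff_rank_genes <- function(ranks, labels, a, b, rank_frac = 0.11,
                            alpha = 0.05, var_equal = FALSE) {
  labels <- check_labels(ranks, labels)
  if (rank_frac <= 0 || rank_frac >= 1) stop("rank_frac must be in (0, 1)",
                                             call. = FALSE)
  n <- nrow(ranks)
  threshold <- round(rank_frac * n)
  if (threshold < 1) stop("rank_frac * n < 1: threshold degenerate",
                          call. = FALSE)
  ra <- ranks[, labels == a, drop = FALSE]
  rb <- ranks[, labels == b, drop = FALSE]
  na <- ncol(ra); nb <- ncol(rb)
  if (na < 2L || nb < 2L) {
    stop("both subtypes need >= 2 samples for the t-test (", a, ": ", na,
         ", ", b, ": ", nb, ")", call. = FALSE)
  }
  ma <- rowMeans(ra); mb <- rowMeans(rb)
  va <- rowSums((ra - ma)^2) / (na - 1L)
  vb <- rowSums((rb - mb)^2) / (nb - 1L)
  difference <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep.int(na + nb - 2L, n)
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  }
  tstat <- difference / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # identical rank vectors in both groups: no evidence either way
  p[!is.finite(tstat)] <- 1
  names(difference) <- names(p) <- rownames(ranks)
  up <- rownames(ranks)[difference > threshold & p < alpha]
  down <- rownames(ranks)[difference < -threshold & p < alpha]
  structure(list(comparison = c(a, b), difference = difference, p = p,
                 threshold = threshold, alpha = alpha,
                 up_genes = up, down_genes = down),
            class = "diff_rank")
}

#' @method print diff_rank
#' @export
print.diff_rank <- function(x, ...) {
  cat("Differential rank comparison:", x$comparison[1L], "vs",
      x$comparison[2L], "\n")
  cat("  rank-difference threshold:", x$threshold, " alpha:", x$alpha, "\n")
  cat("  up:", length(x$up_genes), " down:", length(x$down_genes), "genes\n")
  invisible(x)
}

#' Subtype signature genes from three pairwise comparisons
#'
#' A gene belongs to subtype S's signature when it is consistently up (or
#' consistently down) in S against each of the other three subtypes: the
#' up-sets of the three comparisons are intersected, the down-sets are
#' intersected, and the two intersections are unioned.
#'
#' @param results List of exactly `n_comparisons` [diff_rank_genes()]
#'   results, each oriented with `subtype` first.
#' @param subtype The selected subtype S.
#' @param n_comparisons Expected number of comparisons (3 for the four
#'   consensus subgroups).
#' @return Character vector of signature gene IDs.
#' @export
subtype_signature_genes <- function(results, subtype, n_comparisons = 3L) {
  if (length(results) != n_comparisons) {
    stop("expected ", n_comparisons, " comparisons, got ", length(results),
         call. = FALSE)
  }
  ok <- vapply(results, function(r) inherits(r, "diff_rank") &&
                 r$comparison[1L] == subtype, logical(1L))
  if (!all(ok)) {
    stop("every comparison must be a diff_rank result oriented with '",
         subtype, "' first", call. = FALSE)
  }
  others <- vapply(results, function(r) r$comparison[2L], character(1L))
  if (anyDuplicated(others) || subtype %in% others) {
    stop("comparisons must be against distinct other subtypes", call. = FALSE)
  }
  up <- Reduce(intersect, lapply(results, `[[`, "up_genes"))
  down <- Reduce(intersect, lapply(results, `[[`, "down_genes"))
  union(up, down)
}
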