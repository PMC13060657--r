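#' One-vs-rest classification metrics
#'
#' Evaluates hard predictions and continuous subtype scores against true
#' labels. For each subtype S the other classes are collapsed into a single
#' negative class and nine metrics are computed from the resulting 2x2
#' confusion counts: accuracy, precision, sensitivity, specificity, AUC,
#' Jaccard index, Matthews correlation coefficient, G-measure (geometric mean
#' of precision and sensitivity) and F1. AUC uses S's continuous score as the
#' discriminant with the midrank (Mann-Whitney) convention for ties.
#' Metrics with a zero denominator are reported as `NA` with a warning, never
#' silently as 0.
#'
#' @param truth Named character vector of true subtypes (or unnamed in the
#'   score matrix's row order).
#' @param result A `"ger_scores"` object from [predict.ger_model()].
#' @return Object of class `"ger_metrics"`: list with `per_subtype`
#'   (subtypes x 9 metric matrix), `overall_accuracy`, and `confusion`
#'   (true x predicted counts).
#' @export
compute_metrics <- function(truth, result) {
  stopifnot(inherits(result, "ger_scores"))
  ids <- rownames(result$scores)
  if (is.null(names(truth))) {
    if (length(truth) != length(ids)) {
      stop("unnamed truth must match the number of scored samples",
           call. = FALSE)
    }
    names(truth) <- ids
  }
  if (!all(ids %in% names(truth))) {
    stop("truth is missing samples: ",
         paste(setdiff(ids, names(truth)), collapse = ", "), call. = FALSE)
  }
  truth <- as.character(truth[ids])
  subtypes <- result$subtypes
  pred <- result$prediction[ids]
  confusion <- table(factor(truth, levels = subtypes),
                     factor(pred, levels = subtypes), dnn = c("true", "pred"))
  total <- length(ids)
  metric_names <- c("accuracy", "precision", "sensitivity", "specificity",
                    "auc", "jaccard", "mcc", "gmeasure", "f1")
  per <- matrix(NA_real_, length(subtypes), length(metric_names),
                dimnames = list(subtypes, metric_names))
  for (s in subtypes) {
    pos <- truth == s
    if (!any(pos)) {
      warning("subtype '", s, "' absent from truth; its one-vs-rest metrics ",
              "are undefined", call. = FALSE)
      next
    }
    pp <- pred == s
    tp <- sum(pos & pp); fp <- sum(!pos & pp)
    fn <- sum(pos & !pp); tn <- sum(!pos & !pp)
    per[s, "accuracy"] <- (tp + tn) / total
    per[s, "precision"] <- safe_div(tp, tp + fp, paste0("precision(", s, ")"))
    per[s, "sensitivity"] <- safe_div(tp, tp + fn,
                                      paste0("sensitivity(", s, ")"))
    per[s, "specificity"] <- safe_div(tn, tn + fp,
                                      paste0("specificity(", s, ")"))
    per[s, "jaccard"] <- safe_div(tp, tp + fp + fn,
                                  paste0("jaccard(", s, ")"))
    mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    per[s, "mcc"] <- if (mcc_den == 0) {
      warning("mcc(", s, ") undefined (zero denominator)", call. = FALSE)
      NA_real_
    } else {
      (tp * tn - fp * fn) / mcc_den
    }
    pr <- per[s, "precision"]; se <- per[s, "sensitivity"]
    per[s, "gmeasure"] <- sqrt(pr * se)
    per[s, "f1"] <- if (is.na(pr) || is.na(se) || pr + se == 0) {
      warning("f1(", s, ") undefined", call. = FALSE)
      NA_real_
    } else {
      2 * pr * se / (pr + se)
    }
    per[s, "auc"] <- midrank_auc(result$scores[, s], pos)
  }
  structure(list(per_subtype = per,
                 overall_accuracy = sum(diag(confusion)) / total,
                 confusion = confusion),
            class = "ger_metrics")
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator)", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

# Mann-Whitney AUC with midranks for tied scores.
midrank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  if (anyNA(score)) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @method print ger_metrics
#' @export
print.ger_metrics <- function(x, digits = 3L, ...) {
  cat("Overall accuracy:", format(x$overall_accuracy, digits = digits), "\n")
  cat("\nOne-vs-rest metrics:\n")
  print(round(x$per_subtype, digits))
  cat("\nConfusion matrix (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
as.data.frame.ger_metrics <- function(x, ...) {
  data.frame(subtype = rownames(x$per_subtype), x$per_subtype,
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Score + one-hot visualization matrix
#'
#' Concatenates, per sample, the continuous subtype scores with a one-hot
#' encoding of the predicted subtype (highest score, ties resolved by the
#' model's subtype order), giving a samples x 2C matrix that carries both
#' prediction confidence and categorical identity into the 2-D embedding.
#'
#' @param result A `"ger_scores"` object.
#' @return Numeric samples x (2 x subtypes) matrix.
#' @export
visualization_matrix <- function(result) {
  stopifnot(inherits(result, "ger_scores"))
  sc <- result$scores
  sc[is.na(sc)] <- 0
  onehot <- matrix(0, nrow(sc), ncol(sc),
                   dimnames = list(rownames(sc),
                                   paste0("pred_", colnames(sc))))
  onehot[cbind(seq_len(nrow(sc)),
               match(result$prediction, result$subtypes))] <- 1
  colnames(sc) <- paste0("score_", colnames(sc))
  cbind(sc, onehot)
}

#' 2-D embedding of the visualization matrix
#'
#' Seeded t-SNE wrapper over the score + one-hot matrix, used to display
#' subtype separation free of batch structure.
#'
#' @param m Numeric samples x features matrix (from
#'   [visualization_matrix()]).
#' @param perplexity t-SNE perplexity; needs `3 * perplexity + 1 <= nrow(m)`.
#' @param seed Integer seed; fixed seed gives identical coordinates.
#' @param ... Passed to [Rtsne::Rtsne()].
#' @return Samples x 2 coordinate matrix (columns `tsne1`, `tsne2`).
#' @export
embed_2d <- function(m, perplexity = 30, seed = 1L, ...) {
  m <- as.matrix(m)
  if (nrow(m) < 3 * perplexity + 1) {
    stop("too few samples for perplexity ", perplexity,
         "; reduce it to at most ", floor((nrow(m) - 1) / 3), call. = FALSE)
  }
  if (all(abs(sweep(m, 2L, m[1L, ])) < .Machine$double.eps)) {
    stop("input matrix is constant; embedding is degenerate", call. = FALSE)
  }
  fit <- with_seed(seed, Rtsne::Rtsne(m, dims = 2L, perplexity = perplexity,
                                      check_duplicates = FALSE, pca = FALSE,
                                      ...))
  coords <- fit$Y
  dimnames(coords) <- list(rownames(m), c("tsne1", "tsne2"))
  coords
}

#' Scatter plot of predicted-subtype scores in the 2-D embedding
#'
#' @param x A `"ger_scores"` object.
#' @param color_by Optional named vector (e.g. batch or true subtype) used to
#'   colour points; defaults to the predicted subtype.
#' @param perplexity,seed Passed to [embed_2d()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ger_scores <- function(x, color_by = NULL, perplexity = 30, seed = 1L,
                            ...) {
  coords <- embed_2d(visualization_matrix(x), perplexity = perplexity,
                     seed = seed)
  grp <- if (is.null(color_by)) x$prediction else
    as.character(color_by[rownames(coords)])
  lev <- unique(grp)
  graphics::plot(coords, col = match(grp, lev), pch = 19,
                 xlab = "tsne1", ylab = "tsne2", ...)
  graphics::legend("topright", legend = lev, col = seq_along(lev), pch = 19,
                   cex = 0.8)
  invisible(coords)
}
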