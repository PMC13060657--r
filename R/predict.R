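#' Score samples and assign subtypes
#'
#' Applies a fitted model to new expression data in three stages: (a) restrict
#' the matrix to the model's gene universe and recompute intrasample ranks
#' within it, (b) evaluate every retained gene-pair indicator and average them
#' per subtype, (c) assign each sample the subtype with the highest mean
#' score, breaking exact ties by the model's fixed subtype order (flagged).
#'
#' Ranking within the model's gene universe (default) makes prediction
#' independent of the platform's full gene complement; `rank_within = "all"`
#' ranks over every supplied gene instead for sensitivity analyses — the two
#' modes give identical scores because indicators only compare genes inside
#' the universe, but the option keeps the behaviour explicit.
#'
#' Genes missing from `newdata` are tolerated per subtype up to
#' `max_missing` of that subtype's features (affected features are skipped
#' with a message); beyond that the prediction aborts naming the missing
#' genes.
#'
#' @param object A fitted `"ger_model"`.
#' @param newdata Numeric genes x samples matrix.
#' @param rank_within `"model"` (default) or `"all"`, see Details.
#' @param max_missing Maximum tolerated fraction of a subtype's features
#'   hitting missing genes (default 0.05).
#' @param ... Unused.
#' @return Object of class `"ger_scores"`: list with `scores` (samples x
#'   subtypes matrix of mean indicators in `[0, 1]`), `prediction` (named
#'   character vector), `tie` (logical flags), and `subtypes`.
#' @export
predict.ger_model <- function(object, newdata, rank_within = c("model", "all"),
                              max_missing = 0.05, ...) {
  rank_within <- match.arg(rank_within)
  check_expression_matrix(newdata)
  if (!length(object$gene_universe)) {
    stop("model has no features; cannot predict", call. = FALSE)
  }
  present <- intersect(object$gene_universe, rownames(newdata))
  missing <- setdiff(object$gene_universe, rownames(newdata))

  # per-subtype feature availability
  features <- lapply(object$subtypes, function(s) {
    f <- object$features[[s]]
    if (!nrow(f)) return(f)
    ok <- f$gene_hi %in% present & f$gene_lo %in% present
    if (!all(ok)) {
      frac <- mean(!ok)
      if (frac > max_missing) {
        bad <- setdiff(unique(c(f$gene_hi[!ok], f$gene_lo[!ok])), present)
        stop(sprintf(
          "%.0f%% of subtype '%s' features hit genes absent from newdata (limit %.0f%%): %s",
          100 * frac, s, 100 * max_missing, paste(bad, collapse = ", ")),
          call. = FALSE)
      }
      message("subtype '", s, "': skipping ", sum(!ok),
              " feature(s) with missing genes")
      f <- f[ok, , drop = FALSE]
    }
    f
  })
  names(features) <- object$subtypes

  ranks <- if (rank_within == "model") {
    rank_transform(newdata[present, , drop = FALSE])
  } else {
    rank_transform(newdata)[present, , drop = FALSE]
  }

  scores <- matrix(NA_real_, ncol(newdata), length(object$subtypes),
                   dimnames = list(colnames(newdata), object$subtypes))
  for (s in object$subtypes) {
    f <- features[[s]]
    if (!nrow(f)) {
      warning("subtype '", s, "' has no features; it is never predicted",
              call. = FALSE)
      scores[, s] <- -Inf
      next
    }
    ind <- ranks[f$gene_hi, , drop = FALSE] > ranks[f$gene_lo, , drop = FALSE]
    scores[, s] <- colMeans(ind)
  }
  best <- apply(scores, 1L, max)
  tie <- rowSums(scores == best) > 1L
  # argmax with ties broken by the model's fixed subtype order
  pred <- object$subtypes[apply(scores, 1L, which.max)]
  scores[!is.finite(scores)] <- NA_real_
  structure(list(scores = scores,
                 prediction = stats::setNames(pred, colnames(newdata)),
                 tie = stats::setNames(tie, colnames(newdata)),
                 subtypes = object$subtypes),
            class = "ger_scores")
}

#' @method print ger_scores
#' @export
print.ger_scores <- function(x, ...) {
  cat("Subtype scores for", nrow(x$scores), "samples x",
      length(x$subtypes), "subtypes\n")
  tab <- table(factor(x$prediction, levels = x$subtypes))
  cat("  predictions:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  if (any(x$tie)) cat("  ties:", sum(x$tie), "sample(s)\n")
  invisible(x)
}

#' @export
as.data.frame.ger_scores <- function(x, ...) {
  data.frame(sample_id = rownames(x$scores),
             prediction = unname(x$prediction),
             x$scores,
             tie = unname(x$tie),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write predictions as TSV
#'
#' @param x A `"ger_scores"` object.
#' @param path Output path.
#' @export
write_predictions <- function(x, path) {
  stopifnot(inherits(x, "ger_scores"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
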