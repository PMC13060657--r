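#' Fit a rank-based gene-pair subtype classifier
#'
#' Trains the full pipeline on a labelled expression cohort:
#' \enumerate{
#'   \item intrasample rank transform ([rank_transform()]);
#'   \item differential rank screen between every subtype pair
#'     ([diff_rank_genes()]) and per-subtype signature genes
#'     ([subtype_signature_genes()]);
#'   \item gene-pair reversal screen against reversal-ratio thresholds and
#'     Fisher exact tests ([screen_gers()]);
#'   \item elastic-net logistic refinement, one run per (subtype, other)
#'     comparison, keeping for each subtype the pairs selected in all of its
#'     comparisons ([elastic_net_select()]).
#' }
#' Because every feature is a within-sample rank comparison, the fitted model
#' is invariant to any strictly increasing per-sample transformation of the
#' input — the property that makes it robust to cross-cohort batch effects.
#'
#' @param x Numeric genes x samples expression matrix (log-intensity or TPM;
#'   only within-sample ordering is used).
#' @param labels Named character vector, sample -> subtype, covering all
#'   columns of `x` (or unnamed, in column order).
#' @param subtypes Ordered subtype names; default the four consensus
#'   medulloblastoma subgroups when the labels match them, otherwise order of
#'   appearance. The order is recorded and used for deterministic
#'   tie-breaking at prediction time.
#' @param rank_frac Differential-rank threshold as a fraction of the gene
#'   count (default 0.11).
#' @param sig_alpha t-test significance level for the rank screen.
#' @param thresholds Reversal-ratio threshold matrix from
#'   [reversal_thresholds()].
#' @param fisher_alpha Fisher exact significance level for the pair screen.
#' @param enet [enet_control()] settings for the refinement stage.
#' @param seed Integer seed driving cross-validation fold assignment
#'   (overrides `enet$seed`).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param inclusive Reversal-ratio comparison is `>=` (default) or `>`.
#' @param verbose Print per-stage counts while fitting.
#' @return Object of class `"ger_model"`: a list with `subtypes`, `features`
#'   (per-subtype data.frames of oriented pairs with screening statistics and
#'   elastic-net coefficients), `gene_universe`, `config`, `provenance`, and
#'   per-stage accounting in `stages`.
#' @seealso [predict.ger_model()], [save_ger_model()], [simulate_cohort()]
#' @export
ger_fit <- function(x, labels, subtypes = NULL, rank_frac = 0.11,
                    sig_alpha = 0.05, thresholds = NULL, fisher_alpha = 0.05,
                    enet = enet_control(), seed = 1L, var_equal = FALSE,
                    inclusive = TRUE, verbose = FALSE) {
  check_expression_matrix(x)
  labels <- check_labels(x, labels)
  subtypes <- subtype_set(labels, subtypes)
  if (is.null(thresholds)) thresholds <- reversal_thresholds(subtypes)
  if (!all(subtypes %in% rownames(thresholds))) {
    stop("threshold matrix does not cover all subtypes", call. = FALSE)
  }
  counts <- table(factor(labels, levels = subtypes))
  if (any(counts < 2L)) {
    stop("every subtype needs >= 2 samples; short: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  enet$seed <- as.integer(seed)
  say <- function(...) if (verbose) message(...)

  ranks <- rank_transform(x)

  # stage 1: differential rank screen, one result per ordered subtype pair
  say("stage 1: differential rank screen")
  diff <- list()
  for (a in subtypes) for (b in setdiff(subtypes, a)) {
    key <- paste(a, b, sep = "|")
    rev_key <- paste(b, a, sep = "|")
    if (!is.null(diff[[rev_key]])) {
      r <- diff[[rev_key]]
      diff[[key]] <- structure(
        list(comparison = c(a, b), difference = -r$difference, p = r$p,
             threshold = r$threshold, alpha = r$alpha,
             up_genes = r$down_genes, down_genes = r$up_genes),
        class = "diff_rank")
    } else {
      diff[[key]] <- diff_rank_genes(ranks, labels, a, b,
                                     rank_frac = rank_frac,
                                     alpha = sig_alpha,
                                     var_equal = var_equal)
    }
  }
  signature <- lapply(subtypes, function(s) {
    res <- diff[paste(s, setdiff(subtypes, s), sep = "|")]
    subtype_signature_genes(res, s, n_comparisons = length(subtypes) - 1L)
  })
  names(signature) <- subtypes
  sig_counts <- lengths(signature)
  say("  signature genes: ",
      paste(subtypes, sig_counts, sep = "=", collapse = ", "))

  # stage 2: reversal screen over each subtype's signature-gene pairs
  say("stage 2: gene-pair reversal screen")
  screened <- lapply(subtypes, function(s) {
    if (length(signature[[s]]) < 2L) {
      warning("subtype '", s, "' has < 2 signature genes; no pairs screened",
              call. = FALSE)
      return(result_skeleton(s, setdiff(subtypes, s)))
    }
    screen_gers(ranks, labels, s, signature[[s]], thresholds = thresholds,
                alpha = fisher_alpha, inclusive = inclusive)
  })
  names(screened) <- subtypes
  pair_counts <- vapply(signature, function(g) {
    if (length(g) >= 2L) choose(length(g), 2L) else 0
  }, numeric(1L))
  screen_counts <- vapply(screened, nrow, integer(1L))
  say("  screened GERs: ",
      paste(subtypes, screen_counts, sep = "=", collapse = ", "))

  # stage 3: elastic-net refinement, one run per (subtype, other) comparison
  say("stage 3: elastic-net refinement")
  features <- list()
  run <- 0L
  for (s in subtypes) {
    sc <- screened[[s]]
    if (!nrow(sc)) {
      features[[s]] <- empty_feature_table(s)
      next
    }
    ind_all <- pair_indicator_matrix(ranks, sc)
    sel_sets <- list()
    coefs <- matrix(NA_real_, nrow(sc), length(subtypes) - 1L,
                    dimnames = list(NULL, setdiff(subtypes, s)))
    for (o in setdiff(subtypes, s)) {
      run <- run + 1L
      use <- labels %in% c(s, o)
      ctrl <- enet
      ctrl$seed <- enet$seed + run
      fit <- elastic_net_select(ind_all[use, , drop = FALSE],
                                labels[use] == s, control = ctrl)
      sel_sets[[o]] <- fit$index
      coefs[fit$index, o] <- fit$coef
    }
    keep <- sort(Reduce(intersect, sel_sets))
    if (!length(keep)) {
      warning("elastic-net intersection empty for subtype '", s, "'",
              call. = FALSE)
      features[[s]] <- empty_feature_table(s)
      next
    }
    ft <- sc[keep, , drop = FALSE]
    ft$coefficient <- rowMeans(coefs[keep, , drop = FALSE], na.rm = TRUE)
    rownames(ft) <- NULL
    features[[s]] <- ft
  }
  final_counts <- vapply(features, nrow, integer(1L))
  say("  final GERs: ",
      paste(subtypes, final_counts, sep = "=", collapse = ", "))

  gene_universe <- sort(unique(unlist(lapply(features, function(f) {
    c(f$gene_hi, f$gene_lo)
  }))))
  model <- structure(list(
    subtypes = subtypes,
    features = features,
    gene_universe = gene_universe,
    config = list(rank_frac = rank_frac, sig_alpha = sig_alpha,
                  thresholds = thresholds, fisher_alpha = fisher_alpha,
                  enet = enet, seed = as.integer(seed),
                  var_equal = var_equal, inclusive = inclusive),
    stages = list(signature_genes = sig_counts,
                  candidate_pairs = pair_counts,
                  screened_gers = screen_counts,
                  final_gers = final_counts,
                  unique_genes = length(gene_universe)),
    provenance = list(n_genes = nrow(x), n_samples = ncol(x),
                      label_counts = as.list(as.integer(counts)) |>
                        stats::setNames(subtypes))
  ), class = "ger_model")
  model
}

empty_feature_table <- function(subtype) {
  data.frame(subtype = character(), gene_hi = character(),
             gene_lo = character(), coefficient = numeric(),
             stringsAsFactors = FALSE)
}

#' @method print ger_model
#' @export
print.ger_model <- function(x, ...) {
  cat("Rank-based gene-pair subtype classifier\n")
  cat("  subtypes:", paste(x$subtypes, collapse = ", "), "\n")
  cat("  trained on", x$provenance$n_samples, "samples x",
      x$provenance$n_genes, "genes\n")
  cat("  features per subtype:",
      paste(x$subtypes, x$stages$final_gers, sep = "=", collapse = ", "),
      "\n")
  cat("  gene universe:", length(x$gene_universe), "unique genes\n")
  invisible(x)
}

#' @method summary ger_model
#' @export
summary.ger_model <- function(object, ...) {
  structure(list(model = object), class = "summary.ger_model")
}

#' @method print summary.ger_model
#' @export
print.summary.ger_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nPer-stage accounting:\n")
  tab <- rbind(`signature genes` = m$stages$signature_genes,
               `candidate pairs` = m$stages$candidate_pairs,
               `screened GERs` = m$stages$screened_gers,
               `final GERs` = m$stages$final_gers)
  colnames(tab) <- m$subtypes
  print(tab)
  cat("\nLabel counts:",
      paste(names(m$provenance$label_counts),
            unlist(m$provenance$label_counts), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Extract the fitted feature table
#'
#' @param object A `"ger_model"`.
#' @param ... Unused.
#' @return `data.frame` with one row per retained oriented gene pair:
#'   `subtype`, `gene_hi`, `gene_lo`, per-comparison screening statistics and
#'   the mean elastic-net `coefficient`.
#' @export
coef.ger_model <- function(object, ...) {
  out <- do.call(rbind, lapply(object$subtypes, function(s) {
    f <- object$features[[s]]
    if (!nrow(f)) return(NULL)
    f[, c("subtype", "gene_hi", "gene_lo", "coefficient")]
  }))
  if (is.null(out)) {
    return(empty_feature_table(NA_character_))
  }
  rownames(out) <- NULL
  out
}

#' Plot per-stage feature counts of a fitted model
#'
#' @param x A `"ger_model"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ger_model <- function(x, ...) {
  tab <- rbind(screened = x$stages$screened_gers,
               final = x$stages$final_gers)
  colnames(tab) <- x$subtypes
  graphics::barplot(tab, beside = TRUE, legend.text = rownames(tab),
                    ylab = "gene pairs", ...)
  invisible(x)
}
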