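#' Enumerate all unordered gene pairs
#'
#' @param genes Character vector of >= 2 unique gene IDs.
#' @return Two-column character matrix (`gene_i`, `gene_j`), all
#'   n(n-1)/2 unordered pairs in lexicographic order of the sorted input.
#' @export
enumerate_pairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene IDs", call. = FALSE)
  m <- length(genes)
  if (m < 2L) stop("need >= 2 genes to form pairs", call. = FALSE)
  genes <- sort(genes)
  i <- rep.int(seq_len(m - 1L), (m - 1L):1L)
  j <- sequence((m - 1L):1L, from = 2L:m)
  cbind(gene_i = genes[i], gene_j = genes[j])
}

#' Gene-pair indicator
#'
#' The binary "reversal" encoding of a gene pair inside one sample: 1 when
#' gene i strictly outranks gene j, 0 otherwise (ties fall in the 0 branch).
#'
#' @param ti,tj Rank values from the same sample (vectorised).
#' @return Integer vector of 0/1.
#' @export
ger_indicator <- function(ti, tj) {
  as.integer(ti > tj)
}

#' Reversal ratio of a 2x2 pair-indicator contingency table
#'
#' Rows are (selected subtype, rest subtype), columns are (indicator 1,
#' indicator 0). The reversal ratio (f11 + f22) / t is the fraction of
#' samples whose indicator agrees with the subtype-characteristic
#' orientation; 1 is perfect reversal, 0.5 uninformative.
#'
#' @param f11,f12,f21,f22 Non-negative counts (vectorised).
#' @return Numeric in `[0, 1]`.
#' @export
reversal_ratio <- function(f11, f12, f21, f22) {
  t <- f11 + f12 + f21 + f22
  if (any(t == 0)) stop("empty contingency table", call. = FALSE)
  if (any(c(f11, f12, f21, f22) < 0)) stop("negative count", call. = FALSE)
  (f11 + f22) / t
}

#' Two-sided Fisher exact p-value for 2x2 tables
#'
#' The classical conditional test: with both margins fixed, f11 follows a
#' hypergeometric distribution, and the two-sided p is the sum of the point
#' probabilities of all tables no more probable than the observed one
#' (point-probability rule, with the same 1 + 1e-7 relative guard that
#' `stats::fisher.test` applies to protect ties against rounding).
#' Vectorised so that screening can evaluate many tables cheaply.
#'
#' @param f11,f12,f21,f22 Non-negative integer counts (vectorised, recycled).
#' @return Numeric p-values in (0, 1].
#' @export
fisher_p <- function(f11, f12, f21, f22) {
  n <- max(length(f11), length(f12), length(f21), length(f22))
  f11 <- rep_len(as.numeric(f11), n); f12 <- rep_len(as.numeric(f12), n)
  f21 <- rep_len(as.numeric(f21), n); f22 <- rep_len(as.numeric(f22), n)
  if (any(c(f11, f12, f21, f22) < 0)) stop("negative count", call. = FALSE)
  if (any(f11 + f12 + f21 + f22 == 0)) stop("empty contingency table",
                                            call. = FALSE)
  vapply(seq_len(n), function(k) {
    m1 <- f11[k] + f12[k]           # selected-subtype samples
    m2 <- f21[k] + f22[k]           # rest-subtype samples
    c1 <- f11[k] + f21[k]           # indicator-1 column total
    lo <- max(0, c1 - m2)
    hi <- min(c1, m1)
    probs <- stats::dhyper(lo:hi, m1, m2, c1)
    min(1, sum(probs[probs <= probs[f11[k] - lo + 1L] * (1 + 1e-7)]))
  }, numeric(1L))
}

#' Per-comparison reversal-ratio thresholds
#'
#' The screen compares each selected subtype against each other subtype, so a
#' C-subtype problem has C(C-1) ordered comparisons, each with its own
#' minimum reversal ratio. For the four consensus medulloblastoma subgroups
#' the defaults encode the published operating points: 0.95 whenever the
#' selected subtype is SHH or WNT; 0.90 for Group3/Group4 against SHH; 0.85
#' for Group3/Group4 against WNT and Group4 against Group3; 0.80 for Group3
#' against Group4. For any other subtype set a single `default` fills the
#' table.
#'
#' @param subtypes Ordered subtype names.
#' @param default Threshold used for subtype sets other than the four MB
#'   subgroups.
#' @return Square numeric matrix, rows = selected subtype, columns = rest
#'   subtype, `NA` diagonal.
#' @export
reversal_thresholds <- function(subtypes = mb_subtypes(), default = 0.95) {
  subtypes <- as.character(subtypes)
  C <- length(subtypes)
  if (C < 2L) stop("need >= 2 subtypes", call. = FALSE)
  th <- matrix(default, C, C, dimnames = list(subtypes, subtypes))
  if (setequal(subtypes, mb_subtypes())) {
    th[, ] <- NA_real_
    th[c("SHH", "WNT"), ] <- 0.95
    th["Group3", "SHH"] <- 0.90; th["Group4", "SHH"] <- 0.90
    th["Group3", "WNT"] <- 0.85; th["Group4", "WNT"] <- 0.85
    th["Group4", "Group3"] <- 0.85
    th["Group3", "Group4"] <- 0.80
  }
  diag(th) <- NA_real_
  bad <- th[!is.na(th)]
  if (any(bad <= 0.5 | bad > 1)) stop("thresholds must lie in (0.5, 1]",
                                      call. = FALSE)
  th
}

#' Screen subtype-specific gene-pair reversal features
#'
#' Evaluates every unordered pair of a subtype's signature genes against each
#' of the other subtypes. For a pair and a comparison (S vs O), the 2x2 table
#' counts samples by indicator value; the pair passes the comparison when the
#' reversal ratio meets the comparison's threshold and the Fisher exact p is
#' below `alpha`, in either pair orientation. A pair is retained for S only
#' if one consistent orientation passes all comparisons; the retained
#' orientation (`gene_hi` outranking `gene_lo` characterises S) is recorded
#' together with the per-comparison ratios and p-values.
#'
#' @param ranks Rank matrix from [rank_transform()].
#' @param labels Named sample -> subtype vector covering all columns.
#' @param subtype Selected subtype S.
#' @param genes Signature gene IDs (subset of `rownames(ranks)`).
#' @param thresholds Matrix from [reversal_thresholds()].
#' @param alpha Fisher significance level.
#' @param inclusive If `TRUE` (default) the ratio test is `>= threshold`,
#'   otherwise strictly `>`.
#' @param chunk_size Pairs evaluated per block (memory/time trade-off only;
#'   output is identical to full enumeration).
#' @return `data.frame` with columns `subtype`, `gene_hi`, `gene_lo`, then
#'   `ratio_<other>` and `p_<other>` for each comparison.
#' @export
screen_gers <- function(ranks, labels, subtype, genes,
                        thresholds = reversal_thresholds(subtype_set(labels)),
                        alpha = 0.05, inclusive = TRUE,
                        chunk_size = 50000L) {
  labels <- check_labels(ranks, labels)
  subtypes <- rownames(thresholds)
  others <- setdiff(intersect(subtypes, unique(labels)), subtype)
  if (!subtype %in% labels) stop("no samples labelled '", subtype, "'",
                                 call. = FALSE)
  empty <- result_skeleton(subtype, others)
  if (length(genes) < 2L) {
    warning("fewer than 2 signature genes for '", subtype,
            "': no pairs to screen", call. = FALSE)
    return(empty)
  }
  missing <- setdiff(genes, rownames(ranks))
  if (length(missing)) stop("signature genes absent from rank matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  pairs <- enumerate_pairs(genes)
  sel_cols <- which(labels == subtype)
  other_cols <- lapply(others, function(o) which(labels == o))
  thr <- vapply(others, function(o) thresholds[subtype, o], numeric(1L))
  if (anyNA(thr)) stop("missing threshold for a comparison of '", subtype,
                       "'", call. = FALSE)
  ratio_ok <- if (inclusive) `>=` else `>`

  out <- vector("list", ceiling(nrow(pairs) / chunk_size))
  for (blk in seq_along(out)) {
    idx <- seq.int((blk - 1L) * chunk_size + 1L,
                   min(blk * chunk_size, nrow(pairs)))
    ri <- ranks[pairs[idx, 1L], , drop = FALSE]
    rj <- ranks[pairs[idx, 2L], , drop = FALSE]
    fwd <- ri > rj      # orientation: gene_i outranks gene_j in S
    rev <- rj > ri
    keep_fwd <- rep.int(TRUE, length(idx))
    keep_rev <- rep.int(TRUE, length(idx))
    stats_f <- stats_r <- vector("list", length(others))
    n_sel <- length(sel_cols)
    f11_f <- rowSums(fwd[, sel_cols, drop = FALSE])
    f11_r <- rowSums(rev[, sel_cols, drop = FALSE])
    for (ci in seq_along(others)) {
      oc <- other_cols[[ci]]
      n_oth <- length(oc)
      f21_f <- rowSums(fwd[, oc, drop = FALSE])
      f21_r <- rowSums(rev[, oc, drop = FALSE])
      rr_f <- (f11_f + (n_oth - f21_f)) / (n_sel + n_oth)
      rr_r <- (f11_r + (n_oth - f21_r)) / (n_sel + n_oth)
      keep_fwd <- keep_fwd & ratio_ok(rr_f, thr[ci])
      keep_rev <- keep_rev & ratio_ok(rr_r, thr[ci])
      stats_f[[ci]] <- list(rr = rr_f, f11 = f11_f, f21 = f21_f,
                            n_oth = n_oth)
      stats_r[[ci]] <- list(rr = rr_r, f11 = f11_r, f21 = f21_r,
                            n_oth = n_oth)
    }
    # Fisher tests only for pairs that already clear every ratio threshold
    for (ci in seq_along(others)) {
      for (side in c("f", "r")) {
        keep <- if (side == "f") keep_fwd else keep_rev
        st <- if (side == "f") stats_f[[ci]] else stats_r[[ci]]
        p <- rep.int(NA_real_, length(idx))
        if (any(keep)) {
          p[keep] <- fisher_p(st$f11[keep], n_sel - st$f11[keep],
                              st$f21[keep], st$n_oth - st$f21[keep])
        }
        st$p <- p
        if (side == "f") {
          stats_f[[ci]] <- st
          keep_fwd <- keep & !is.na(p) & p < alpha
        } else {
          stats_r[[ci]] <- st
          keep_rev <- keep & !is.na(p) & p < alpha
        }
      }
    }
    rows <- which(keep_fwd | keep_rev)
    if (!length(rows)) next
    use_fwd <- keep_fwd[rows]   # fwd wins if both orientations pass
    hi <- ifelse(use_fwd, pairs[idx[rows], 1L], pairs[idx[rows], 2L])
    lo <- ifelse(use_fwd, pairs[idx[rows], 2L], pairs[idx[rows], 1L])
    df <- data.frame(subtype = subtype, gene_hi = hi, gene_lo = lo,
                     stringsAsFactors = FALSE)
    for (ci in seq_along(others)) {
      df[[paste0("ratio_", others[ci])]] <-
        ifelse(use_fwd, stats_f[[ci]]$rr[rows], stats_r[[ci]]$rr[rows])
      df[[paste0("p_", others[ci])]] <-
        ifelse(use_fwd, stats_f[[ci]]$p[rows], stats_r[[ci]]$p[rows])
    }
    out[[blk]] <- df
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) {
    warning("no gene pairs passed screening for '", subtype, "'",
            call. = FALSE)
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

result_skeleton <- function(subtype, others) {
  df <- data.frame(subtype = character(), gene_hi = character(),
                   gene_lo = character(), stringsAsFactors = FALSE)
  for (o in others) {
    df[[paste0("ratio_", o)]] <- numeric()
    df[[paste0("p_", o)]] <- numeric()
  }
  df
}
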