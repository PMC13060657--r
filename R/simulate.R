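#' Specification for a synthetic multi-batch expression cohort
#'
#' Describes a cohort with planted subtype structure and batch distortion.
#' Defaults emulate a large four-subgroup medulloblastoma training cohort:
#' 763 samples in proportions 223:70:144:326 (SHH:WNT:Group3:Group4) over
#' 2000 genes, 40 disjoint marker genes per subtype (half shifted up, half
#' down by 20% of the rank scale), and three batches carrying both a
#' sample-level monotone warp (rank-preserving: identity, affine, power or
#' log) and an additive gene-level batch shift (rank-perturbing) so that
#' batch robustness is actually exercised.
#'
#' @param n_samples Total sample count.
#' @param n_genes Gene count.
#' @param proportions Named positive weights per subtype (normalised to 1).
#' @param markers_per_subtype Marker genes per subtype (half up, half down);
#'   markers are disjoint across subtypes.
#' @param marker_shift Target mean rank displacement of a marker in its
#'   subtype, as a fraction of `n_genes`, in (0, 0.5).
#' @param batches List of batch descriptors, each
#'   `list(name=, frac=, warp=, gene_shift_sd=)` with `warp` one of
#'   `"identity"`, `"affine"`, `"power"`, `"log"`. `frac`s are normalised.
#' @param noise_sd Per-entry Gaussian noise sd on the log-expression scale.
#' @param baseline_mean,baseline_sd Gaussian baseline of per-gene
#'   log-expression.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_samples = 763L, n_genes = 2000L,
                        proportions = c(SHH = 223, WNT = 70,
                                        Group3 = 144, Group4 = 326),
                        markers_per_subtype = 40L, marker_shift = 0.2,
                        batches = default_batch_plan(), noise_sd = 0.4,
                        baseline_mean = 6, baseline_sd = 2, seed = 1L) {
  if (is.null(names(proportions)) || anyDuplicated(names(proportions))) {
    stop("proportions must be uniquely named by subtype", call. = FALSE)
  }
  if (length(proportions) < 2L || any(proportions <= 0)) {
    stop("need >= 2 subtypes with positive proportions", call. = FALSE)
  }
  if (marker_shift <= 0 || marker_shift >= 0.5) {
    stop("marker_shift must be in (0, 0.5)", call. = FALSE)
  }
  if (markers_per_subtype * length(proportions) > n_genes) {
    stop("more marker genes requested than genes available", call. = FALSE)
  }
  fr <- vapply(batches, function(b) b$frac, numeric(1L))
  if (any(fr <= 0)) stop("batch fractions must be positive", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 proportions = proportions / sum(proportions),
                 markers_per_subtype = as.integer(markers_per_subtype),
                 marker_shift = marker_shift,
                 batches = batches, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default three-batch distortion plan
#'
#' Batch 1 is the clean reference; batches 2 and 3 combine a sample-level
#' monotone warp (an affine gain/offset and a log compression, the classic
#' linear-versus-log scale disparity between cohorts) with gene-level
#' additive shifts of sd 0.8 (twice the default entry noise). The warps break
#' absolute-expression classifiers outright while leaving within-sample
#' ranks untouched; the gene-level shifts perturb ranks, which is what makes
#' rank-based recovery non-trivial.
#'
#' @return List of batch descriptors for [cohort_spec()].
#' @export
default_batch_plan <- function() {
  list(list(name = "batch1", frac = 0.4, warp = "identity",
            gene_shift_sd = 0),
       list(name = "batch2", frac = 0.3, warp = "affine",
            gene_shift_sd = 0.8),
       list(name = "batch3", frac = 0.3, warp = "log",
            gene_shift_sd = 0.8))
}

apply_warp <- function(v, warp) {
  switch(warp,
         identity = v,
         affine = 1.6 * v + 3,
         power = (v - min(v) + 1)^1.3,
         log = log(v - min(v) + 1),
         stop("unknown warp '", warp, "'", call. = FALSE))
}

#' Generate a synthetic multi-batch cohort
#'
#' Draws a per-gene Gaussian log-expression baseline, plants subtype markers
#' by quantile shifting (an up-marker's subtype mean is moved to the baseline
#' value `marker_shift` quantiles higher, so its mean rank displacement is
#' calibrated on the rank scale), then applies per-batch gene-level additive
#' shifts and the batch's sample-level monotone warp. Up-markers are drawn
#' from the (0.35, 0.45) baseline quantile band and down-markers from
#' (0.55, 0.65), so in the marked subtype every (up, down) marker pair
#' reverses its baseline order — these are the planted reversal pairs
#' recorded in the truth set.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `"ger_cohort"`: `x` (genes x samples matrix),
#'   `labels`, `batches` (named vectors), and `truth` (per-subtype `up` /
#'   `down` marker lists and `pairs`, the planted oriented reversal pairs).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subtypes <- names(spec$proportions)
  n <- spec$n_samples
  g <- spec$n_genes

  # integer class sizes by largest remainder
  sizes <- floor(spec$proportions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(spec$proportions * n - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  labels <- rep(subtypes, times = sizes)

  # batch assignment stratified within subtype
  bfr <- vapply(spec$batches, function(b) b$frac, numeric(1L))
  bfr <- bfr / sum(bfr)
  bnames <- vapply(spec$batches, function(b) b$name, character(1L))
  batches <- character(n)
  for (s in subtypes) {
    idx <- which(labels == s)
    bs <- floor(bfr * length(idx))
    brem <- length(idx) - sum(bs)
    if (brem > 0) {
      extra <- order(bfr * length(idx) - bs,
                     decreasing = TRUE)[seq_len(brem)]
      bs[extra] <- bs[extra] + 1L
    }
    batches[idx] <- rep(bnames, times = bs)
  }

  gene_ids <- sprintf("g%04d", seq_len(g))
  sample_ids <- sprintf("s%04d", seq_len(n))

  x <- with_seed(spec$seed, {
    mu <- stats::rnorm(g, spec$baseline_mean, spec$baseline_sd)
    names(mu) <- gene_ids
    ord <- order(mu)                     # baseline ranks
    half <- spec$markers_per_subtype %/% 2L
    # candidate bands on the baseline rank scale
    band <- function(lo, hi) ord[seq.int(max(1L, round(lo * g)),
                                         round(hi * g))]
    up_band <- band(0.35, 0.45)
    down_band <- band(0.55, 0.65)
    if (length(up_band) < half * length(subtypes) ||
        length(down_band) < (spec$markers_per_subtype - half) *
        length(subtypes)) {
      stop("marker quantile bands too small for the requested marker count",
           call. = FALSE)
    }
    up_pick <- sample(up_band, half * length(subtypes))
    down_pick <- sample(down_band,
                        (spec$markers_per_subtype - half) * length(subtypes))
    markers <- list()
    for (k in seq_along(subtypes)) {
      markers[[subtypes[k]]] <- list(
        up = gene_ids[up_pick[seq.int((k - 1L) * half + 1L, k * half)]],
        down = gene_ids[down_pick[seq.int(
          (k - 1L) * (spec$markers_per_subtype - half) + 1L,
          k * (spec$markers_per_subtype - half))]])
    }
    # quantile-shift deltas: move a marker's subtype mean to the baseline
    # value marker_shift quantiles away
    mu_sorted <- mu[ord]
    rank_of <- integer(g); rank_of[ord] <- seq_len(g)
    shift_to <- function(gid, direction) {
      r <- rank_of[match(gid, gene_ids)]
      tgt <- pmin(g, pmax(1L, r + direction * round(spec$marker_shift * g)))
      mu_sorted[tgt] - mu[match(gid, gene_ids)]
    }
    delta <- matrix(0, g, length(subtypes),
                    dimnames = list(gene_ids, subtypes))
    for (s in subtypes) {
      delta[markers[[s]]$up, s] <- shift_to(markers[[s]]$up, +1L)
      delta[markers[[s]]$down, s] <- shift_to(markers[[s]]$down, -1L)
    }
    # gene-level additive batch shifts
    bshift <- vapply(spec$batches, function(b) {
      stats::rnorm(g, 0, b$gene_shift_sd)
    }, numeric(g))
    colnames(bshift) <- bnames

    xm <- matrix(stats::rnorm(g * n, 0, spec$noise_sd), g, n,
                 dimnames = list(gene_ids, sample_ids))
    xm <- xm + mu + delta[, labels] + bshift[, batches]
    for (j in seq_len(n)) {
      xm[, j] <- apply_warp(xm[, j], spec$batches[[
        match(batches[j], bnames)]]$warp)
    }
    attr(xm, "markers") <- markers
    xm
  })
  markers <- attr(x, "markers")
  attr(x, "markers") <- NULL

  pairs <- lapply(markers, function(m) {
    data.frame(gene_hi = rep(m$up, each = length(m$down)),
               gene_lo = rep(m$down, times = length(m$up)),
               stringsAsFactors = FALSE)
  })
  structure(list(x = x,
                 labels = stats::setNames(labels, sample_ids),
                 batches = stats::setNames(batches, sample_ids),
                 truth = list(markers = markers, pairs = pairs),
                 spec = spec),
            class = "ger_cohort")
}

#' @method print ger_cohort
#' @export
print.ger_cohort <- function(x, ...) {
  cat("Synthetic cohort:", ncol(x$x), "samples x", nrow(x$x), "genes\n")
  cat("  subtypes:",
      paste(names(table(x$labels)), table(x$labels), sep = "=",
            collapse = ", "), "\n")
  cat("  batches:",
      paste(names(table(x$batches)), table(x$batches), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Split a cohort into train/test by batch
#'
#' Batches are atomic: every sample of a test batch goes to the test side.
#' Because batch assignment is stratified by subtype, both sides keep the
#' cohort's label proportions.
#'
#' @param cohort A `"ger_cohort"`.
#' @param test_batches Character vector of batch names held out as test.
#' @return List with `train` and `test`, each a list `x`, `labels`,
#'   `batches`.
#' @export
split_by_batch <- function(cohort, test_batches) {
  stopifnot(inherits(cohort, "ger_cohort"))
  all_b <- unique(cohort$batches)
  bad <- setdiff(test_batches, all_b)
  if (length(bad)) stop("unknown batches: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (length(setdiff(all_b, test_batches)) == 0L) {
    stop("no batches left for training", call. = FALSE)
  }
  if (!length(test_batches)) stop("empty test side", call. = FALSE)
  te <- cohort$batches %in% test_batches
  list(train = list(x = cohort$x[, !te, drop = FALSE],
                    labels = cohort$labels[!te],
                    batches = cohort$batches[!te]),
       test = list(x = cohort$x[, te, drop = FALSE],
                   labels = cohort$labels[te],
                   batches = cohort$batches[te]))
}

#' Write a cohort to disk as plain-text fixtures
#'
#' Writes the expression TSV, a two-column label TSV, a batch TSV and the
#' truth record as JSON, so the command-line interface can run end-to-end
#' from files.
#'
#' @param cohort A `"ger_cohort"`.
#' @param dir Output directory (created if needed).
#' @return Invisible named vector of the four file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ger_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             batches = file.path(dir, "batches.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$x, paths["expression"])
  utils::write.table(data.frame(names(cohort$labels),
                                unname(cohort$labels)),
                     paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(names(cohort$batches),
                                unname(cohort$batches)),
                     paths["batches"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
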