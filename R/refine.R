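#' Elastic-net selection settings
#'
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge). The
#'   default 0.1 is ridge-leaning: screened pair features are strongly
#'   correlated and a small alpha keeps groups of them while still zeroing
#'   uninformative ones.
#' @param n_folds Cross-validation folds.
#' @param lambda_rule `"lambda_1se"` (default; the largest penalty whose CV
#'   deviance is within one standard error of the minimum, favouring sparser
#'   models) or `"lambda_min"`.
#' @param loss CV loss: binomial `"deviance"` (default) or `"class"`.
#' @param nlambda,lambda_min_ratio Penalty path: `nlambda` log-spaced values
#'   from the all-zero lambda down `-log10(lambda_min_ratio)` decades.
#' @param seed Integer controlling fold assignment.
#' @return List of class `"enet_control"`.
#' @export
enet_control <- function(alpha = 0.1, n_folds = 10L,
                         lambda_rule = c("lambda_1se", "lambda_min"),
                         loss = c("deviance", "class"),
                         nlambda = 100L, lambda_min_ratio = 1e-4,
                         seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, n_folds >= 2L, nlambda >= 2L,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 lambda_rule = match.arg(lambda_rule),
                 loss = match.arg(loss), nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed)),
            class = "enet_control")
}

# Deterministic class-stratified fold assignment.
stratified_folds <- function(y, n_folds, seed) {
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  foldid
}

#' Select informative features by cross-validated elastic-net logistic
#' regression
#'
#' Fits the penalized binomial objective over a lambda path with glmnet,
#' picks lambda by the configured rule from seeded, class-stratified
#' cross-validation, and returns the features with nonzero coefficients at
#' that lambda. Binary indicator features are already on a common scale, so
#' standardization is off.
#'
#' @param x Samples x features numeric matrix (binary indicators in this
#'   pipeline).
#' @param y Binary outcome (logical, 0/1, or two-level factor).
#' @param control [enet_control()] settings.
#' @return List with `index` (selected column indices), `coef` (their
#'   coefficients at the chosen lambda), `lambda`, and the `cv` fit.
#' @export
elastic_net_select <- function(x, y, control = enet_control()) {
  x <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(as.logical(y))
  tab <- table(y)
  if (length(tab) < 2L) stop("y has a single class", call. = FALSE)
  if (min(tab) < 2L) stop("need >= 2 samples per class", call. = FALSE)
  n_folds <- control$n_folds
  if (n_folds > min(tab)) {
    n_folds <- max(3L, as.integer(min(tab)))
    warning("n_folds exceeds the smallest class; using ", n_folds,
            " stratified folds", call. = FALSE)
  }
  foldid <- stratified_folds(y, n_folds, control$seed)
  cv <- glmnet::cv.glmnet(
    x, y, family = "binomial", alpha = control$alpha,
    type.measure = if (control$loss == "deviance") "deviance" else "class",
    foldid = foldid, standardize = FALSE,
    nlambda = control$nlambda, lambda.min.ratio = control$lambda_min_ratio)
  lam <- if (control$lambda_rule == "lambda_1se") cv$lambda.1se else
    cv$lambda.min
  beta <- as.numeric(stats::coef(cv, s = lam))[-1L]  # drop intercept
  idx <- which(beta != 0)
  list(index = idx, coef = beta[idx], lambda = lam, cv = cv)
}

# Build the samples x pairs indicator matrix for a screened feature table.
pair_indicator_matrix <- function(ranks, features) {
  if (!nrow(features)) {
    return(matrix(0L, ncol(ranks), 0L,
                  dimnames = list(colnames(ranks), character())))
  }
  hi <- ranks[features$gene_hi, , drop = FALSE]
  lo <- ranks[features$gene_lo, , drop = FALSE]
  m <- t(hi > lo) * 1L
  colnames(m) <- paste(features$gene_hi, features$gene_lo, sep = ">")
  m
}
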