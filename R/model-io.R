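MODEL_SCHEMA_VERSION <- "1.0"

#' Save a fitted model as JSON
#'
#' The model is written as a single JSON document with a schema-version tag.
#' Gene pairs are stored by gene ID, not matrix index, so a saved model
#' applies to expression matrices with any gene ordering.
#'
#' @param model A `"ger_model"`.
#' @param path Output path.
#' @export
save_ger_model <- function(model, path) {
  stopifnot(inherits(model, "ger_model"))
  cfg <- model$config
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    subtypes = model$subtypes,
    gene_universe = model$gene_universe,
    features = model$features,
    config = list(
      rank_frac = cfg$rank_frac, sig_alpha = cfg$sig_alpha,
      fisher_alpha = cfg$fisher_alpha, var_equal = cfg$var_equal,
      inclusive = cfg$inclusive, seed = cfg$seed,
      thresholds = list(values = as.vector(cfg$thresholds),
                        subtypes = rownames(cfg$thresholds)),
      enet = unclass(cfg$enet)),
    stages = lapply(model$stages, as.list),
    provenance = model$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path Path written by [save_ger_model()].
#' @return A `"ger_model"`.
#' @export
load_ger_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$schema_version) ||
      !identical(as.character(doc$schema_version), MODEL_SCHEMA_VERSION)) {
    stop("model schema version mismatch: expected ", MODEL_SCHEMA_VERSION,
         ", found ", doc$schema_version %||% "<none>", call. = FALSE)
  }
  subtypes <- as.character(doc$subtypes)
  th <- matrix(as.numeric(doc$config$thresholds$values),
               length(doc$config$thresholds$subtypes),
               length(doc$config$thresholds$subtypes),
               dimnames = list(doc$config$thresholds$subtypes,
                               doc$config$thresholds$subtypes))
  enet <- doc$config$enet
  features <- lapply(subtypes, function(s) {
    f <- doc$features[[s]]
    if (is.null(f) || !length(f) || !NROW(f)) {
      warning("loaded model has no features for subtype '", s, "'",
              call. = FALSE)
      return(empty_feature_table(s))
    }
    as.data.frame(f, stringsAsFactors = FALSE)
  })
  names(features) <- subtypes
  structure(list(
    subtypes = subtypes,
    features = features,
    gene_universe = as.character(doc$gene_universe),
    config = list(rank_frac = doc$config$rank_frac,
                  sig_alpha = doc$config$sig_alpha,
                  thresholds = th,
                  fisher_alpha = doc$config$fisher_alpha,
                  enet = do.call(enet_control, enet[c(
                    "alpha", "n_folds", "lambda_rule", "loss", "nlambda",
                    "lambda_min_ratio", "seed")]),
                  seed = as.integer(doc$config$seed),
                  var_equal = isTRUE(doc$config$var_equal),
                  inclusive = isTRUE(doc$config$inclusive)),
    stages = lapply(doc$stages, function(s) {
      if (is.list(s)) unlist(s) else s
    }),
    provenance = doc$provenance
  ), class = "ger_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the feature table as TSV
#'
#' @param model A `"ger_model"`.
#' @param path Output path.
#' @export
write_feature_table <- function(model, path) {
  stopifnot(inherits(model, "ger_model"))
  tabs <- lapply(model$subtypes, function(s) model$features[[s]])
  tabs <- tabs[vapply(tabs, nrow, integer(1L)) > 0L]
  out <- if (length(tabs)) {
    all_cols <- unique(unlist(lapply(tabs, names)))
    do.call(rbind, lapply(tabs, function(f) {
      f[setdiff(all_cols, names(f))] <- NA
      f[all_cols]
    }))
  } else {
    empty_feature_table(NA_character_)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
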