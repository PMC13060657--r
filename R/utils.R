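#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Canonical medulloblastoma subgroup order; used for deterministic tie-breaks.
mb_subtypes <- function() c("SHH", "WNT", "Group3", "Group4")

# Resolve the ordered subtype set from labels (canonical MB order when the
# labels are exactly the four consensus subgroups, otherwise order of
# appearance), or validate a user-supplied order.
subtype_set <- function(labels, subtypes = NULL) {
  obs <- unique(as.character(labels))
  if (is.null(subtypes)) {
    subtypes <- if (all(obs %in% mb_subtypes())) {
      mb_subtypes()[mb_subtypes() %in% obs]
    } else {
      obs
    }
  }
  subtypes <- as.character(subtypes)
  if (anyDuplicated(subtypes)) stop("duplicate subtype names", call. = FALSE)
  if (length(subtypes) < 2L) stop("need at least 2 subtypes", call. = FALSE)
  missing <- setdiff(obs, subtypes)
  if (length(missing)) {
    stop("labels contain subtypes not in the subtype set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  subtypes
}

check_labels <- function(x, labels) {
  if (is.null(names(labels))) {
    if (length(labels) != ncol(x)) {
      stop("unnamed labels must have one entry per sample", call. = FALSE)
    }
    names(labels) <- colnames(x)
  }
  unknown <- setdiff(names(labels), colnames(x))
  if (length(unknown)) {
    stop("labels reference unknown samples: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(as.character(labels)[match(colnames(x), names(labels))],
                         colnames(x))
  if (anyNA(out)) {
    stop("labels missing for samples: ",
         paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

check_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression input must be a numeric matrix (genes x samples)",
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene IDs: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample IDs: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x)) stop("expression matrix contains missing values", call. = FALSE)
  invisible(x)
}
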