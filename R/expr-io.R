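#' Read a gene expression matrix from TSV/CSV
#'
#' Reads a genes x samples expression table (first column = gene IDs, header
#' row = sample IDs) as produced by most expression pipelines. Values may be
#' log-scale microarray intensities or TPM; the classifier only ever uses
#' their within-sample ordering.
#'
#' @param path Path to the expression table.
#' @param format `"tsv"` or `"csv"`; default guessed from the file extension.
#' @param label_path Optional two-column table (sample_id, subtype). Labels
#'   are attached as the `"labels"` attribute of the returned matrix.
#' @param na_action `"error"` (default) rejects missing values;
#'   `"drop_genes"` removes genes with any missing entry (count reported).
#' @return Numeric matrix (genes x samples) with gene rownames and sample
#'   colnames; row order preserved from the file. If labels were given, a
#'   named character vector attribute `"labels"`.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv"),
                            label_path = NULL,
                            na_action = c("error", "drop_genes")) {
  format <- match.arg(format)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("expression table needs >= 1 sample column",
                          call. = FALSE)
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1L]
      stop("non-numeric value at gene '", gene_ids[bad], "', sample '",
           colnames(vals)[j], "'", call. = FALSE)
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- gene_ids
  if (anyNA(x)) {
    if (na_action == "error") {
      bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", rownames(x)[bad[1L]], "', sample '",
           colnames(x)[bad[2L]], "'", call. = FALSE)
    }
    drop <- rowSums(is.na(x)) > 0L
    message("dropping ", sum(drop), " genes with missing values")
    x <- x[!drop, , drop = FALSE]
  }
  check_expression_matrix(x)
  if (!is.null(label_path)) {
    labels <- read_labels(label_path)
    unknown <- setdiff(names(labels), colnames(x))
    if (length(unknown)) {
      stop("label file references unknown samples: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    attr(x, "labels") <- labels
  }
  x
}

#' Read a sample-to-subtype label table
#'
#' @param path Two-column TSV/CSV (sample_id, subtype); a header is detected
#'   and skipped if its first field is not reused as a sample elsewhere.
#' @return Named character vector, `names` = sample IDs.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = FALSE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("label table needs two columns", call. = FALSE)
  # tolerate a header row
  if (tolower(df[1L, 1L]) %in% c("sample", "sample_id", "id")) {
    df <- df[-1L, , drop = FALSE]
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.character(df[[2L]]), ids)
}

#' Write an expression matrix as TSV
#'
#' @param x Numeric genes x samples matrix.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  check_expression_matrix(x)
  # 17 significant digits so values round-trip bit-exactly
  chr <- matrix(sprintf("%.17g", x), nrow(x), dimnames = dimnames(x))
  df <- data.frame(gene_id = rownames(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score normalise an expression matrix
#'
#' Centers and scales each sample (column) or each gene (row) to mean 0 and
#' sample standard deviation 1 (divisor n-1). Per-sample z-scoring is a
#' strictly increasing affine map within each sample, so it never changes
#' intrasample ranks and is a no-op for the rank-based classifier; it is
#' offered because cross-cohort inputs routinely arrive on wildly different
#' scales and other tools in a workflow may need comparable values.
#'
#' Zero-variance vectors are replaced with all zeros (with a warning) rather
#' than aborting, so constant probes do not kill a run.
#'
#' @param x Numeric genes x samples matrix.
#' @param axis `"per_sample"` (default, columns) or `"per_gene"` (rows).
#' @return Matrix of the same shape and dimnames.
#' @export
zscore_normalize <- function(x, axis = c("per_sample", "per_gene")) {
  axis <- match.arg(axis)
  check_expression_matrix(x)
  if (axis == "per_gene") {
    return(t(zscore_normalize(t(x), "per_sample")))
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    warning(sum(zero), " zero-variance vector(s) set to all zeros",
            call. = FALSE)
    sdv[zero] <- 1
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  z[, zero] <- 0
  z
}
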