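#' Expression matrix container
#'
#' A light S3 wrapper around a genes x samples numeric matrix that tracks
#' which value space the numbers live in (\code{"tpm"}, \code{"log2p1"}, or
#' \code{"zscore"}) and optional per-sample phenotype metadata. Tracking the
#' value space lets downstream stages refuse inputs on the wrong scale (for
#' example, row z-scoring is only defined on log2(1+TPM) values).
#'
#' @param values Numeric matrix, rows = genes, columns = samples. Dimnames are
#'   required and must be unique after symbol normalization.
#' @param value_space One of \code{"tpm"}, \code{"log2p1"}, \code{"zscore"}.
#' @param sample_meta Optional data.frame with columns \code{sample_id},
#'   \code{phenotype_label}, and optionally \code{lineage}.
#' @return An object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, value_space = c("tpm", "log2p1", "zscore"),
                              sample_meta = NULL) {
  value_space <- match.arg(value_space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (value_space == "tpm" && any(values < 0, na.rm = TRUE))
    stop("TPM values must be non-negative")
  if (!is.null(sample_meta)) {
    if (!all(c("sample_id", "phenotype_label") %in% names(sample_meta)))
      stop("sample_meta needs columns sample_id and phenotype_label")
    sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
    if (anyNA(sample_meta$sample_id))
      stop("sample_meta is missing entries for some samples")
  }
  structure(list(values = values, value_space = value_space,
                 sample_meta = sample_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$value_space))
  if (!is.null(x$sample_meta))
    cat("phenotypes:", paste(unique(x$sample_meta$phenotype_label), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV/CSV
#'
#' Two dialects are supported. \code{"plain"}: first column gene symbol, header
#' row of sample ids, values taken as TPM. \code{"depmap"}: the DepMap
#' \code{OmicsExpressionProteinCodingGenesTPMLogp1}-style layout with rows =
#' cell lines, columns = \code{"SYMBOL (ENTREZID)"} headers, values already on
#' the log2(1+TPM) scale; the matrix is transposed to genes x lines and headers
#' reduced to bare symbols.
#'
#' @param path Path to a delimited text file (delimiter inferred from the
#'   extension: .csv = comma, otherwise tab).
#' @param dialect \code{"plain"} or \code{"depmap"}.
#' @param sample_meta Optional phenotype data.frame (see
#'   \code{\link{expression_matrix}}), or a path to a sidecar TSV with columns
#'   sample_id, phenotype_label, lineage.
#' @param on_duplicate What to do when two rows normalize to the same symbol:
#'   \code{"fail"} (default) or \code{"first"} (keep first, warn).
#' @param value_space Value space of a \code{plain} file (default
#'   \code{"tpm"}); ignored for the depmap dialect, which is always
#'   log2(1+TPM) per its file naming.
#' @return An \code{ExpressionMatrix}.
#' @export
read_expression <- function(path, dialect = c("plain", "depmap"),
                            sample_meta = NULL,
                            on_duplicate = c("fail", "first"),
                            value_space = "tpm") {
  dialect <- match.arg(dialect)
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!apply(df[, -1L, drop = FALSE], 2L, is.numeric))[1L]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1L]]))))[1L]
    stop(sprintf("non-numeric value at row %d, column '%s' of %s",
                 row, names(df)[bad + 1L], path))
  }
  rownames(mat) <- ids
  if (dialect == "depmap") {
    mat <- t(mat)  # rows become genes, columns cell lines
    value_space <- "log2p1"
  }
  sym <- normalize_symbols(rownames(mat))
  if (anyDuplicated(sym)) {
    dups <- unique(sym[duplicated(sym)])
    if (on_duplicate == "fail")
      stop("duplicate gene symbol(s) after normalization: ",
           paste(dups, collapse = ", "))
    warning("duplicate gene symbol(s), keeping first occurrence: ",
            paste(dups, collapse = ", "))
    keep <- !duplicated(sym)
    mat <- mat[keep, , drop = FALSE]
    sym <- sym[keep]
  }
  rownames(mat) <- sym
  if (is.character(sample_meta) && length(sample_meta) == 1L)
    sample_meta <- utils::read.table(sample_meta, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
  expression_matrix(mat, value_space, sample_meta)
}

#' Write an expression matrix as plain TSV
#'
#' First column \code{gene}, one column per sample. The value space is not
#' serialized; callers re-reading the file state it via the dialect.
#'
#' @param x An \code{ExpressionMatrix}.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' log2(1 + x) transform
#'
#' @param x An \code{ExpressionMatrix} in TPM space.
#' @return The matrix in \code{log2p1} space.
#' @export
log2p1 <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$value_space != "tpm")
    stop("log2p1 expects TPM values, got ", x$value_space)
  if (any(x$values < 0, na.rm = TRUE)) stop("negative TPM values")
  expression_matrix(log2(1 + x$values), "log2p1", x$sample_meta)
}

#' Per-gene (row) z-scores
#'
#' Standardizes each gene across samples using the sample standard deviation
#' (n - 1 denominator). Rows with zero variance map to all zeros rather than
#' NaN so that downstream heatmaps and correlations stay finite.
#'
#' @param x An \code{ExpressionMatrix} in log2p1 space.
#' @return The matrix in \code{zscore} space.
#' @export
zscore_rows <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$value_space != "log2p1")
    stop("zscore_rows expects log2(1+TPM) values, got ", x$value_space)
  if (ncol(x$values) < 2L) stop("need at least 2 samples to z-score")
  mu <- rowMeans(x$values)
  sd <- apply(x$values, 1L, stats::sd)
  z <- (x$values - mu) / sd
  z[sd == 0, ] <- 0
  expression_matrix(z, "zscore", x$sample_meta)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Computes per-sample fold changes from qPCR Ct values: Delta-Ct subtracts the
#' reference gene's Ct within each sample, Delta-Delta-Ct subtracts the control
#' sample's Delta-Ct, and fold change is 2^(-DDCt). The control sample's fold
#' change is exactly 1 by construction.
#'
#' @param ct Long-format data.frame with columns \code{sample}, \code{gene},
#'   \code{ct}.
#' @param reference_gene Housekeeping gene (e.g. GAPDH).
#' @param control_sample Sample all others are expressed relative to.
#' @return data.frame with columns sample, gene, dct, ddct, fold.
#' @export
ddct_fold_change <- function(ct, reference_gene = "GAPDH", control_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  ct$gene <- normalize_symbols(ct$gene)
  reference_gene <- normalize_symbols(reference_gene)
  if (!reference_gene %in% ct$gene)
    stop("reference gene ", reference_gene, " not in table")
  if (!control_sample %in% ct$sample)
    stop("control sample ", control_sample, " not in table")
  missing_ct <- !is.finite(ct$ct)
  if (any(missing_ct)) {
    warning(sum(missing_ct), " row(s) with missing Ct omitted")
    ct <- ct[!missing_ct, , drop = FALSE]
  }
  ref <- ct[ct$gene == reference_gene, c("sample", "ct")]
  names(ref)[2L] <- "ref_ct"
  m <- merge(ct[ct$gene != reference_gene, , drop = FALSE], ref, by = "sample")
  m$dct <- m$ct - m$ref_ct
  ctrl <- m[m$sample == control_sample, c("gene", "dct")]
  names(ctrl)[2L] <- "ctrl_dct"
  m <- merge(m, ctrl, by = "gene")
  m$ddct <- m$dct - m$ctrl_dct
  m$fold <- 2^(-m$ddct)
  m[order(m$sample, m$gene), c("sample", "gene", "dct", "ddct", "fold")]
}
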