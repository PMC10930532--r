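#' CRISPR dependency score table
#'
#' @param scores Numeric matrix, cell lines x genes (Chronos scores; more
#'   negative = stronger dependence). Column names are normalized symbols
#'   (DepMap-style \code{"SYMBOL (ENTREZID)"} headers accepted).
#' @param lineage Optional named character vector (cell line -> lineage).
#' @return Object of class \code{DependencyTable}.
#' @export
dependency_table <- function(scores, lineage = NULL) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores needs cell-line rownames and gene colnames")
  colnames(scores) <- normalize_symbols(colnames(scores))
  structure(list(scores = scores, lineage = lineage),
            class = "DependencyTable")
}

#' Read a dependency CSV (rows cell lines, columns genes)
#'
#' @param path CSV path; first column cell-line id.
#' @param lineage_path Optional sidecar CSV with columns cell_line, lineage.
#' @return A \code{DependencyTable}.
#' @export
read_dependency <- function(path, lineage_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  lineage <- NULL
  if (!is.null(lineage_path)) {
    ld <- utils::read.csv(lineage_path, stringsAsFactors = FALSE)
    lineage <- stats::setNames(ld$lineage, ld$cell_line)
  }
  dependency_table(m, lineage)
}

#' Binarize Chronos dependency scores
#'
#' A cell line is dependent on a gene iff its Chronos score is <= the
#' threshold (boundary counts as dependent). Group labels follow OR rules:
#' YAP/TAZ-dependent = dependent on YAP1 or WWTR1; TEAD-dependent = dependent
#' on any of TEAD1-4. Lines missing a score for any required gene are
#' excluded with a message.
#'
#' @param dep A \code{DependencyTable} containing YAP1, WWTR1, and TEAD1-4.
#' @param threshold Chronos cutoff (default -0.65).
#' @return data.frame: cell_line, one logical column per required gene,
#'   dependent_yap_taz, dependent_tead.
#' @export
binarize_dependency <- function(dep, threshold = -0.65) {
  stopifnot(inherits(dep, "DependencyTable"))
  required <- c("YAP1", "WWTR1", "TEAD1", "TEAD2", "TEAD3", "TEAD4")
  miss <- setdiff(required, colnames(dep$scores))
  if (length(miss)) stop("missing required gene(s): ", paste(miss, collapse = ", "))
  m <- dep$scores[, required, drop = FALSE]
  ok <- stats::complete.cases(m) & apply(is.finite(m), 1L, all)
  if (any(!ok))
    message("binarize_dependency: excluded ", sum(!ok),
            " line(s) with missing scores")
  m <- m[ok, , drop = FALSE]
  lab <- m <= threshold
  data.frame(cell_line = rownames(m), lab,
             dependent_yap_taz = lab[, "YAP1"] | lab[, "WWTR1"],
             dependent_tead = lab[, "TEAD1"] | lab[, "TEAD2"] |
                              lab[, "TEAD3"] | lab[, "TEAD4"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ROC analysis of a continuous score against binary labels
#'
#' Higher scores predict the positive class. AUC is the Mann-Whitney
#' concordance (tied score pairs count 1/2); its p-value tests AUC = 0.5 with
#' the DeLong placement variance. The optimal operating point maximizes the
#' Youden index J = sensitivity + specificity - 1 over cutoffs placed at
#' midpoints between adjacent distinct scores (J ties resolved to the lower
#' cutoff); a sample is called positive when its score is >= the cutoff.
#'
#' @param scores Numeric vector.
#' @param labels Logical vector (TRUE = positive class).
#' @return list of class \code{RocResult}: auc, auc_p, youden_j, cutoff,
#'   sensitivity, specificity, n_pos, n_neg, and a \code{curve} data.frame of
#'   (cutoff, fpr, tpr) points.
#' @export
roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) stop("both classes must be non-empty")

  # Mann-Whitney AUC via midranks (ties = 1/2).
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)

  # DeLong placements.
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  auc_p <- if (!is.finite(var_auc) || var_auc <= 0) {
    if (abs(auc - 0.5) < .Machine$double.eps^0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(auc - 0.5) / sqrt(var_auc))
  }

  sv <- sort(unique(scores))
  cutoffs <- if (length(sv) > 1L) (sv[-1L] + sv[-length(sv)]) / 2 else sv
  cutoffs <- c(sv[1L] - 1, cutoffs, sv[length(sv)] + 1)
  sens <- vapply(cutoffs, function(cc) mean(pos >= cc), 0)
  spec <- vapply(cutoffs, function(cc) mean(neg < cc), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.min(cutoffs[best])]

  structure(list(
    auc = auc, auc_p = auc_p, youden_j = j[best], cutoff = cutoffs[best],
    sensitivity = sens[best], specificity = spec[best],
    n_pos = m, n_neg = n,
    curve = data.frame(cutoff = cutoffs, fpr = 1 - spec, tpr = sens)
  ), class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (p = %.3g), J %.3f at cutoff %.3g (sens %.3f, spec %.3f), %d pos / %d neg\n",
              x$auc, x$auc_p, x$youden_j, x$cutoff, x$sensitivity,
              x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Predict YAP/TAZ and TEAD dependence from signature enrichment
#'
#' The published evaluation pipeline: score each gene set in each cell line
#' with \code{\link{gsva}}, binarize Chronos scores into YAP/TAZ- and
#' TEAD-dependence labels, and ask via ROC how well the per-line enrichment
#' score predicts each label.
#'
#' @param x \code{ExpressionMatrix} (log2p1) over cell lines.
#' @param genesets List of \code{GeneSet}s.
#' @param dep A \code{DependencyTable} sharing cell lines with \code{x}.
#' @param lineage_filter Optional lineage string; keeps only matching lines
#'   (requires \code{dep$lineage}).
#' @param threshold Chronos dependence cutoff (default -0.65).
#' @return list: \code{report} data.frame (geneset, label, n_dep, n_indep,
#'   auc, auc_p, youden_j, cutoff, sensitivity, specificity), \code{scores}
#'   (the GSVA matrix), \code{labels}, and \code{rocs} (nested RocResults).
#' @export
predict_dependency <- function(x, genesets, dep, lineage_filter = NULL,
                               threshold = -0.65) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(dep, "DependencyTable"))
  lines <- rownames(dep$scores)
  if (!is.null(lineage_filter)) {
    if (is.null(dep$lineage)) stop("no lineage metadata to filter on")
    lines <- lines[dep$lineage[lines] == lineage_filter]
  }
  shared <- intersect(colnames(x$values), lines)
  if (length(shared) < 10L)
    stop("need >=10 shared cell lines after filtering, got ", length(shared))
  labels <- binarize_dependency(
    dependency_table(dep$scores[shared, , drop = FALSE]), threshold)
  xm <- expression_matrix(x$values[, labels$cell_line, drop = FALSE],
                          x$value_space)
  scores <- gsva(xm, genesets)

  report <- list(); rocs <- list()
  for (g in rownames(scores)) {
    for (lab in c("dependent_yap_taz", "dependent_tead")) {
      y <- labels[[lab]]
      if (sum(y) < 2L) {
        warning("fewer than 2 dependent lines for ", lab, "; ROC skipped")
        next
      }
      r <- roc(scores[g, ], y)
      rocs[[g]][[lab]] <- r
      report[[length(report) + 1L]] <- data.frame(
        geneset = g, label = lab, n_dep = sum(y), n_indep = sum(!y),
        auc = r$auc, auc_p = r$auc_p, youden_j = r$youden_j,
        cutoff = r$cutoff, sensitivity = r$sensitivity,
        specificity = r$specificity, stringsAsFactors = FALSE)
    }
  }
  list(report = do.call(rbind, report), scores = scores,
       labels = labels, rocs = rocs)
}
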