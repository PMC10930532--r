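#' Differential-expression table constructor
#'
#' A per-contrast table of oriented effect sizes. \code{orientation} records
#' how the contrast was set up: \code{"activation"} means positive log2FC
#' already corresponds to higher YAP/TAZ activity (e.g. constitutively active
#' YAP vs control); \code{"depletion"} means the contrast compared control vs
#' YAP/TAZ knockdown so the sign must be flipped by \code{\link{orient}}
#' before signature derivation.
#'
#' @param gene Character vector of symbols (normalized, unique).
#' @param log2fc,p,fdr Numeric vectors, one entry per gene.
#' @param detected Logical; FALSE marks genes quantified in the anchor
#'   experiment but absent from this contrast's platform.
#' @param contrast_id Label for provenance.
#' @param orientation \code{"activation"} or \code{"depletion"}.
#' @return data.frame of class \code{DETable} with attributes
#'   \code{contrast_id}, \code{orientation}, \code{oriented}.
#' @export
de_table <- function(gene, log2fc, p, fdr, detected = TRUE,
                     contrast_id = "contrast", orientation = c("activation", "depletion")) {
  orientation <- match.arg(orientation)
  gene <- normalize_symbols(gene)
  if (anyDuplicated(gene))
    stop("duplicate genes in DE table: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) stop("fdr outside [0, 1]")
  df <- data.frame(gene = gene, log2fc = log2fc, p = p, fdr = fdr,
                   detected = rep_len(detected, length(gene)),
                   stringsAsFactors = FALSE)
  attr(df, "contrast_id") <- contrast_id
  attr(df, "orientation") <- orientation
  attr(df, "oriented") <- FALSE
  class(df) <- c("DETable", "data.frame")
  df
}

#' Read / write a DE table as TSV with a YAML metadata sidecar
#'
#' The TSV carries columns gene, log2fc, p, fdr, detected; contrast id and
#' orientation travel in a YAML sidecar (\code{<path>.yaml}) so external DE
#' results can be dropped into the pipeline.
#'
#' @param de A \code{DETable}.
#' @param path TSV path; the sidecar is written next to it.
#' @export
write_de_table <- function(de, path) {
  stopifnot(inherits(de, "DETable"))
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(contrast_id = attr(de, "contrast_id"),
                        orientation = attr(de, "orientation"),
                        oriented = attr(de, "oriented")),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_de_table
#' @return \code{read_de_table}: the \code{DETable} (orientation state
#'   restored from the sidecar).
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  de <- de_table(df$gene, df$log2fc, df$p, df$fdr, df$detected,
                 contrast_id = meta$contrast_id,
                 orientation = meta$orientation)
  attr(de, "oriented") <- isTRUE(meta$oriented)
  de
}

#' Stand-in differential expression test
#'
#' A transparent replacement for external DE pipelines, used on synthetic
#' data: log2 fold change from pseudocounted TPM group means, p-values from
#' Welch's two-sample t-test on log2(1+TPM) values, and Benjamini-Hochberg FDR
#' across all detected genes.
#'
#' @param x An \code{ExpressionMatrix} in TPM space.
#' @param group_a,group_b Character vectors of sample ids (a = numerator).
#' @param pseudocount Added to both group means before the ratio (default 1).
#' @param contrast_id,orientation Passed to \code{\link{de_table}}.
#' @return A \code{DETable}.
#' @export
standin_de <- function(x, group_a, group_b, pseudocount = 1,
                       contrast_id = "standin", orientation = "activation") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$value_space != "tpm") stop("standin_de expects TPM values")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need >=2 samples per group")
  miss <- setdiff(c(group_a, group_b), colnames(x$values))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  a <- x$values[, group_a, drop = FALSE]
  b <- x$values[, group_b, drop = FALSE]
  lfc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
  la <- log2(1 + a); lb <- log2(1 + b)
  na <- ncol(la); nb <- ncol(lb)
  va <- apply(la, 1L, stats::var); vb <- apply(lb, 1L, stats::var)
  se2 <- va / na + vb / nb
  t <- (rowMeans(la) - rowMeans(lb)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- 1  # zero-variance genes with equal means
  fdr <- stats::p.adjust(p, method = "BH")
  de_table(rownames(x$values), lfc, p, fdr, detected = TRUE,
           contrast_id = contrast_id, orientation = orientation)
}

#' Orient a DE table so positive log2FC means YAP/TAZ-induced
#'
#' Depletion contrasts (control vs knockdown where the raw sign follows the
#' knockdown direction) have their log2FC negated; activation contrasts pass
#' through unchanged. Calling orient twice is an error — orientation is a
#' one-way normalization, not an involution on the stored table.
#'
#' @param de A \code{DETable}.
#' @return The oriented \code{DETable} (attribute \code{oriented = TRUE}).
#' @export
orient <- function(de) {
  stopifnot(inherits(de, "DETable"))
  if (isTRUE(attr(de, "oriented"))) stop("DE table is already oriented")
  if (attr(de, "orientation") == "depletion") de$log2fc <- -de$log2fc
  attr(de, "oriented") <- TRUE
  de
}

#' Call regulated genes at fold-change and FDR cutoffs
#'
#' Both thresholds are strict, matching the published rule (fold change > 2,
#' FDR < 0.05): boundary genes are excluded. Undetected genes never qualify.
#'
#' @param de An oriented \code{DETable}.
#' @param fc_threshold Linear fold-change cutoff (> 1).
#' @param fdr_threshold FDR cutoff.
#' @return list(up = character, down = character).
#' @export
call_regulated <- function(de, fc_threshold = 2, fdr_threshold = 0.05) {
  stopifnot(inherits(de, "DETable"))
  if (!isTRUE(attr(de, "oriented"))) stop("orient() the table first")
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  lfc_cut <- log2(fc_threshold)
  ok <- de$detected & is.finite(de$log2fc) & is.finite(de$fdr) & de$fdr < fdr_threshold
  list(up   = de$gene[ok & de$log2fc >  lfc_cut],
       down = de$gene[ok & de$log2fc < -lfc_cut])
}
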