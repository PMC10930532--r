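#' Split samples into marker-high / marker-low groups
#'
#' Tumors are grouped on a canonical target gene (CTGF or CYR61 in the
#' melanoma cohort): high iff the marker's log2(1+TPM) value is >= mean + k*SD
#' over all samples, low iff <= mean - k*SD (both boundaries inclusive),
#' everything else "neither".
#'
#' @param x \code{ExpressionMatrix} in log2p1 space.
#' @param marker Gene symbol.
#' @param k SD multiplier (default 1).
#' @return list of class \code{MarkerGrouping}: marker, mean, sd, and
#'   \code{groups}, a named character vector over samples.
#' @export
assign_groups <- function(x, marker, k = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$value_space != "log2p1") stop("assign_groups expects log2p1 values")
  marker <- normalize_symbols(marker)
  if (!marker %in% rownames(x$values)) stop("marker ", marker, " not in matrix")
  v <- x$values[marker, ]
  mu <- mean(v); sd <- stats::sd(v)
  if (sd == 0) stop("degenerate marker: ", marker, " is constant")
  groups <- ifelse(v >= mu + k * sd, "high",
                   ifelse(v <= mu - k * sd, "low", "neither"))
  structure(list(marker = marker, mean = mu, sd = sd, k = k,
                 groups = stats::setNames(groups, colnames(x$values))),
            class = "MarkerGrouping")
}

#' Compare gene expression between marker-high and marker-low samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per gene, with
#' Benjamini-Hochberg correction across the tested genes.
#'
#' @param x \code{ExpressionMatrix} (log2p1).
#' @param grouping A \code{MarkerGrouping} over the same samples.
#' @param genes Genes to test (default: all but the marker).
#' @return data.frame: gene, median_high, median_low, p, fdr.
#' @export
group_compare <- function(x, grouping, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(grouping, "MarkerGrouping"))
  g <- grouping$groups[colnames(x$values)]
  hi <- which(g == "high"); lo <- which(g == "low")
  if (length(hi) < 3L || length(lo) < 3L)
    stop("need >=3 samples per group (", length(hi), " high, ", length(lo), " low)")
  genes <- normalize_symbols(genes %||% setdiff(rownames(x$values), grouping$marker))
  genes <- intersect(genes, rownames(x$values))
  res <- do.call(rbind, lapply(genes, function(gn) {
    a <- x$values[gn, hi]; b <- x$values[gn, lo]
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    data.frame(gene = gn, median_high = stats::median(a),
               median_low = stats::median(b), p = p, stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Spearman correlation of each gene with an anchor marker
#'
#' Spearman's rank correlation (average ranks for ties) of every requested
#' gene against the marker, with a permutation p-value: the marker profile is
#' permuted \code{nperm} times and p = (b + 1) / (nperm + 1) where b counts
#' permutations with |r_perm| >= |r|. Correlations are binned for reporting:
#' strong r >= 0.4, moderate 0.3 <= r < 0.4, weak r < 0.3. Constant genes
#' have undefined r; they are flagged, binned weak, with p = 1.
#'
#' @param x \code{ExpressionMatrix} (any value space; ranks only).
#' @param marker Anchor gene symbol.
#' @param genes Genes to correlate (default all others).
#' @param nperm Number of marker permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return data.frame of class \code{CorrelationReport}: gene, spearman_r,
#'   permutation_p, bin, flagged.
#' @export
spearman_vs_marker <- function(x, marker, genes = NULL, nperm = 1000, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  n <- ncol(x$values)
  if (n < 5L) stop("need >=5 samples")
  marker <- normalize_symbols(marker)
  if (!marker %in% rownames(x$values)) stop("marker ", marker, " not in matrix")
  genes <- normalize_symbols(genes %||% setdiff(rownames(x$values), marker))
  genes <- intersect(genes, rownames(x$values))

  rm_ <- rank(x$values[marker, ])
  gm <- x$values[genes, , drop = FALSE]
  rg <- t(apply(gm, 1L, rank))
  constant <- apply(gm, 1L, function(v) length(unique(v)) == 1L)
  # Standardize ranks once; r is then a cross-product.
  std <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  zm <- std(rm_)
  zg <- t(apply(rg, 1L, std))
  r <- as.numeric(zg %*% zm) / (n - 1)

  set.seed(seed)
  perm <- replicate(nperm, std(rm_[sample.int(n)]))
  rp <- abs(zg %*% perm) / (n - 1)  # genes x nperm
  b <- rowSums(rp >= abs(r) - 1e-12)
  p <- (b + 1) / (nperm + 1)

  r[constant] <- NA_real_
  p[constant] <- 1
  bin <- correlation_bin(r)
  data.frame(gene = genes, spearman_r = r, permutation_p = p, bin = bin,
             flagged = constant, stringsAsFactors = FALSE)
}

#' Bin correlation values
#'
#' strong = [0.4, 1], moderate = [0.3, 0.4), weak = [-1, 0.3); NA (undefined)
#' values bin weak.
#'
#' @param r Numeric vector of correlations.
#' @return Character vector of bins.
#' @export
correlation_bin <- function(r) {
  ifelse(!is.na(r) & r >= 0.4, "strong",
         ifelse(!is.na(r) & r >= 0.3, "moderate", "weak"))
}

#' Pairwise Spearman similarity matrix, sorted by anchor correlation
#'
#' All pairwise Spearman correlations between the requested genes over all
#' samples, with rows and columns ordered by each gene's correlation with the
#' anchor marker, descending — the heatmap-ready layout in which co-regulated
#' blocks cluster around the anchor.
#'
#' @param x \code{ExpressionMatrix}.
#' @param genes Genes to include (the anchor is added if absent).
#' @param anchor_marker Anchor gene symbol.
#' @return Numeric matrix (genes x genes) with attribute \code{anchor_r}, the
#'   named anchor-correlation vector used for sorting.
#' @export
similarity_matrix <- function(x, genes, anchor_marker) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  anchor_marker <- normalize_symbols(anchor_marker)
  genes <- union(normalize_symbols(genes), anchor_marker)
  genes <- intersect(genes, rownames(x$values))
  if (length(genes) < 2L) stop("need >=2 genes")
  m <- stats::cor(t(x$values[genes, , drop = FALSE]), method = "spearman")
  anchor_r <- m[, anchor_marker]
  ord <- order(-anchor_r, rownames(m))
  m <- m[ord, ord]
  attr(m, "anchor_r") <- anchor_r[ord]
  m
}

#' Venn of strongly marker-correlated genes between two reports
#'
#' Counts genes whose Spearman correlation meets the strong threshold
#' (inclusive >=) against marker A only, marker B only, or both.
#'
#' @param report_a,report_b \code{spearman_vs_marker} outputs over the same
#'   gene universe.
#' @param threshold Strong-correlation cutoff (default 0.4).
#' @return list: only_a, only_b, both (counts) and the gene vectors
#'   (genes_only_a, genes_only_b, genes_both).
#' @export
strong_correlation_venn <- function(report_a, report_b, threshold = 0.4) {
  if (!setequal(report_a$gene, report_b$gene))
    stop("reports cover different gene universes")
  report_b <- report_b[match(report_a$gene, report_b$gene), ]
  sa <- !is.na(report_a$spearman_r) & report_a$spearman_r >= threshold
  sb <- !is.na(report_b$spearman_r) & report_b$spearman_r >= threshold
  list(only_a = sum(sa & !sb), only_b = sum(sb & !sa), both = sum(sa & sb),
       genes_only_a = report_a$gene[sa & !sb],
       genes_only_b = report_a$gene[sb & !sa],
       genes_both = report_a$gene[sa & sb])
}
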