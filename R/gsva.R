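#' Single-sample gene-set enrichment scores (GSVA algorithm)
#'
#' Computes per-sample enrichment scores following the published GSVA
#' procedure. Each gene's expression profile is first turned into a smoothed
#' relative-rank via a Gaussian kernel CDF estimate,
#' z_ij = (1/n) * sum_k Phi((x_ij - x_ik) / h_i), with per-gene bandwidth
#' h_i = s_i / 4 (s_i the sample SD; zero-variance genes fall back to a tiny
#' epsilon bandwidth, which reduces to ranking by raw value). Within each
#' sample, genes are ranked by z descending (ties broken lexicographically by
#' symbol), the rank is centered into the symmetric statistic |N/2 - r_ij|,
#' and a weighted KS random walk is run down the ranked genes: set members add
#' |N/2 - r|^tau (normalized), non-members subtract 1/(N - set size). With
#' \code{mx_diff = TRUE} the score is the maximum positive deviation plus the
#' minimum negative deviation of the walk; with \code{FALSE} it is the single
#' largest deviation from zero.
#'
#' Because the kernel CDF is a monotone summary of each gene's values across
#' samples, scores are invariant to strictly increasing transforms applied to
#' any one gene's row.
#'
#' @param x An \code{ExpressionMatrix} in \code{log2p1} space (continuous
#'   expression; \code{kcdf = "gaussian"}), with at least 3 samples.
#' @param genesets List of \code{GeneSet}s or character vectors. Members
#'   absent from the matrix are dropped (with a message); sets left empty are
#'   an error.
#' @param kcdf Kernel for the CDF estimate; only \code{"gaussian"}.
#' @param tau Weight exponent on the rank statistic (default 1).
#' @param mx_diff See above (default TRUE).
#' @return Numeric matrix, gene sets x samples, with attribute
#'   \code{parameters}.
#' @export
gsva <- function(x, genesets, kcdf = "gaussian", tau = 1, mx_diff = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"), kcdf == "gaussian")
  if (x$value_space == "tpm")
    stop("gsva expects log2(1+TPM) values; apply log2p1() first")
  v <- x$values
  n <- ncol(v); N <- nrow(v)
  if (n < 3L) stop("gsva needs at least 3 samples")
  if (is.null(names(genesets)))
    names(genesets) <- vapply(genesets, function(s)
      if (inherits(s, "GeneSet")) s$name else "set", "")
  members <- lapply(genesets, function(s) {
    g <- if (inherits(s, "GeneSet")) s$genes else normalize_symbols(s)
    keep <- intersect(g, rownames(v))
    if (length(keep) < length(g))
      message(sprintf("gsva: dropped %d gene(s) absent from the matrix",
                      length(g) - length(keep)))
    keep
  })
  if (any(lengths(members) == 0L))
    stop("geneset(s) with no genes in the matrix: ",
         paste(names(genesets)[lengths(members) == 0L], collapse = ", "))

  z <- kcdf_gaussian(v)
  scores <- matrix(NA_real_, length(genesets), n,
                   dimnames = list(names(genesets), colnames(v)))
  genes <- rownames(v)
  for (j in seq_len(n)) {
    ord <- order(-z[, j], genes)            # rank 1 = highest z
    r <- integer(N); r[ord] <- seq_len(N)
    stat <- abs(N / 2 - r)^tau
    stat_ord <- stat[ord]
    for (s in seq_along(members)) {
      hit_idx <- which(genes[ord] %in% members[[s]])
      walk <- es_walk(stat_ord, hit_idx, N)
      rs <- walk$running_sum
      scores[s, j] <- if (mx_diff) max(0, max(rs)) + min(0, min(rs))
                      else walk$es
    }
  }
  attr(scores, "parameters") <- list(kcdf = kcdf, tau = tau, mx_diff = mx_diff)
  scores
}

# Gaussian kernel CDF estimate per gene row; bandwidth s_i/4 with an epsilon
# floor for constant rows.
kcdf_gaussian <- function(v, eps = 1e-8) {
  h <- pmax(apply(v, 1L, stats::sd) / 4, eps)
  z <- v
  for (i in seq_len(nrow(v))) {
    d <- outer(v[i, ], v[i, ], "-") / h[i]
    z[i, ] <- rowMeans(stats::pnorm(d))
  }
  z
}
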