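#' Rank genes by a class-separation metric
#'
#' Builds the rank-ordered list that the enrichment statistics walk over.
#' The default metric is signal-to-noise, (mu_a - mu_b) / (sd_a + sd_b), with
#' each class standard deviation floored at 0.2 * |class mean| (and at a small
#' epsilon when the mean is zero) — the conventional desktop-tool floor that
#' keeps low-variance genes from dominating the ranking. Ties are broken
#' lexicographically by symbol so the ordering is deterministic.
#'
#' @param x An \code{ExpressionMatrix} with \code{sample_meta}.
#' @param phenotype_a,phenotype_b Phenotype labels; a is the "activity-high"
#'   class, so positive metric means higher in a.
#' @param metric Only \code{"signal2noise"} is implemented.
#' @return data.frame of class \code{RankedList} (columns \code{gene},
#'   \code{metric}), sorted descending.
#' @export
rank_genes <- function(x, phenotype_a, phenotype_b, metric = "signal2noise") {
  stopifnot(inherits(x, "ExpressionMatrix"), metric == "signal2noise")
  if (is.null(x$sample_meta)) stop("expression matrix has no phenotype labels")
  lab <- x$sample_meta$phenotype_label
  a <- x$values[, lab == phenotype_a, drop = FALSE]
  b <- x$values[, lab == phenotype_b, drop = FALSE]
  if (ncol(a) == 0L) stop("no samples with phenotype ", phenotype_a)
  if (ncol(b) == 0L) stop("no samples with phenotype ", phenotype_b)
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("signal2noise needs >=2 samples per class")
  s2n <- signal2noise(a, b)
  ranked_list(rownames(x$values), s2n, metric_name = metric)
}

# Signal-to-noise per gene row between two sample blocks, with the
# sigma >= max(0.2|mu|, eps) floor applied per class.
signal2noise <- function(a, b, eps = 1e-8) {
  floor_sd <- function(m) {
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    list(mu = mu, sd = pmax(sd, 0.2 * abs(mu), eps))
  }
  fa <- floor_sd(a); fb <- floor_sd(b)
  (fa$mu - fb$mu) / (fa$sd + fb$sd)
}

#' Construct a ranked list
#'
#' @param genes Symbols (normalized; must be unique).
#' @param metric Numeric ranking metric, same length.
#' @param metric_name Label recorded on the object.
#' @return data.frame of class \code{RankedList}, sorted by metric descending
#'   with lexicographic tie-break.
#' @export
ranked_list <- function(genes, metric, metric_name = "metric") {
  genes <- normalize_symbols(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in ranked list")
  ord <- order(-metric, genes)
  df <- data.frame(gene = genes[ord], metric = metric[ord],
                   stringsAsFactors = FALSE)
  attr(df, "metric_name") <- metric_name
  class(df) <- c("RankedList", "data.frame")
  df
}

# Weighted KS running sum over hit positions. absw = |metric|^weight in
# ranked order; returns the signed maximum deviation and the walk itself.
es_walk <- function(absw, hit_idx, N) {
  nh <- length(hit_idx)
  w <- absw[hit_idx]
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep(1 / nh, nh)  # all-zero metric: equal steps
  step <- numeric(N)
  step[hit_idx] <- w
  if (N > nh) step[-hit_idx] <- -1 / (N - nh)
  rs <- cumsum(step)
  i <- which.max(abs(rs))
  list(es = rs[i], running_sum = rs, peak = i)
}

#' GSEA enrichment score for one gene set
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: walking down the ranked
#' list, hits add |metric|^weight (normalized to sum to 1 over hits) and
#' misses subtract 1/(N - N_hits); the enrichment score is the signed maximum
#' deviation from zero. The leading edge is the hit genes at or before the
#' extremum (at or after it, for negative scores).
#'
#' @param ranked A \code{RankedList}.
#' @param geneset A \code{GeneSet} or character vector.
#' @param weight Exponent on |metric| (1 = classic weighted GSEA, 0 =
#'   unweighted KS).
#' @return list(es, running_sum, leading_edge).
#' @export
gsea_es <- function(ranked, geneset, weight = 1) {
  stopifnot(inherits(ranked, "RankedList"))
  genes <- if (inherits(geneset, "GeneSet")) geneset$genes
           else normalize_symbols(geneset)
  hit_idx <- which(ranked$gene %in% genes)
  if (length(hit_idx) == 0L) stop("geneset not represented in the ranked list")
  N <- nrow(ranked)
  walk <- es_walk(abs(ranked$metric)^weight, hit_idx, N)
  le <- if (walk$es >= 0) hit_idx[hit_idx <= walk$peak]
        else hit_idx[hit_idx >= walk$peak]
  list(es = walk$es, running_sum = walk$running_sum,
       leading_edge = ranked$gene[le])
}

#' Two-class GSEA with permutation-based NES and FDR
#'
#' Ranks genes by signal-to-noise between two phenotype classes, computes the
#' weighted KS enrichment score for each gene set, and assesses significance
#' against a permutation null. With \code{perm_type = "auto"} the published
#' rule is applied: phenotype (label) permutation when both classes have at
#' least 8 samples, gene-set permutation (random gene sets of equal size
#' sampled from the ranked genes) otherwise. NES divides each observed score
#' by the mean |permutation score| of matching sign; the nominal p-value is
#' the add-one-smoothed same-sign permutation tail, and FDR q follows the
#' pooled positive/negative NES scheme of the original GSEA method.
#'
#' @param x An \code{ExpressionMatrix} with phenotype labels.
#' @param phenotype_a,phenotype_b Class labels (a = activity-high).
#' @param genesets List of \code{GeneSet}s (or character vectors).
#' @param nperm Number of permutations (>= 10).
#' @param perm_type \code{"auto"}, \code{"phenotype"}, or \code{"geneset"}.
#' @param weight Hit-weight exponent (default 1).
#' @param seed Integer seed; results are reproducible given it.
#' @return data.frame (one row per gene set): name, size, es, nes, nominal_p,
#'   fdr_q, pct_leading_edge, leading_edge (comma-joined). Attribute
#'   \code{perm_type} records the mode used.
#' @export
gsea <- function(x, phenotype_a, phenotype_b, genesets, nperm = 1000,
                 perm_type = c("auto", "phenotype", "geneset"), weight = 1,
                 seed = 1L) {
  perm_type <- match.arg(perm_type)
  if (nperm < 10) stop("nperm must be at least 10")
  if (length(genesets) == 0L) stop("no genesets")
  if (is.null(names(genesets)))
    names(genesets) <- vapply(genesets, function(s)
      if (inherits(s, "GeneSet")) s$name else "set", "")
  lab <- x$sample_meta$phenotype_label
  na <- sum(lab == phenotype_a); nb <- sum(lab == phenotype_b)
  if (perm_type == "auto")
    perm_type <- if (na >= 8 && nb >= 8) "phenotype" else "geneset"

  ranked <- rank_genes(x, phenotype_a, phenotype_b)
  N <- nrow(ranked)
  absw <- abs(ranked$metric)^weight
  members <- lapply(genesets, function(s) {
    g <- if (inherits(s, "GeneSet")) s$genes else normalize_symbols(s)
    intersect(g, ranked$gene)
  })
  sizes <- lengths(members)
  if (any(sizes == 0L))
    stop("geneset(s) not represented: ",
         paste(names(genesets)[sizes == 0L], collapse = ", "))

  obs <- lapply(members, function(g) gsea_es(ranked, g, weight))
  es <- vapply(obs, `[[`, 0, "es")

  set.seed(seed)
  perm_es <- matrix(NA_real_, length(genesets), nperm)
  if (perm_type == "geneset") {
    for (j in seq_len(nperm)) {
      for (i in seq_along(genesets)) {
        idx <- sort(sample.int(N, sizes[i]))
        perm_es[i, j] <- es_walk(absw, idx, N)$es
      }
    }
  } else {
    idx_a <- which(lab == phenotype_a)
    all_ab <- c(idx_a, which(lab == phenotype_b))
    vals <- x$values[, all_ab, drop = FALSE]
    for (j in seq_len(nperm)) {
      pa <- sample(seq_along(all_ab), length(idx_a))
      s2n <- signal2noise(vals[, pa, drop = FALSE], vals[, -pa, drop = FALSE])
      rl <- ranked_list(rownames(vals), s2n)
      aw <- abs(rl$metric)^weight
      for (i in seq_along(genesets)) {
        idx <- which(rl$gene %in% members[[i]])
        perm_es[i, j] <- es_walk(aw, idx, N)$es
      }
    }
  }

  # Per-geneset sign-matched normalization constants.
  norm_const <- function(i, sign_pos) {
    v <- perm_es[i, ]
    v <- v[if (sign_pos) v >= 0 else v < 0]
    if (length(v) == 0L) return(NA_real_)
    mean(abs(v))
  }
  nes <- numeric(length(es))
  nominal_p <- numeric(length(es))
  for (i in seq_along(es)) {
    pos <- es[i] >= 0
    same <- perm_es[i, if (pos) perm_es[i, ] >= 0 else perm_es[i, ] < 0]
    nc <- norm_const(i, pos)
    nes[i] <- if (is.na(nc) || nc == 0) NA_real_ else es[i] / nc
    nominal_p[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
  }
  # Pooled-NES FDR: normalize every permutation score by its geneset's
  # matching-sign constant, pool across genesets, and compare tails.
  perm_nes <- perm_es
  for (i in seq_along(es)) {
    cpos <- norm_const(i, TRUE); cneg <- norm_const(i, FALSE)
    pos <- perm_es[i, ] >= 0
    perm_nes[i, pos] <- if (is.na(cpos)) NA else perm_es[i, pos] / cpos
    perm_nes[i, !pos] <- if (is.na(cneg)) NA else perm_es[i, !pos] / cneg
  }
  pool <- perm_nes[is.finite(perm_nes)]
  fdr_q <- vapply(seq_along(es), function(i) {
    if (!is.finite(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[is.finite(nes) & nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[is.finite(nes) & nes < 0] <= nes[i])
    }
    if (!is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, 0)

  res <- data.frame(
    name = names(genesets), size = as.integer(sizes), es = es, nes = nes,
    nominal_p = nominal_p, fdr_q = fdr_q,
    pct_leading_edge = 100 * vapply(obs, function(o)
      length(o$leading_edge), 0L) / sizes,
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "perm_type") <- perm_type
  res
}

#' Percent rank of genes in a ranked list
#'
#' pct = 100 * rank / N with rank 1 the most activity-enriched gene. Bins:
#' top (pct <= 15, enriched with activity), bottom (pct >= 85, enriched
#' against activity), mid otherwise; genes not in the list are "absent".
#'
#' @param ranked A \code{RankedList}.
#' @param genes Character vector (or \code{GeneSet}) to look up.
#' @return data.frame: gene, pct (NA when absent), bin.
#' @export
percent_rank <- function(ranked, genes) {
  stopifnot(inherits(ranked, "RankedList"), nrow(ranked) > 0L)
  genes <- if (inherits(genes, "GeneSet")) genes$genes else normalize_symbols(genes)
  N <- nrow(ranked)
  pos <- match(genes, ranked$gene)
  pct <- 100 * pos / N
  bin <- ifelse(is.na(pct), "absent",
                ifelse(pct <= 15, "top", ifelse(pct >= 85, "bottom", "mid")))
  data.frame(gene = genes, pct = pct, bin = bin, stringsAsFactors = FALSE)
}
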