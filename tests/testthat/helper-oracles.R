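# Independent oracles, deliberately written as plain step-by-step loops so
# they share no code path with the package implementations they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted KS enrichment score by explicit walk over the ranked list.
oracle_es <- function(metric, genes, set, weight = 1) {
  N <- length(genes)
  hits <- genes %in% set
  nh <- sum(hits)
  denom <- sum(abs(metric[hits])^weight)
  cur <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      cur <- cur + (if (denom > 0) abs(metric[i])^weight / denom else 1 / nh)
    } else {
      cur <- cur - 1 / (N - nh)
    }
    if (abs(cur) > abs(best)) best <- cur
  }
  best
}

# O(n^2) pairwise-concordance AUC with ties counted 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# Transparent two-pass single-sample enrichment: explicit kernel-CDF table,
# per-sample ranks, then a literal random walk.
oracle_gsva <- function(v, set, tau = 1, mx_diff = TRUE) {
  N <- nrow(v); n <- ncol(v)
  z <- matrix(0, N, n)
  for (i in seq_len(N)) {
    h <- stats::sd(v[i, ]) / 4
    if (h == 0) h <- 1e-8
    for (j in seq_len(n)) z[i, j] <- mean(stats::pnorm((v[i, j] - v[i, ]) / h))
  }
  scores <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(-z[, j], rownames(v))
    walk <- 0; mx <- 0; mn <- 0; best <- 0
    r <- integer(N); r[ord] <- seq_len(N)
    stat <- abs(N / 2 - r)^tau
    hits <- rownames(v) %in% set
    denom <- sum(stat[hits])
    nmiss <- N - sum(hits)
    for (k in ord) {
      walk <- walk + if (hits[k]) stat[k] / denom else -1 / nmiss
      if (walk > mx) mx <- walk
      if (walk < mn) mn <- walk
      if (abs(walk) > abs(best)) best <- walk
    }
    scores[j] <- if (mx_diff) mx + mn else best
  }
  scores
}

# Small two-class TPM fixture with known group means.
toy_expression <- function(seed = 42, n_genes = 30, per_group = 3) {
  set.seed(seed)
  v <- matrix(stats::rexp(n_genes * 2 * per_group, rate = 0.1),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%d", seq_len(2 * per_group))))
  meta <- data.frame(sample_id = colnames(v),
                     phenotype_label = rep(c("a", "b"), each = per_group),
                     stringsAsFactors = FALSE)
  expression_matrix(v, "tpm", meta)
}
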