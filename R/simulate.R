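#' Simulate a TPM expression matrix with planted activity-responsive genes
#'
#' Gene-level log2 expression is baseline_g + beta * a_s for planted
#' up-responsive genes, baseline_g - beta * a_s for planted down-responsive
#' genes, plus Gaussian noise; baselines are N(4, 2) on the log2 scale and
#' TPM = 2^x - 1 clipped at zero. The per-sample activity a_s is either a
#' two-class indicator (activity-high samples get a_s = 1, low get 0 — the
#' constitutive-activation vs control design) or a continuous latent
#' N(0, 1) factor.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param n_up,n_down Numbers of planted up/down-responsive genes (defaults
#'   80 and 52, the composition of the consensus melanoma signature).
#' @param beta Effect size in log2 units per unit activity.
#' @param noise_sd Residual SD in log2 units.
#' @param activity \code{"two_class"} or \code{"latent"}.
#' @param seed RNG seed (mandatory; generators never touch global state
#'   beyond \code{set.seed}).
#' @return list: \code{matrix} (an \code{ExpressionMatrix} in TPM space with
#'   phenotype labels "high"/"low" in the two-class design) and \code{truth}
#'   (planted up/down gene ids and the activity vector).
#' @export
simulate_expression <- function(n_genes = 2000, n_samples = 40, n_up = 80,
                                n_down = 52, beta = 2, noise_sd = 0.5,
                                activity = c("two_class", "latent"),
                                seed) {
  activity <- match.arg(activity)
  if (n_up + n_down > n_genes) stop("more planted genes than genes")
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  planted <- sample(genes, n_up + n_down)
  up <- sort(planted[seq_len(n_up)])
  down <- sort(planted[n_up + seq_len(n_down)])
  samples <- sprintf("S%03d", seq_len(n_samples))
  a <- if (activity == "two_class")
    rep(c(1, 0), c(ceiling(n_samples / 2), floor(n_samples / 2)))
  else stats::rnorm(n_samples)
  baseline <- stats::rnorm(n_genes, 4, 2)
  eff <- numeric(n_genes)
  eff[genes %in% up] <- beta
  eff[genes %in% down] <- -beta
  x <- baseline + outer(eff, a) +
    matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes)
  tpm <- pmax(2^x - 1, 0)
  dimnames(tpm) <- list(genes, samples)
  meta <- if (activity == "two_class")
    data.frame(sample_id = samples,
               phenotype_label = ifelse(a == 1, "high", "low"),
               stringsAsFactors = FALSE)
  else data.frame(sample_id = samples, phenotype_label = "cohort",
                  stringsAsFactors = FALSE)
  list(matrix = expression_matrix(tpm, "tpm", meta),
       truth = list(up = up, down = down, activity = stats::setNames(a, samples)))
}

#' Simulate a suite of oriented DE contrasts with partial overlap
#'
#' Emulates the multi-cell-line design behind the consensus signature: one
#' anchor contrast in which every planted gene responds, plus
#' \code{n_supports} supporting contrasts in which each planted gene responds
#' independently with a per-support inclusion probability. The last support
#' is emitted with \code{orientation = "depletion"} and its raw log2FC
#' sign-flipped, emulating a knockdown-design contrast that \code{orient()}
#' must normalize. Responsive genes get log2FC beta (up) or -beta (down) plus
#' noise and a near-zero p-value; background genes get null effects and
#' uniform p-values; FDR is Benjamini-Hochberg within each contrast.
#'
#' @param n_genes Total genes per contrast.
#' @param n_up,n_down Planted set sizes (defaults 80 / 52).
#' @param n_supports Number of supporting contrasts (default 3).
#' @param inclusion_probs Per-support probability that a planted gene is
#'   responsive there (scalar recycled; default 0.8).
#' @param beta Responsive log2FC magnitude (default 2).
#' @param noise_sd SD of log2FC noise (default 0.25; keep beta - 3*noise_sd
#'   above log2(fold cutoff) for clean recovery).
#' @param detect_prob Probability a gene is detected in a support (default 1;
#'   lower values emulate platform dropouts, which count as non-supporting).
#' @param seed RNG seed.
#' @return list: \code{anchor} (oriented-convention \code{DETable},
#'   orientation "activation"), \code{supports} (list of \code{DETable}s,
#'   last one "depletion"), \code{truth}.
#' @export
simulate_contrast_suite <- function(n_genes = 2000, n_up = 80, n_down = 52,
                                    n_supports = 3, inclusion_probs = 0.8,
                                    beta = 2, noise_sd = 0.25,
                                    detect_prob = 1, seed) {
  set.seed(seed)
  inclusion_probs <- rep_len(inclusion_probs, n_supports)
  genes <- sprintf("G%05d", seq_len(n_genes))
  planted <- sample(genes, n_up + n_down)
  up <- sort(planted[seq_len(n_up)])
  down <- sort(planted[n_up + seq_len(n_down)])

  make_contrast <- function(id, responsive_up, responsive_down, depletion) {
    lfc <- stats::rnorm(n_genes, 0, noise_sd)
    p <- stats::runif(n_genes)
    iu <- genes %in% responsive_up
    idn <- genes %in% responsive_down
    lfc[iu] <- beta + stats::rnorm(sum(iu), 0, noise_sd)
    lfc[idn] <- -beta + stats::rnorm(sum(idn), 0, noise_sd)
    p[iu | idn] <- stats::runif(sum(iu | idn), 1e-10, 1e-6)
    detected <- stats::runif(n_genes) <= detect_prob
    fdr <- stats::p.adjust(p, method = "BH")
    if (depletion) lfc <- -lfc  # raw sign convention of a knockdown contrast
    de_table(genes, lfc, p, fdr, detected, contrast_id = id,
             orientation = if (depletion) "depletion" else "activation")
  }
  anchor <- make_contrast("anchor", up, down, depletion = FALSE)
  supports <- lapply(seq_len(n_supports), function(i) {
    ru <- up[stats::runif(n_up) <= inclusion_probs[i]]
    rd <- down[stats::runif(n_down) <= inclusion_probs[i]]
    make_contrast(paste0("support", i), ru, rd,
                  depletion = (i == n_supports))
  })
  list(anchor = anchor, supports = supports,
       truth = list(up = up, down = down))
}

#' Simulate a cell-line cohort with expression-linked dependency
#'
#' Emulates the DepMap melanoma analysis: dependent cell lines sit in the
#' upper tail of the latent YAP/TAZ-activity factor (a_s ~ N(activity_shift,
#' 1) vs N(0, 1)), planted signature genes respond to a_s in log2(1+TPM)
#' space, and Chronos scores for WWTR1 are drawn from class-specific normals
#' whose defaults (-1.0 dependent, -0.1 independent, SD 0.15) put the -0.65
#' cutoff between the classes with negligible mass on the wrong side. Default
#' composition mirrors the melanoma cohort: 62 lines, 17 dependent (all via
#' WWTR1; subsets of 9 and 1 additionally dependent on TEAD1 and TEAD4, and
#' 2 on YAP1).
#'
#' @param n_cell_lines,n_dependent Cohort composition (defaults 62 / 17).
#' @param n_genes Background gene count (default 500).
#' @param up_genes,down_genes Optional planted gene-id vectors (e.g. from
#'   \code{simulate_contrast_suite} truth); otherwise sampled fresh with
#'   sizes \code{n_up}/\code{n_down}.
#' @param n_up,n_down Planted set sizes when ids are not supplied.
#' @param beta,noise_sd Expression model parameters (log2 units).
#' @param activity_shift Mean activity of dependent lines (default 2; with
#'   the expression defaults the per-line enrichment score is a nearly
#'   noiseless readout of a_s, so its class shift is ~2 score-SDs).
#' @param chronos_mean_dep,chronos_mean_indep,chronos_sd Chronos score model.
#' @param seed RNG seed.
#' @return list: \code{matrix} (log2p1 \code{ExpressionMatrix}),
#'   \code{dependency} (\code{DependencyTable} with YAP1/WWTR1/TEAD1-4 and
#'   lineage "melanoma"), \code{truth}.
#' @export
simulate_dependency_cohort <- function(n_cell_lines = 62, n_dependent = 17,
                                       n_genes = 500, up_genes = NULL,
                                       down_genes = NULL, n_up = 80,
                                       n_down = 52, beta = 2, noise_sd = 0.5,
                                       activity_shift = 2,
                                       chronos_mean_dep = -1,
                                       chronos_mean_indep = -0.1,
                                       chronos_sd = 0.15, seed) {
  if (n_dependent >= n_cell_lines) stop("n_dependent must be < n_cell_lines")
  set.seed(seed)
  if (is.null(up_genes) || is.null(down_genes)) {
    genes <- sprintf("G%05d", seq_len(n_genes))
    planted <- sample(genes, n_up + n_down)
    up_genes <- sort(planted[seq_len(n_up)])
    down_genes <- sort(planted[n_up + seq_len(n_down)])
  } else {
    up_genes <- normalize_symbols(up_genes)
    down_genes <- normalize_symbols(down_genes)
    genes <- union(sprintf("G%05d", seq_len(n_genes)),
                   c(up_genes, down_genes))
  }
  lines <- sprintf("LINE%03d", seq_len(n_cell_lines))
  dep_lines <- sort(sample(lines, n_dependent))
  is_dep <- lines %in% dep_lines
  a <- stats::rnorm(n_cell_lines, ifelse(is_dep, activity_shift, 0), 1)

  baseline <- stats::rnorm(length(genes), 4, 2)
  eff <- numeric(length(genes))
  eff[genes %in% up_genes] <- beta
  eff[genes %in% down_genes] <- -beta
  x <- baseline + outer(eff, a) +
    matrix(stats::rnorm(length(genes) * n_cell_lines, 0, noise_sd),
           length(genes))
  x <- pmax(x, 0)  # log2(1+TPM) is non-negative
  dimnames(x) <- list(genes, lines)

  draw <- function(dep_subset) {
    d <- lines %in% dep_subset
    stats::rnorm(n_cell_lines,
                 ifelse(d, chronos_mean_dep, chronos_mean_indep), chronos_sd)
  }
  yap_dep <- dep_lines[seq_len(min(2, n_dependent))]
  tead1_dep <- dep_lines[seq_len(min(9, n_dependent))]
  tead4_dep <- dep_lines[n_dependent]
  chronos <- cbind(YAP1 = draw(yap_dep), WWTR1 = draw(dep_lines),
                   TEAD1 = draw(tead1_dep), TEAD2 = draw(character()),
                   TEAD3 = draw(character()), TEAD4 = draw(tead4_dep))
  rownames(chronos) <- lines
  meta <- data.frame(sample_id = lines,
                     phenotype_label = ifelse(is_dep, "dependent", "independent"),
                     lineage = "melanoma", stringsAsFactors = FALSE)
  list(matrix = expression_matrix(x, "log2p1", meta),
       dependency = dependency_table(
         chronos, stats::setNames(rep("melanoma", n_cell_lines), lines)),
       truth = list(up = up_genes, down = down_genes,
                    dependent_lines = dep_lines,
                    activity = stats::setNames(a, lines)))
}

#' Simulate a tumor cohort with planted marker correlations
#'
#' Each gene is generated jointly with the anchor marker from a Gaussian
#' copula whose Pearson parameter is chosen so that the population Spearman
#' correlation equals the planted target: for bivariate normals
#' rho_S = (6/pi) * asin(r/2), inverted as r = 2 * sin(pi * rho_S / 6)
#' (naive Pearson planting would bias the Spearman target). Latents are
#' mapped to log2(1+TPM) by a per-gene linear (hence monotone) transform.
#'
#' @param rho Named numeric vector: planted Spearman targets per gene.
#' @param n_samples Cohort size (default 300, echoing the 303-tumor melanoma
#'   cohort).
#' @param marker Anchor marker name (default "CTGF").
#' @param n_background Extra genes with rho = 0 (default 0).
#' @param seed RNG seed.
#' @return list: \code{matrix} (log2p1 \code{ExpressionMatrix} containing the
#'   marker row) and \code{truth} (the planted rho, including backgrounds).
#' @export
simulate_tumor_cohort <- function(rho, n_samples = 300, marker = "CTGF",
                                  n_background = 0, seed) {
  if (any(abs(rho) > 1)) stop("|rho| must be <= 1")
  if (is.null(names(rho)) && length(rho)) stop("rho must be named by gene")
  set.seed(seed)
  if (n_background > 0) {
    bg <- stats::setNames(rep(0, n_background),
                          sprintf("BG%04d", seq_len(n_background)))
    rho <- c(rho, bg)
  }
  marker <- normalize_symbols(marker)
  zm <- stats::rnorm(n_samples)
  r <- 2 * sin(pi * rho / 6)
  z <- vapply(seq_along(rho), function(i)
    r[i] * zm + sqrt(1 - r[i]^2) * stats::rnorm(n_samples),
    numeric(n_samples))
  mu <- stats::rnorm(length(rho), 6, 1)
  x <- t(z) * 1 + mu          # per-gene monotone map to expression scale
  x <- rbind(x, 6 + zm)
  rownames(x) <- c(names(rho), marker)
  colnames(x) <- sprintf("T%04d", seq_len(n_samples))
  x <- pmax(x, 0)
  meta <- data.frame(sample_id = colnames(x), phenotype_label = "tumor",
                     stringsAsFactors = FALSE)
  list(matrix = expression_matrix(x, "log2p1", meta),
       truth = list(rho = rho, marker = marker))
}

#' Simulate a compact gene model
#'
#' Genes laid end to end along a few chromosomes with wide intergenic gaps
#' (so promoter windows never collide), random strand, and 2-6 exons each.
#'
#' @param n_genes Number of genes.
#' @param n_chrom Number of chromosomes.
#' @param seed RNG seed.
#' @return A \code{GeneModel} with gene ids \code{G00001...}.
#' @export
simulate_gene_model <- function(n_genes = 200, n_chrom = 4, seed) {
  set.seed(seed)
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  chrom <- paste0("chr", 1 + (seq_len(n_genes) - 1) %% n_chrom)
  len <- sample(2000:20000, n_genes, replace = TRUE)
  start <- integer(n_genes)
  pos <- stats::setNames(rep(10000L, n_chrom), unique(chrom))
  for (i in seq_len(n_genes)) {
    start[i] <- pos[[chrom[i]]]
    pos[[chrom[i]]] <- start[i] + len[i] + 30000L  # gap >> promoter window
  }
  end <- start + len
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  exon_starts <- vector("list", n_genes)
  exon_ends <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    k <- sample(2:6, 1L)
    cuts <- sort(sample(seq(start[i], end[i] - 1L), 2L * k))
    exon_starts[[i]] <- cuts[seq(1L, 2L * k, 2L)]
    exon_ends[[i]] <- cuts[seq(2L, 2L * k, 2L)]
  }
  gene_model(gene_id, chrom, strand, start, end, exon_starts, exon_ends)
}

#' Simulate ChIP-seq peak datasets with promoter-planted targets
#'
#' Per dataset, each target gene receives a promoter peak with probability
#' \code{promoter_rate}, each non-target gene with \code{background_rate}.
#' Peaks are 200-600 bp wide, centered within +/-400 bp of the TSS so they
#' fall inside the default +/-1 kb promoter window.
#'
#' @param model A \code{GeneModel}.
#' @param target_genes Planted target gene ids.
#' @param n_datasets Number of datasets (default 8).
#' @param promoter_rate,background_rate Per-gene peak probabilities.
#' @param seed RNG seed.
#' @return list: \code{peaks} (named list of BED-style data.frames) and
#'   \code{truth} (target gene ids).
#' @export
simulate_peaks <- function(model, target_genes, n_datasets = 8,
                           promoter_rate = 0.9, background_rate = 0.05, seed) {
  stopifnot(inherits(model, "GeneModel"))
  if (promoter_rate < 0 || promoter_rate > 1 ||
      background_rate < 0 || background_rate > 1)
    stop("rates must be in [0, 1]")
  target_genes <- normalize_symbols(target_genes)
  set.seed(seed)
  is_target <- model$gene_id %in% target_genes
  peaks <- lapply(seq_len(n_datasets), function(d) {
    rate <- ifelse(is_target, promoter_rate, background_rate)
    take <- stats::runif(nrow(model)) <= rate
    idx <- which(take)
    if (length(idx) == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        stringsAsFactors = FALSE))
    width <- sample(200:600, length(idx), replace = TRUE)
    center <- model$tss[idx] + sample(-400:400, length(idx), replace = TRUE)
    start <- pmax(center - width %/% 2L, 0L)
    data.frame(chrom = model$chrom[idx], start = start, end = start + width,
               name = sprintf("peak_%d_%d", d, seq_along(idx)),
               stringsAsFactors = FALSE)
  })
  names(peaks) <- sprintf("dataset%02d", seq_len(n_datasets))
  list(peaks = peaks, truth = list(targets = sort(intersect(target_genes,
                                                            model$gene_id))))
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth A truth list from any generator.
#' @param path Output path (conventionally \code{truth.json}).
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
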