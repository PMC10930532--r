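#' Default pipeline configuration
#'
#' All thresholds default to the published settings: fold change > 2 and
#' FDR < 0.05 for the signature, Chronos <= -0.65 for dependence, +/-1 kb TSS
#' window for promoters, mean +/- 1 SD marker grouping, 1000 permutations.
#'
#' @param seed Base seed; each stochastic stage derives its own stream seed.
#' @param out_dir Output directory.
#' @return Named list understood by \code{\link{run_pipeline}}.
#' @export
default_run_config <- function(seed = 1L, out_dir = "results/pipeline") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("signature", "enrichment", "dependency", "correlation", "peaks"),
    fc_threshold = 2, fdr_threshold = 0.05,
    min_support = 2, n_supports = 3, inclusion_probs = 0.8,
    chronos_threshold = -0.65,
    tss_window = 1000, downstream_window = 3000,
    group_k = 1, nperm = 1000,
    n_genes = 2000, n_up = 80, n_down = 52,
    n_cell_lines = 62, n_dependent = 17, dep_n_genes = 500,
    n_tumors = 300, rho_up = 0.6, rho_down = 0.1,
    n_model_genes = 200, n_peak_datasets = 8,
    promoter_rate = 0.9, background_rate = 0.05
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order — consensus signature derivation,
#' two-class GSEA of the signature in the dependency cohort, GSVA + ROC
#' dependency prediction, tumor-cohort marker correlation, and ChIP-peak
#' annotation — over inputs drawn by the synthetic-data generators, and
#' writes every stage report as plain TSV/JSON plus a run manifest. Outputs
#' are byte-identical across reruns with the same config.
#'
#' @param config A config list (see \code{\link{default_run_config}}) or a
#'   path to a YAML file with the same fields.
#' @return The manifest (invisibly), also written to
#'   \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_run_config()
  config <- utils::modifyList(defaults, config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out, "run_config.yaml"))
  outputs <- list()
  tsv <- function(df, name) {
    path <- file.path(out, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- path
    path
  }

  # --- signature ------------------------------------------------------------
  suite <- simulate_contrast_suite(
    n_genes = config$n_genes, n_up = config$n_up, n_down = config$n_down,
    n_supports = config$n_supports, inclusion_probs = config$inclusion_probs,
    seed = derive_seed(config$seed, "contrasts"))
  sig <- derive_consensus(orient(suite$anchor), lapply(suite$supports, orient),
                          min_support = config$min_support,
                          fc_threshold = config$fc_threshold,
                          fdr_threshold = config$fdr_threshold)
  if ("signature" %in% config$stages) {
    write_signature(sig, file.path(out, "signature.gmt"),
                    file.path(out, "signature_provenance.tsv"))
    outputs[["signature.gmt"]] <- file.path(out, "signature.gmt")
    up_calls <- c(list(anchor = call_regulated(orient(suite$anchor),
                                               config$fc_threshold,
                                               config$fdr_threshold)$up),
                  lapply(suite$supports, function(s)
                    call_regulated(orient(s), config$fc_threshold,
                                   config$fdr_threshold)$up))
    names(up_calls) <- c("anchor", sprintf("support%d",
                                           seq_along(suite$supports)))
    jsonlite::write_json(as.list(venn_counts(up_calls)),
                         file.path(out, "venn_up.json"), auto_unbox = TRUE)
    outputs[["venn_up.json"]] <- file.path(out, "venn_up.json")
  }

  # --- dependency cohort (shared by enrichment + ROC stages) ---------------
  cohort <- simulate_dependency_cohort(
    n_cell_lines = config$n_cell_lines, n_dependent = config$n_dependent,
    n_genes = config$dep_n_genes,
    up_genes = sig$up$genes, down_genes = sig$down$genes,
    seed = derive_seed(config$seed, "dependency"))

  if ("enrichment" %in% config$stages) {
    enr <- gsea(cohort$matrix, "dependent", "independent",
                list(sig$up, sig$down), nperm = config$nperm,
                seed = derive_seed(config$seed, "gsea"))
    tsv(enr[, setdiff(names(enr), "leading_edge")], "gsea_report.tsv")
    rl <- rank_genes(cohort$matrix, "dependent", "independent")
    pr <- percent_rank(rl, c(sig$up$genes, sig$down$genes))
    tsv(pr, "percent_rank.tsv")
  }

  if ("dependency" %in% config$stages) {
    pred <- predict_dependency(cohort$matrix, list(sig$up, sig$down),
                               cohort$dependency,
                               threshold = config$chronos_threshold)
    tsv(pred$report, "roc_report.tsv")
    tsv(data.frame(geneset = rownames(pred$scores), pred$scores,
                   check.names = FALSE), "gsva_scores.tsv")
  }

  # --- tumor cohort ---------------------------------------------------------
  if ("correlation" %in% config$stages) {
    rho <- c(stats::setNames(rep(config$rho_up, length(sig$up$genes)),
                             sig$up$genes),
             stats::setNames(rep(config$rho_down, length(sig$down$genes)),
                             sig$down$genes),
             CYR61 = 0.7)
    tum <- simulate_tumor_cohort(rho, n_samples = config$n_tumors,
                                 marker = "CTGF", n_background = 100,
                                 seed = derive_seed(config$seed, "tumors"))
    grouping <- assign_groups(tum$matrix, "CTGF", k = config$group_k)
    tsv(data.frame(sample = names(grouping$groups), group = grouping$groups),
        "marker_groups.tsv")
    cmp <- group_compare(tum$matrix, grouping, sig$up$genes)
    tsv(cmp, "group_compare.tsv")
    rep_a <- spearman_vs_marker(tum$matrix, "CTGF", sig$up$genes,
                                nperm = config$nperm,
                                seed = derive_seed(config$seed, "perm"))
    rep_b <- spearman_vs_marker(tum$matrix, "CYR61", sig$up$genes,
                                nperm = config$nperm,
                                seed = derive_seed(config$seed, "perm"))
    tsv(rep_a, "correlation_ctgf.tsv")
    tsv(rep_b, "correlation_cyr61.tsv")
    sim <- similarity_matrix(tum$matrix, sig$up$genes, "CTGF")
    tsv(data.frame(gene = rownames(sim), sim, check.names = FALSE),
        "similarity_matrix.tsv")
    venn <- strong_correlation_venn(rep_a, rep_b)
    jsonlite::write_json(venn[c("only_a", "only_b", "both")],
                         file.path(out, "strong_correlation_venn.json"),
                         auto_unbox = TRUE)
    outputs[["strong_correlation_venn.json"]] <-
      file.path(out, "strong_correlation_venn.json")
  }

  # --- peaks ----------------------------------------------------------------
  if ("peaks" %in% config$stages) {
    model <- simulate_gene_model(config$n_model_genes,
                                 seed = derive_seed(config$seed, "peaks"))
    targets <- model$gene_id[seq_len(min(config$n_up, nrow(model)))]
    pk <- simulate_peaks(model, targets,
                         n_datasets = config$n_peak_datasets,
                         promoter_rate = config$promoter_rate,
                         background_rate = config$background_rate,
                         seed = derive_seed(config$seed, "peaks") + 1L)
    ann <- lapply(pk$peaks, annotate_peaks, model = model,
                  tss_window = config$tss_window,
                  downstream_window = config$downstream_window)
    mat <- gene_peak_matrix(ann, model$gene_id, model)
    tsv(data.frame(gene = rownames(mat), mat, check.names = FALSE),
        "peak_matrix.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("yaptazsig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = config$stages,
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
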