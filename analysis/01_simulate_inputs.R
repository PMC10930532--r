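#!/usr/bin/env Rscript
# Generate every synthetic study input in the on-disk formats the analysis
# stages read: four oriented DE contrasts (one knockdown-style), a 62-line
# cell-line cohort with Chronos dependency scores, a 300-tumor cohort with
# marker-correlated signature genes, and 8 ChIP-seq peak datasets over a
# compact gene model. Ground truth is serialized next to each dataset.

suppressPackageStartupMessages(library(yaptazsig))
seed <- 20240216L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("== contrasts ==")
suite <- simulate_contrast_suite(inclusion_probs = 1, noise_sd = 0,
                                 seed = seed)
write_de_table(suite$anchor, file.path(out, "contrast_anchor.tsv"))
for (i in seq_along(suite$supports))
  write_de_table(suite$supports[[i]],
                 file.path(out, sprintf("contrast_support%d.tsv", i)))
write_sim_truth(suite$truth, file.path(out, "contrast_truth.json"))
message("  4 contrasts over 2000 genes; planted ",
        length(suite$truth$up), " up / ", length(suite$truth$down), " down")

message("== dependency cohort ==")
co <- simulate_dependency_cohort(up_genes = suite$truth$up,
                                 down_genes = suite$truth$down,
                                 seed = seed + 1L)
write_expression(co$matrix, file.path(out, "cellline_log2tpm.tsv"))
write.table(co$matrix$sample_meta, file.path(out, "cellline_phenotypes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.csv(data.frame(cell_line = rownames(co$dependency$scores),
                     co$dependency$scores, check.names = FALSE),
          file.path(out, "chronos_scores.csv"), row.names = FALSE)
write.csv(data.frame(cell_line = names(co$dependency$lineage),
                     lineage = co$dependency$lineage),
          file.path(out, "cellline_lineage.csv"), row.names = FALSE)
write_sim_truth(co$truth[c("dependent_lines", "up", "down")],
                file.path(out, "dependency_truth.json"))
message("  ", ncol(co$matrix$values), " cell lines, ",
        length(co$truth$dependent_lines), " truly dependent")

message("== tumor cohort ==")
rho <- c(setNames(rep(0.6, length(suite$truth$up)), suite$truth$up),
         setNames(rep(0.1, length(suite$truth$down)), suite$truth$down),
         CYR61 = 0.7)
tum <- simulate_tumor_cohort(rho, n_samples = 300, marker = "CTGF",
                             n_background = 200, seed = seed + 2L)
write_expression(tum$matrix, file.path(out, "tumor_log2tpm.tsv"))
write_sim_truth(tum$truth, file.path(out, "tumor_truth.json"))
message("  300 tumors; signature-up genes planted at rho = 0.6 vs CTGF")

message("== gene model + ChIP peaks ==")
model <- simulate_gene_model(200, seed = seed + 3L)
write_gene_model(model, file.path(out, "gene_model.tsv"))
set.seed(seed + 4L)
targets <- sort(sample(model$gene_id, 80))
pk <- simulate_peaks(model, targets, n_datasets = 8,
                     promoter_rate = 0.9, background_rate = 0.05,
                     seed = seed + 5L)
for (d in names(pk$peaks))
  write_bed(pk$peaks[[d]], file.path(out, paste0("peaks_", d, ".bed")))
write_sim_truth(pk$truth, file.path(out, "peak_truth.json"))
message("  8 datasets; ", length(targets), " promoter-planted target genes")
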