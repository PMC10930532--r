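#!/usr/bin/env Rscript
# Marker-anchored validation in the tumor cohort: split tumors on CTGF
# (mean +/- 1 SD), compare signature-gene expression between groups, rank
# genes by Spearman correlation with CTGF and CYR61 (permutation-tested),
# build the sorted pairwise similarity matrix, and count the r >= 0.4 Venn.

suppressPackageStartupMessages(library(yaptazsig))
data_dir <- "results/data"
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tum <- read_expression(file.path(data_dir, "tumor_log2tpm.tsv"), "plain",
                       value_space = "log2p1")
sig_sets <- read_gmt(file.path(out, "signature.gmt"))
up <- sig_sets$YAP_TAZ_UP$genes

grouping <- assign_groups(tum, "CTGF", k = 1)
message(sprintf("CTGF grouping: %d high / %d low / %d neither",
                sum(grouping$groups == "high"), sum(grouping$groups == "low"),
                sum(grouping$groups == "neither")))
write.table(data.frame(sample = names(grouping$groups),
                       group = grouping$groups),
            file.path(out, "ctgf_groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cmp <- group_compare(tum, grouping, up)
write.table(cmp, file.path(out, "ctgf_group_compare.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%.0f%% of signature-up genes higher in CTGF-high tumors at FDR<0.05",
                100 * mean(cmp$fdr < 0.05 & cmp$median_high > cmp$median_low)))

rep_ctgf <- spearman_vs_marker(tum, "CTGF", up, nperm = 1000, seed = 21L)
rep_cyr61 <- spearman_vs_marker(tum, "CYR61", up, nperm = 1000, seed = 22L)
write.table(rep_ctgf, file.path(out, "correlation_ctgf.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rep_cyr61, file.path(out, "correlation_cyr61.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("strong (r>=0.4) vs CTGF: %d genes; vs CYR61: %d genes",
                sum(rep_ctgf$bin == "strong"), sum(rep_cyr61$bin == "strong")))

sim <- similarity_matrix(tum, up, "CTGF")
write.table(data.frame(gene = rownames(sim), sim, check.names = FALSE),
            file.path(out, "similarity_matrix_ctgf.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

venn <- strong_correlation_venn(rep_ctgf, rep_cyr61)
jsonlite::write_json(venn[c("only_a", "only_b", "both")],
                     file.path(out, "strong_correlation_venn.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message(sprintf("r>=0.4 venn: CTGF-only %d, CYR61-only %d, both %d",
                venn$only_a, venn$only_b, venn$both))
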