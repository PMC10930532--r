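#!/usr/bin/env Rscript
# Annotate each ChIP-seq peak dataset to genes with the strand-aware
# Promoter > Exon > Intron > Downstream > Intergenic cascade (+/-1 kb TSS
# window) and assemble the binary gene x dataset peak matrix; report how well
# a majority-of-datasets rule recovers the promoter-planted target genes.

suppressPackageStartupMessages(library(yaptazsig))
data_dir <- "results/data"
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- read_gene_model(file.path(data_dir, "gene_model.tsv"))
bed_files <- list.files(data_dir, "^peaks_.*\\.bed$", full.names = TRUE)
ann <- lapply(bed_files, function(f) annotate_peaks(read_bed(f), model))
names(ann) <- sub("^peaks_(.*)\\.bed$", "\\1", basename(bed_files))

for (d in names(ann)) {
  write.table(ann[[d]], file.path(out, paste0("annotation_", d, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cats <- table(unlist(lapply(ann, `[[`, "category")))
message("category totals across datasets: ",
        paste(names(cats), cats, sep = "=", collapse = ", "))

mat <- gene_peak_matrix(ann, model$gene_id, model)
write.table(data.frame(gene = rownames(mat), mat, check.names = FALSE),
            file.path(out, "peak_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path(data_dir, "peak_truth.json"),
                             simplifyVector = TRUE)
called <- rownames(mat)[rowSums(mat) >= length(ann) / 2]
message(sprintf(
  "majority-rule target recovery: sensitivity %.2f, FDR %.2f (%d called)",
  mean(truth$targets %in% called),
  if (length(called)) mean(!(called %in% truth$targets)) else 0,
  length(called)))
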