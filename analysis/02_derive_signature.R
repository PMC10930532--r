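#!/usr/bin/env Rscript
# Derive the consensus up/down signature from the four oriented contrasts:
# a gene qualifies if it clears the >2-fold / FDR<0.05 cutoffs in the anchor
# line and in at least two supporting lines, in a consistent direction after
# orientation. Writes the signature GMT, per-gene provenance, and the Venn
# region counts of the per-contrast up-calls.

suppressPackageStartupMessages(library(yaptazsig))
data_dir <- "results/data"
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

anchor <- orient(read_de_table(file.path(data_dir, "contrast_anchor.tsv")))
supports <- lapply(list.files(data_dir, "contrast_support[0-9]+\\.tsv$",
                              full.names = TRUE),
                   function(f) orient(read_de_table(f)))

sig <- derive_consensus(anchor, supports, min_support = 2)
write_signature(sig, file.path(out, "signature.gmt"),
                file.path(out, "signature_provenance.tsv"))

truth <- jsonlite::read_json(file.path(data_dir, "contrast_truth.json"),
                             simplifyVector = TRUE)
message(sprintf("consensus signature: %d up / %d down (planted %d / %d)",
                length(sig$up$genes), length(sig$down$genes),
                length(truth$up), length(truth$down)))
message(sprintf("planted-up recovery: %.1f%%, planted-down recovery: %.1f%%",
                100 * mean(truth$up %in% sig$up$genes),
                100 * mean(truth$down %in% sig$down$genes)))

up_calls <- c(list(anchor = call_regulated(anchor)$up),
              setNames(lapply(supports, function(s) call_regulated(s)$up),
                       sprintf("support%d", seq_along(supports))))
venn <- venn_counts(up_calls)
jsonlite::write_json(as.list(venn), file.path(out, "venn_up.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("up-call venn regions written; union size ", sum(venn))
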