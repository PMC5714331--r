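#!/usr/bin/env Rscript
# Stage 1: draw the study cohort.
#
# Generates the default synthetic cohort — 179 assays x 27 samples in four
# progression groups (NGT 9, NP-IGT 4, P-IGT 5, T2D 9), group concentration
# shifts, a shared latent concentration factor with group-dependent loading
# dispersion, Table-2-like differential effects, LOD censoring at Ct 37 —
# and writes it in the same text formats the reader accepts, so every later
# stage can run from files alone.

suppressPackageStartupMessages(library(miRpanel))

seed <- 1
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
coh <- generate_cohort(cfg)

write_ct_table(coh$ct, file.path(out, "ct_panel.tsv"))
write.table(coh$annotations, file.path(out, "annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(coh$qc_meta, file.path(out, "qc_metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(coh$spikein, file.path(out, "spikein.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(coh$truth$de, file.path(out, "truth_de.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d assays x %d samples (seed %d)\n",
            nrow(coh$ct), ncol(coh$ct), seed))
cat(sprintf("groups: %s\n",
            paste(names(table(coh$annotations$group)),
                  table(coh$annotations$group), collapse = ", ")))
cat(sprintf("undetected cells before QC: %d (%.1f%%)\n",
            sum(is.na(coh$ct)), 100 * mean(is.na(coh$ct))))
cat(sprintf("injected differential effects: %d assay/group pairs\n",
            nrow(coh$truth$de)))
cat("wrote cohort files under", out, "\n")
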