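#!/usr/bin/env Rscript
# Stage 4 — per-protein differential testing.
#
# Poisson log-linear group-effect deviance test with BH adjustment across
# proteins, pairwise pooled t-tests for the three contrasts, and log2
# pseudocounted changes of each fluoxetine arm against CORT/V.

suppressPackageStartupMessages(library(flxsig))
cm <- read_count_matrix("results/03_inference/counts.tsv",
                        "results/03_inference/design.tsv")

res <- test_differential(cm)
dir.create("results/04_differential", showWarnings = FALSE, recursive = TRUE)
write_flx_table(res, "results/04_differential/differential.tsv")

message(sprintf("group effect: %d proteins at p<0.05 (%d at q<0.05) of %d",
                sum(res$p_group < 0.05), sum(res$q_group < 0.05),
                nrow(res)))
message(sprintf("pairwise p<0.05: R-vs-CORT %d, NR-vs-CORT %d, R-vs-NR %d",
                sum(res$p_r_vs_cort < 0.05), sum(res$p_nr_vs_cort < 0.05),
                sum(res$p_r_vs_nr < 0.05)))
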