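#!/usr/bin/env Rscript
# Stage 5 — Venn partition, directional correlations, signature selection.
#
# Partitions the proteins significantly changed by fluoxetine in each arm,
# correlates responder vs non-responder log2 changes over the Venn subsets,
# and applies the three-criterion rule: significant R-vs-NR, significant
# R-vs-CORT/V, and opposite direction or greater amplitude in responders.

suppressPackageStartupMessages(library(flxsig))
res <- read_flx_table("results/04_differential/differential.tsv")
truth <- read_flx_table("results/01_simulate/proteome_truth.tsv")

alpha <- 0.05
set_r <- res$accession[res$p_r_vs_cort < alpha]
set_nr <- res$accession[res$p_nr_vs_cort < alpha]
venn <- venn_partition(set_r, set_nr)
print(venn)

dr <- setNames(res$delta_r, res$accession)
dnr <- setNames(res$delta_nr, res$accession)
for (sub in c("solely_r", "solely_nr", "common")) {
  members <- venn[[sub]]
  if (length(members) >= 3) {
    cr <- directional_correlation(dr, dnr, subset = members)
    message(sprintf("%s (n=%d): Pearson r = %.3f, p = %.3g",
                    sub, cr$n, cr$r, cr$p_value))
  }
}

sig <- select_signature(res, alpha = alpha)
dir.create("results/05_signature", showWarnings = FALSE, recursive = TRUE)
write_flx_table(data.frame(subset = names(venn$counts),
                           n = as.integer(venn$counts)),
                "results/05_signature/venn.tsv")
write_flx_table(sig, "results/05_signature/signature.tsv")

m <- merge(sig, truth, by = "accession")
planted <- m$class %in% c("signature_opposite", "signature_amplified")
message(sprintf("signature: %d selected of %d R-vs-NR significant proteins",
                sum(sig$selected), sum(sig$p_r_vs_nr < alpha)))
message(sprintf("recovery of planted signature classes: %.2f; null false-selection %.3f",
                mean(m$selected[planted]),
                mean(m$selected[m$class == "null"])))
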