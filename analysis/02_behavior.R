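#!/usr/bin/env Rscript
# Stage 2 — emotionality scoring, response classification, animal selection.
#
# Z-scores each measure against the same-session vehicle controls, averages
# within and then across the three tests, applies the 50% improvement rule,
# and picks the most affected 5/7/6 animals per group for proteomics.

suppressPackageStartupMessages(library(flxsig))
rec <- read_flx_table("results/01_simulate/behavior_records.tsv")

scores <- emotionality(zscore_measures(rec))
labels <- classify_response(scores)
selected <- select_most_affected(scores, labels)

dir.create("results/02_behavior", showWarnings = FALSE, recursive = TRUE)
write_flx_table(scores, "results/02_behavior/emotionality.tsv")
write_flx_table(labels, "results/02_behavior/response_labels.tsv")
write_flx_table(selected, "results/02_behavior/selected_animals.tsv")

s1 <- scores[scores$session == 1, ]
s2 <- scores[scores$session == 2, ]
message(sprintf("session-1 emotionality: VEH/V %.2f, CORT/V %.2f, CORT/Flx %.2f",
                mean(s1$emotionality[s1$group == "VEH/V"]),
                mean(s1$emotionality[s1$group == "CORT/V"]),
                mean(s1$emotionality[s1$group == "CORT/Flx"])))
resp <- labels$label == "responder"
message(sprintf("responders: %d/%d (%.1f%%); mean change %.2f (R) vs %+.2f (NR)",
                sum(resp), nrow(labels), responder_rate(labels),
                mean(labels$pre_score[resp] - labels$post_score[resp]),
                mean(labels$post_score[!resp] - labels$pre_score[!resp])))
truth <- read_flx_table("results/01_simulate/behavior_latent_truth.tsv")
m <- merge(labels, truth, by = "animal_id")
message(sprintf("latent responders: %d/%d; 50%%-rule agreement %.2f",
                sum(m$latent_responder), nrow(m),
                mean((m$label == "responder") == m$latent_responder)))
message(sprintf("selected for proteomics: %s",
                paste(names(table(selected$proteome_group)),
                      table(selected$proteome_group),
                      sep = "=", collapse = ", ")))
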