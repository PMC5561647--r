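#!/usr/bin/env Rscript
# Stage 1 — generate the study cohort and proteome.
#
# Behavioral arms mirror the corticosterone design: 14 vehicle controls,
# 12 corticosterone/vehicle, 46 corticosterone/fluoxetine, two sessions
# (week-4 baseline, week-9 post-treatment), with a latent 65.2% responder
# subpopulation. The proteome gets 938 proteins at spectral-count rates
# 5-50 with planted null / common-fluoxetine / arm-specific / signature
# classes over 5 + 7 + 6 samples.

suppressPackageStartupMessages(library(flxsig))
dir.create("results", showWarnings = FALSE)

seed <- 20170816L
beh <- simulate_behavior(behavioral_sim_config(seed = seed))
prot <- simulate_psms(proteome_sim_config(seed = seed + 1L))

dir.create("results/01_simulate", showWarnings = FALSE, recursive = TRUE)
write_flx_table(beh$records, "results/01_simulate/behavior_records.tsv")
write_flx_table(beh$truth, "results/01_simulate/behavior_latent_truth.tsv")
write_flx_table(prot$psms, "results/01_simulate/psms.tsv")
write_flx_table(prot$design, "results/01_simulate/proteome_design.tsv")
write_flx_table(prot$truth, "results/01_simulate/proteome_truth.tsv")

message(sprintf("cohort: %d animals x 2 sessions; latent responders %d/%d",
                length(unique(beh$records$animal_id)),
                sum(beh$truth$latent_responder), nrow(beh$truth)))
message(sprintf("proteome: %d PSM rows over %d proteins, %d samples",
                nrow(prot$psms), nrow(prot$truth), nrow(prot$design)))
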