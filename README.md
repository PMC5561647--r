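# flxsig

Who responds to an antidepressant, and what does their blood say about it?
In the chronic-corticosterone mouse model of anxiety/depression, chronic
fluoxetine normalizes behavior in only a subset of animals — much like the
roughly two-thirds clinical response rate to a first-line SSRI. `flxsig`
implements the complete analysis chain for that question:

1. **Behavioral emotionality scoring.** Each measure of a three-test
   battery (elevated plus maze, novelty suppressed feeding, splash test) is
   standardized against same-session vehicle controls,
   `z = s·(X − μ)/σ`, oriented so larger z means higher emotionality, then
   averaged first within and then across tests for equal test weighting.
2. **Responder classification.** A treated animal is a responder
   (CORT/Flx-R) when its emotionality score drops by at least 50% between
   the pre- and post-treatment sessions, the clinical definition of
   response; otherwise CORT/Flx-NR. The "most affected" 5/7/6 animals per
   group are selected for proteomics.
3. **Protein inference from PSM tables.** Peptide-spectrum matches are
   filtered (peptide E < 0.01, protein E < 1e−4, ≥ 2 distinct peptides),
   proteins sharing peptides are grouped (connected components of the
   protein–peptide graph), subgroups with specific peptides become the
   quantified units, and spectral counts are summed per protein × sample.
4. **Differential testing.** Per protein, a closed-form Poisson log-linear
   likelihood-ratio test of the group effect (χ², groups − 1 df) with
   Benjamini–Hochberg adjustment, plus pairwise pooled t-tests and log2
   pseudocounted changes `δ_g = log2((ȳ_g + ½)/(ȳ_CORT/V + ½))`.
5. **Signature selection.** A protein is response-associated when it
   differs significantly between responders and non-responders *and*
   between responders and CORT/V, *and* its change is either opposite in
   direction between the arms or of greater amplitude in responders.
6. **Multivariate views.** UPGMA/Euclidean biclustering of
   row-standardized log abundances and PCA with per-group bivariate-normal
   score densities.

Because no raw data are deposited for this design, the package includes a
first-class synthetic-data generator (`simulate_behavior()`,
`simulate_psms()`) producing cohorts with a latent ~65% responder
subpopulation and proteomes with planted null / common-fluoxetine /
arm-specific / signature effect classes, so every stage is testable against
known truth.

## Worked example

```r
library(flxsig)

cohort <- simulate_behavior(behavioral_sim_config(seed = 1))
scores <- emotionality(zscore_measures(cohort$records))
labels <- classify_response(scores)
sprintf("responders: %d/%d (%.1f%%)",
        sum(labels$label == "responder"), nrow(labels),
        responder_rate(labels))
#> responders: 24/46 (52.2%)

prot <- simulate_psms(proteome_sim_config(n_proteins = 938, seed = 2))
filt <- filter_identifications(prot$psms)
cm <- build_count_matrix(filt, group_proteins(filt), prot$design)
cm
#> Spectral-count matrix: 938 proteins x 18 samples
#> Groups: CORT/Flx-NR (n=6), CORT/Flx-R (n=7), CORT/V (n=5)

res <- test_differential(cm)
sum(res$p_group < 0.05)
#> [1] 316

venn_partition(res$accession[res$p_r_vs_cort < 0.05],
               res$accession[res$p_nr_vs_cort < 0.05])
#> Fluoxetine-effect Venn partition:
#>   R-significant 253 | NR-significant 266 | common 180
#>   solely-R 73 | solely-NR 86 | union 339

sig <- select_signature(res)
table(merge(sig[sig$selected, ], prot$truth, by = "accession")$class)
#>          common_flx             nr_only                null              r_only
#>                   3                   2                   5                  47
#> signature_amplified  signature_opposite
#>                  21                  28
```

Reading the output: with one simulated 46-animal treated cohort, 24 animals
cleared the 50% improvement cut-off (the latent rate is 65.2%; a single
cohort's observed rate scatters around it). Of 938 simulated proteins, 316
show a Poisson group effect at p < 0.05; the pairwise-significant sets
overlap heavily (180 of a 339-protein union), reflecting that most
fluoxetine effects are shared by responders and non-responders. The
signature rule selects 106 proteins, dominated by the planted
responder-only, opposite-direction and amplified classes — the classes that
genuinely carry response information — with only 5 of 657 planted nulls
slipping in.

## The analysis workflow

`analysis/` contains the pipeline as numbered drivers, each a thin script
over the package functions, writing tab-delimited tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort + proteome with planted truth
Rscript analysis/02_behavior.R      # z-scores, 50% rule, animal selection
Rscript analysis/03_inference.R     # PSM filtering, grouping, count matrix
Rscript analysis/04_differential.R  # Poisson LRT + BH, pairwise t, deltas
Rscript analysis/05_signature.R     # Venn, correlations, signature rule
Rscript analysis/06_multivariate.R  # UPGMA dendrograms, PCA scores
```

The same stages can be run in one call with a manifest via
`run_pipeline(run_config(out_dir, seed))`; identical configuration and seed
reproduce every output byte-for-byte.

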