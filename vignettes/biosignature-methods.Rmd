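---
title: "Methods: emotionality scoring and a spectral-count biosignature of antidepressant response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotionality scoring and a spectral-count biosignature of antidepressant response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flxsig)
```

# The problem

Chronic corticosterone in the drinking water gives mice a reproducible
anxiety/depression-like phenotype, and chronic fluoxetine reverses it — but
only in a subset of animals, much as roughly half to two thirds of patients
respond to a first-line antidepressant. `flxsig` implements the full
analysis chain for studying that split: a composite *behavioral
emotionality* score built from three tests, a clinical-style 50%
improvement rule separating responders (CORT/Flx-R) from non-responders
(CORT/Flx-NR), and a label-free spectral-counting proteomic comparison of
peripheral blood mononuclear cells (PBMCs) from the most affected animals
of each group, ending in a short list of proteins whose behavior tracks
response rather than mere drug exposure.

Because no raw behavioral tables or mass-spectrometry identifications are
publicly deposited for this design, the package ships a synthetic-data
generator that reproduces the statistical structure the analysis assumes.
All statistical guarantees quoted below are measured on that generator,
with known ground truth.

# Behavioral emotionality

## The z-score composite

Each raw measure $X$ is standardized against the vehicle control group of
the *same session*,

$$z = s \cdot \frac{X - \mu}{\sigma},$$

where $\mu$ and $\sigma$ are the control mean and (n−1) standard deviation
and $s \in \{+1, -1\}$ orients the measure so that larger $z$ always means
higher emotionality: less open-arm time and fewer open-arm entries in the
elevated plus maze (EPM), longer latency to feed in novelty suppressed
feeding (NSF), less grooming in the splash test (ST). Food consumed after
the NSF is carried along as an appetite-confound control but never scored.

Per-measure z-scores are averaged *within* each test, and the three
per-test values are then averaged with equal weight. The two-stage average
matters: with EPM z-scores $\{1, 3\}$, NSF $\{2\}$ and ST $\{0\}$ the
composite is $(2 + 2 + 0)/3 = 4/3$, not the flat mean $1.5$ — a test
contributing two measures does not get double weight. By construction the
control cohort has composite mean exactly 0, and the composite is invariant
to affine rescaling of any raw measure.

Two referencing choices were genuinely open and are settled as follows.
First, $\mu, \sigma$ come from same-session controls (rather than session-1
or pooled controls) so that any drift in the assay between week 4 and week
9 is absorbed by the reference. Second, $\sigma$ uses the unbiased (n−1)
estimator. Both are configurable only by editing the scoring call, not
buried options.

A caution that the synthetic cohorts make vivid: with a realistic control
group of ~14 animals and a right-skewed measure such as NSF latency, the
estimated $\sigma$ is itself noisy, and an unlucky control draw can inflate
every z-score of that measure for the session. Across repeated cohorts the
responder rate is recovered without bias (see the generator section), but
any *single* cohort's rate carries substantial sampling error — worth
remembering when comparing one cohort's percentage to another study's.

## Response classification and animal selection

A treated animal is a responder when its emotionality dropped by at least
half between sessions: $(\text{pre} - \text{post})/\text{pre} \ge 0.5$,
mirroring the clinical definition of response as a 50% rating-scale
decrease. The rule is monotone in the post score and ill-defined for
non-positive baselines (z composites can be negative), so animals with
pre-score ≤ 0 are labeled `not_applicable`; by default they stay in the
cohort-rate denominator, counted as not responding, so that a 46-animal
cohort with 30 responders reports 65.2% regardless of degenerate baselines.
An optional exclusion band around the cutoff can drop behaviorally
ambiguous animals; it defaults to width 0 because no principled width is
available.

The "most affected" animals carried into proteomics (defaults 5 CORT/V, 7
responders, 6 non-responders) are chosen deterministically: CORT/V and
non-responders by descending post-treatment emotionality (still most
emotional), responders by descending relative improvement (clearest
response), ties broken by animal id. No published criterion exists for this
selection, so the ranking is an explicit, configurable argument rather than
a hidden rule.

# From peptide-spectrum matches to counts

Identification filtering keeps PSMs with peptide E-value < 0.01 (strict)
and proteins with E-value < 1e−4 and at least two distinct retained peptide
sequences; contaminant accessions are dropped by list or prefix. Distinct
peptides are compared as sequence strings, so modified forms collapse.

Proteins sharing at least one retained peptide are grouped — groups are the
connected components of the protein–peptide bipartite graph (computed with
`igraph`, and cross-checked in the test suite against a hand-written
union-find oracle). Within a group, any protein with at least one specific
peptide is a *subgroup*, the reported quantification unit. Spectral counts
are summed per subgroup and sample from specific peptides only
("unique-only" mode), so no spectrum is ever counted twice; a "group-level"
mode adds one row per group including shared-peptide spectra for users who
prefer group-level quantification. The choice of unique-only as default is
conservative: shared spectra cannot be attributed to a single protein
without a model, and discarding them biases no contrast.

# Differential testing

Spectral counts are modeled per protein as Poisson with one rate per group.
The group-effect test is the likelihood-ratio deviance against an
intercept-only model, referred to $\chi^2$ with (groups − 1) degrees of
freedom. Because the group MLEs are just group means, the fit is
closed-form — no iterative solver — and the implementation is verified
against `glm(..., family = poisson)` to 1e−10 in the tests. The model is
fixed-effects only: the design has one observation per animal and no
random-effect structure is identifiable from it. An optional total-count
offset (library-size normalization) is available but off by default; with
roughly constant per-sample depth it changes little, and the default keeps
the analysis on the raw counts the quantification produces.

Benjamini–Hochberg adjustment is applied to the group-effect p-values only.
The three pairwise contrasts (R vs CORT/V, NR vs CORT/V, R vs NR) use
two-sided pooled-variance Student's t-tests on the per-sample counts at raw
p < 0.05 — a deliberately two-tier scheme: a multiplicity-controlled screen
for *any* group effect, then uncorrected pairwise calls used for set
partitioning. Degenerate rows are handled explicitly: all-zero rows report
p = 1 with a flag, zero-pooled-variance t-tests report p = 1 (equal means)
or p = 0 (unequal, flagged).

Direction and amplitude of change use $\delta_g = \log_2((\bar{y}_g +
c)/(\bar{y}_{\text{ref}} + c))$ with pseudocount $c = 0.5$, which keeps
ratios finite for zero means while barely perturbing counts in the 5–50
range.

Measured operating characteristics (fixed seeds, re-run by the acceptance
script): on an all-null proteome of 5000 proteins at rates 5–50 with 5/7/6
samples per group, the deviance test rejects 4–7% of proteins at p < 0.05
and BH leaves essentially nothing at q < 0.05. The 5000-protein size makes
the binomial standard error of the rejection rate ~0.3%, tight enough to
detect miscalibration while running in seconds.

# Venn partition, correlations, signature rule

Proteins significant in R vs CORT/V and in NR vs CORT/V form two sets whose
partition (common, solely-R, solely-NR, union) is exact set algebra;
Pearson correlations of $\delta_R$ vs $\delta_{NR}$ over these subsets
quantify how similarly the two arms respond to the drug.

The signature rule then asks which proteins track *response* rather than
exposure. A protein is selected when all three hold:

1. significantly different between responders and non-responders,
2. significantly different between responders and CORT/V,
3. its direction of change is either **opposite** in the two arms
   ($\operatorname{sign}\delta_R \cdot \operatorname{sign}\delta_{NR} < 0$,
   both nonzero) or of **greater amplitude** in responders (same sign,
   $|\delta_R| > |\delta_{NR}|$).

Amplitude is compared on the log2 pseudocounted scale as a point estimate;
no statistical superiority of $|\delta_R|$ is required, since the R-vs-NR
significance criterion already guards the comparison. Changes below 1e−12
in magnitude count as neither opposite nor amplified. The selected set is
by construction a subset of the R-vs-NR significant set, and the rule is
symmetric under a global sign flip of all deltas. On the default synthetic
proteome (2000 proteins, planted |log2FC| = 1.5), selection recovers ≥ 80%
of the planted opposite/amplified signature proteins with a false-selection
rate among nulls below 1%.

# Multivariate views

Hierarchical bivariate clustering uses Euclidean distances and unweighted
pair-group average linkage (UPGMA) on proteins and samples independently.
Counts are log2(count + 0.5) transformed and row-standardized by default,
so the clustered quantity is above- vs below-average expression per
protein; without a published preprocessing recipe, this is the conventional
heatmap normalization and is exposed as a flag. Agglomeration ties are
resolved by `stats::hclust`'s deterministic smallest-index rule; the merge
trees are verified against a naive O(n³) UPGMA oracle in the tests.

PCA runs on centered (not scaled) log abundances of the sample profiles,
and each group's scores on the first two components are summarized by a
bivariate normal (mean vector and covariance), from which density contours
can be drawn. The parametric summary — rather than kernel smoothing — is
the honest choice for 5–7 samples per group.

# The synthetic-data generator

The behavioral generator draws, per animal and session, the five raw
measures around realistic vehicle baselines (60 ± 20 s open-arm time,
10 ± 3 entries, log-normal latency with median 150 s censored at the
10-minute ceiling, 80 ± 25 s grooming, 8 ± 2 mg/g food). Corticosterone
shifts every scored measure by `cort_effect_sd` (default 2) control-SDs in
its emotionality-increasing direction; at session 2, latent responders
(Bernoulli 0.652, the observed cohort rate) recover 90% of the shift while
non-responders recover none and drift a further 0.25 SD upward, mimicking
the published mean worsening of refractory animals. Times are truncated at
zero, entry counts rounded, latency right-censored at the ceiling — which
also means censoring compresses the latency z-score exactly as it does in
real scoring, where censored latencies enter at the ceiling value.

What this emulates: group-structured measures with a latent responder
subpopulation, direction conventions, censoring, and the referencing
pitfalls of small control groups. What it does not: within-animal
correlation across tests beyond the shared latent shift, bimodality of
individual measures, appetite effects, or any pharmacokinetics — so passing
tests demonstrate the *analysis* is correct under the assumed structure,
not that the model captures all behavior of real cohorts.

The proteome generator gives each protein a log-uniform baseline rate in
5–50 expected spectra, an effect class, and a random direction. Classes
(defaults: 70% null, 12% common-fluoxetine, 5% responder-only, 7%
non-responder-only, 3% opposite-direction, 3% amplified) multiply the
fluoxetine-arm rates by $2^{\pm 1.5}$; the amplified class gives
non-responders half the responder log2 effect. Counts are Poisson — matching
the analysis model; a negative-binomial option exists, off by default, for
robustness experiments — distributed over each protein's 2+ specific
peptides, with a configurable fraction of additional two-protein shared
peptides carrying their own small counts so grouping is exercised without
perturbing unique-only quantification. Identification scores are drawn to
pass the thresholds; filtering failures are injected explicitly by tests.
Regenerating with the same seed is byte-identical.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use 5000 proteins for the null
calibration, 2000 for signature recovery, 500 treated animals for the
responder-rate Monte-Carlo check, and ≤ 50 proteins / ≤ 12 leaves / n ≤ 8
for the brute-force oracle equivalences — sizes chosen so each check has
enough resolution to catch real defects (binomial SEs of a few tenths of a
percent for the calibration rates) while the whole suite runs in well under
a minute per check. Pseudocount 0.5, the 1e−12 zero-delta guard, strict
threshold inequalities, and lexicographic tie-breaking are all stated at
their point of use above.

# Limitations

The pipeline treats spectral counts as Poisson; real spectral counts are
often overdispersed, and the generator's negative-binomial switch exists
precisely to explore how the error rates degrade. The pairwise t-tests on
counts of 5–7 samples lean on approximate normality; the test suite bounds
their disagreement with exact permutation enumeration on small fixtures.
The published protein totals from the original cohort (1245 detected, 938
after the two-peptide rule, 305 group-effect proteins, the specific
19-protein list) depend on undeposited raw data and are used here only as
worked-example arithmetic (set sizes, rates, fractions), never as
quantities the synthetic pipeline is tuned to reproduce.
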