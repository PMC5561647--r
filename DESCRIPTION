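Package: flxsig
Title: Behavioral Emotionality Scoring and a PBMC Spectral-Count
    Biosignature of Antidepressant Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for discriminating fluoxetine responders from
    non-responders in the chronic-corticosterone mouse model of
    anxiety/depression and deriving a peripheral blood mononuclear cell
    (PBMC) proteomic biosignature of treatment response. Computes composite
    behavioral emotionality z-scores from an elevated plus maze / novelty
    suppressed feeding / splash test battery, classifies response by the 50%
    improvement cut-off, filters and groups peptide-spectrum matches into
    protein subgroups, quantifies proteins by spectral counting, tests group
    effects with a Poisson log-linear likelihood-ratio test with
    Benjamini-Hochberg adjustment, partitions significant sets, and applies
    a three-criterion rule to extract the response-associated signature.
    Includes a synthetic-data generator with planted effect classes so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
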