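PROTEOME_CLASSES <- c("null", "common_flx", "r_only", "nr_only",
                      "signature_opposite", "signature_amplified")

#' Configuration for the spectral-count / PSM simulator
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_samples_per_group Samples per arm, named over `cort_v`, `flx_r`,
#'   `flx_nr` (defaults 5, 7, 6, the proteomic design).
#' @param baseline_rate_range Range of expected spectral counts per protein
#'   per sample in the reference (CORT/V) condition (default 5-50).
#' @param class_fractions Proportions of the six planted effect classes:
#'   `null` (no change), `common_flx` (same fluoxetine effect in responders
#'   and non-responders), `r_only` / `nr_only` (effect in one arm only),
#'   `signature_opposite` (opposite directions in the two arms), and
#'   `signature_amplified` (same direction, twice the log2 amplitude in
#'   responders). Must sum to 1.
#' @param effect_log2fc Planted log2 fold-change magnitude (default 1.5).
#' @param shared_peptide_fraction Fraction of peptides mapped to a second
#'   protein, to exercise grouping (default 0.1).
#' @param overdispersion Negative-binomial size parameter; `Inf` (default)
#'   gives pure Poisson counts, finite values add overdispersion for
#'   robustness checks.
#' @param seed Integer RNG seed.
#' @return A list of class `proteome_sim_config`.
#' @export
proteome_sim_config <- function(n_proteins = 938,
                                n_samples_per_group = c(cort_v = 5,
                                                        flx_r = 7,
                                                        flx_nr = 6),
                                baseline_rate_range = c(5, 50),
                                class_fractions = c(null = 0.70,
                                                    common_flx = 0.12,
                                                    r_only = 0.05,
                                                    nr_only = 0.07,
                                                    signature_opposite = 0.03,
                                                    signature_amplified = 0.03),
                                effect_log2fc = 1.5,
                                shared_peptide_fraction = 0.1,
                                overdispersion = Inf,
                                seed = 1L) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (!setequal(names(class_fractions), PROTEOME_CLASSES)) {
    stop("class_fractions must be named over: ",
         paste(PROTEOME_CLASSES, collapse = ", "))
  }
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1")
  }
  if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  if (shared_peptide_fraction < 0 || shared_peptide_fraction > 1) {
    stop("shared_peptide_fraction must be in [0, 1]")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_samples_per_group = n_samples_per_group,
                 baseline_rate_range = baseline_rate_range,
                 class_fractions = class_fractions[PROTEOME_CLASSES],
                 effect_log2fc = effect_log2fc,
                 shared_peptide_fraction = shared_peptide_fraction,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "proteome_sim_config")
}

.rcounts <- function(n, lambda, size) {
  if (is.infinite(size)) stats::rpois(n, lambda)
  else stats::rnbinom(n, mu = lambda, size = size)
}

#' Simulate a peptide-spectrum-match table with planted effect classes
#'
#' Each protein receives a baseline spectral-count rate (log-uniform over
#' `baseline_rate_range`), an effect class, and a random effect direction.
#' Group rates are the baseline multiplied by `2^(effect_log2fc)` according
#' to the class: both fluoxetine arms for `common_flx`, one arm for
#' `r_only` / `nr_only`, opposite signs for `signature_opposite`, and the
#' same sign at full vs half amplitude for `signature_amplified`. Counts are
#' Poisson (optionally negative-binomial) per sample, distributed over the
#' protein's specific peptides; a `shared_peptide_fraction` of additional
#' peptides map to two proteins and carry their own small counts so that
#' grouping is exercised without perturbing subgroup quantification in
#' unique-only mode.
#'
#' @param config A [proteome_sim_config()].
#' @return List with `psms` (long PSM table: `peptide_sequence`,
#'   `peptide_evalue`, `protein_accession`, `protein_evalue`, `sample_id`,
#'   `spectra`), `design` (`sample_id`, `group`), and `truth` (per protein:
#'   `accession`, `class`, `direction`, `lambda_base`).
#' @export
simulate_psms <- function(config = proteome_sim_config()) {
  stopifnot(inherits(config, "proteome_sim_config"))
  set.seed(config$seed)
  np <- config$n_proteins
  nsg <- config$n_samples_per_group
  groups <- rep(PROTEOME_GROUPS, times = nsg)
  sample_id <- unlist(lapply(seq_along(PROTEOME_GROUPS), function(i) {
    sprintf("%s_%02d", gsub("[/-]", "_", PROTEOME_GROUPS[i]), seq_len(nsg[i]))
  }))
  design <- data.frame(sample_id = sample_id, group = groups,
                       stringsAsFactors = FALSE)

  acc <- sprintf("PSIM%04d", seq_len(np))
  classes <- sample(rep(PROTEOME_CLASSES,
                        times = round_fractions(config$class_fractions, np)))
  direction <- sample(c(-1, 1), np, replace = TRUE)
  lr <- log(config$baseline_rate_range)
  lambda_base <- exp(stats::runif(np, lr[1], lr[2]))

  f <- 2^config$effect_log2fc
  mult_r <- rep(1, np)
  mult_nr <- rep(1, np)
  for (i in seq_len(np)) {
    d <- direction[i]
    switch(classes[i],
      null = NULL,
      common_flx = { mult_r[i] <- f^d; mult_nr[i] <- f^d },
      r_only = { mult_r[i] <- f^d },
      nr_only = { mult_nr[i] <- f^d },
      signature_opposite = { mult_r[i] <- f^d; mult_nr[i] <- f^-d },
      signature_amplified = { mult_r[i] <- f^d; mult_nr[i] <- f^(d / 2) }
    )
  }
  rates <- cbind("CORT/V" = lambda_base,
                 "CORT/Flx-R" = lambda_base * mult_r,
                 "CORT/Flx-NR" = lambda_base * mult_nr)

  n_specific <- 2L + stats::rpois(np, 2)
  pep_of <- rep(seq_len(np), n_specific)
  n_pep <- length(pep_of)
  pep_seq <- random_peptides(n_pep)
  n_shared <- round(config$shared_peptide_fraction * n_pep)

  # Specific-peptide PSMs: each protein's per-sample total is split evenly
  # across its specific peptides, so subgroup quantification stays Poisson
  # at the planted rate.
  rows <- vector("list", np + 1L)
  for (i in seq_len(np)) {
    lam <- rates[i, groups]
    peps <- which(pep_of == i)
    counts <- .rcounts(length(peps) * length(sample_id),
                       rep(lam / length(peps), each = length(peps)),
                       config$overdispersion)
    m <- matrix(counts, nrow = length(peps))
    nz <- which(m > 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) next
    rows[[i]] <- data.frame(
      peptide_sequence = pep_seq[peps[nz[, 1]]],
      protein_accession = acc[i],
      sample_id = sample_id[nz[, 2]],
      spectra = m[nz],
      stringsAsFactors = FALSE
    )
  }

  # Shared peptides: map to two distinct proteins, small independent counts.
  if (n_shared > 0 && np >= 2) {
    sh_seq <- random_peptides(n_shared, prefix = "SH")
    p1 <- sample(np, n_shared, replace = TRUE)
    p2 <- (p1 + sample(np - 1L, n_shared, replace = TRUE) - 1L) %% np + 1L
    sh <- lapply(seq_len(n_shared), function(j) {
      cnt <- stats::rpois(length(sample_id), 2)
      keep <- cnt > 0
      if (!any(keep)) keep[1] <- TRUE  # every peptide observed at least once
      cnt[cnt == 0 & keep] <- 1L
      data.frame(
        peptide_sequence = sh_seq[j],
        protein_accession = rep(c(acc[p1[j]], acc[p2[j]]), each = sum(keep)),
        sample_id = rep(sample_id[keep], 2),
        spectra = rep(cnt[keep], 2),
        stringsAsFactors = FALSE
      )
    })
    rows[[np + 1L]] <- do.call(rbind, sh)
  }
  psms <- do.call(rbind, rows)
  rownames(psms) <- NULL

  # Identification scores: all simulated identifications pass the default
  # thresholds; the filtering operation is exercised by tests that inject
  # failures explicitly.
  pep_e <- stats::runif(length(unique(psms$peptide_sequence)), 1e-6, 5e-3)
  names(pep_e) <- unique(psms$peptide_sequence)
  prot_e <- stats::runif(np, 1e-10, 5e-5)
  names(prot_e) <- acc
  psms$peptide_evalue <- unname(pep_e[psms$peptide_sequence])
  psms$protein_evalue <- unname(prot_e[psms$protein_accession])
  psms <- psms[, c("peptide_sequence", "peptide_evalue", "protein_accession",
                   "protein_evalue", "sample_id", "spectra")]

  truth <- data.frame(accession = acc, class = classes,
                      direction = direction, lambda_base = lambda_base,
                      stringsAsFactors = FALSE)
  list(psms = psms, design = design, truth = truth)
}

# Largest-remainder apportionment of n items to the class fractions.
round_fractions <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Deterministic pseudo-tryptic peptide sequences (unique, end in K/R).
random_peptides <- function(n, prefix = "PEP") {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  len <- sample(7:14, n, replace = TRUE)
  body <- vapply(len, function(l) {
    paste(sample(aa, l, replace = TRUE), collapse = "")
  }, character(1))
  paste0(body, sample(c("K", "R"), n, replace = TRUE), ".", prefix,
         seq_len(n))
}
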