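# Baseline (vehicle) distributions for the simulated battery. Location and
# spread are on the raw measurement scale; NSF latency is log-normal and the
# sd is on the log scale.
.behavior_baselines <- function() {
  data.frame(
    measure = c("epm_open_time_s", "epm_open_entries", "nsf_latency_s",
                "nsf_food_mg_per_g", "st_grooming_s"),
    mu    = c(60, 10, log(150), 8, 80),
    sigma = c(20, 3, 0.5, 2, 25),
    log_scale = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the behavioral cohort simulator
#'
#' @param n_per_group Animals per arm (VEH/V, CORT/V, CORT/Flx).
#' @param responder_fraction Latent probability that a treated animal
#'   responds to fluoxetine (default 0.652, the observed cohort rate).
#' @param cort_effect_sd Size of the corticosterone shift, in control-SD
#'   units, applied to every scored measure in its emotionality-increasing
#'   direction (default 2).
#' @param flx_recovery_fraction Fraction of the corticosterone shift
#'   reversed at session 2 in latent responders (default 0.9).
#' @param nonresponder_drift_sd Additional emotionality drift, in control-SD
#'   units, applied to latent non-responders at session 2 (default 0.25),
#'   mimicking the worsening seen in refractory animals.
#' @param measure_noise_sd Residual per-measure noise, in control-SD units
#'   (default 1: the control variability itself).
#' @param nsf_ceiling_s Right-censoring limit of the novelty-suppressed
#'   feeding latency, seconds (default 600, the 10-min test).
#' @param seed Integer RNG seed.
#' @return A list of class `behavioral_sim_config`.
#' @export
behavioral_sim_config <- function(n_per_group = c(veh_v = 14, cort_v = 12,
                                                  cort_flx = 46),
                                  responder_fraction = 0.652,
                                  cort_effect_sd = 2,
                                  flx_recovery_fraction = 0.9,
                                  nonresponder_drift_sd = 0.25,
                                  measure_noise_sd = 1,
                                  nsf_ceiling_s = 600,
                                  seed = 1L) {
  if (length(n_per_group) == 1L) {
    n_per_group <- c(veh_v = n_per_group, cort_v = n_per_group,
                     cort_flx = n_per_group)
  }
  if (any(n_per_group < 2)) stop("n_per_group must be >= 2 in every arm")
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("responder_fraction must be in [0, 1]")
  }
  if (nsf_ceiling_s <= 0) stop("nsf_ceiling_s must be > 0")
  if (measure_noise_sd < 0) stop("measure_noise_sd must be >= 0")
  structure(list(n_per_group = n_per_group,
                 responder_fraction = responder_fraction,
                 cort_effect_sd = cort_effect_sd,
                 flx_recovery_fraction = flx_recovery_fraction,
                 nonresponder_drift_sd = nonresponder_drift_sd,
                 measure_noise_sd = measure_noise_sd,
                 nsf_ceiling_s = nsf_ceiling_s,
                 seed = as.integer(seed)),
            class = "behavioral_sim_config")
}

#' Simulate a corticosterone / fluoxetine behavioral cohort
#'
#' Generates the three-arm design: vehicle controls, chronic corticosterone,
#' and corticosterone plus fluoxetine, each tested in two sessions
#' (post-corticosterone baseline and post-antidepressant). Corticosterone
#' shifts every scored measure by `cort_effect_sd` control-SDs in its
#' emotionality-increasing direction at both sessions. At session 2, latent
#' responders (Bernoulli `responder_fraction`) recover
#' `flx_recovery_fraction` of that shift; latent non-responders recover
#' nothing and drift a further `nonresponder_drift_sd` upward. Times and
#' counts are truncated at zero; entry counts are rounded; NSF latency is
#' log-normal and right-censored at the 10-min ceiling; food consumption is
#' unaffected by group (appetite control).
#'
#' @param config A [behavioral_sim_config()].
#' @return List with `records` (one row per animal x session) and `truth`
#'   (per treated animal, the latent responder label).
#' @export
simulate_behavior <- function(config = behavioral_sim_config()) {
  stopifnot(inherits(config, "behavioral_sim_config"))
  set.seed(config$seed)
  base <- .behavior_baselines()
  conv <- direction_convention()
  n <- config$n_per_group
  groups <- rep(BEHAVIOR_GROUPS, times = n)
  n_tot <- sum(n)
  ids <- sprintf("M%03d", seq_len(n_tot))

  treated <- groups == "CORT/Flx"
  latent <- rep(NA, n_tot)
  latent[treated] <- stats::rbinom(sum(treated), 1L,
                                   config$responder_fraction) == 1L

  # Latent emotionality shift per animal x session, in control-SD units.
  shift <- function(session) {
    e <- numeric(n_tot)
    e[groups != "VEH/V"] <- config$cort_effect_sd
    if (session == 2L) {
      resp <- treated & latent
      nonresp <- treated & !latent
      e[resp] <- e[resp] * (1 - config$flx_recovery_fraction)
      e[nonresp] <- e[nonresp] + config$nonresponder_drift_sd
    }
    e
  }

  records <- list()
  for (s in 1:2) {
    e <- shift(s)
    rec <- data.frame(animal_id = ids, group = groups, session = s,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(base))) {
      m <- base$measure[i]
      dir <- conv$sign[conv$measure == m]
      eff <- if (conv$scored[conv$measure == m]) dir * e else 0
      raw <- base$mu[i] + base$sigma[i] *
        (eff + stats::rnorm(n_tot, 0, config$measure_noise_sd))
      if (base$log_scale[i]) {
        x <- pmin(exp(raw), config$nsf_ceiling_s)
      } else {
        x <- pmax(raw, 0)
        if (m == "epm_open_entries") x <- round(x)
      }
      rec[[m]] <- x
    }
    records[[s]] <- rec
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  truth <- data.frame(
    animal_id = ids[treated],
    latent_responder = latent[treated],
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}
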