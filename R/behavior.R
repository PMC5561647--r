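# Canonical group labels used throughout the pipeline.
BEHAVIOR_GROUPS <- c("VEH/V", "CORT/V", "CORT/Flx")
PROTEOME_GROUPS <- c("CORT/V", "CORT/Flx-R", "CORT/Flx-NR")

#' Direction convention for the behavioral battery
#'
#' Maps each raw measure of the three-test battery (elevated plus maze,
#' novelty suppressed feeding, splash test) to its test and to the sign that
#' converts its z-score into the emotionality direction: `+1` when a larger
#' raw value indicates higher emotionality (NSF latency), `-1` when a larger
#' value indicates lower emotionality (open-arm time and entries, grooming).
#' Food consumption after the NSF is an appetite-confound control and is
#' never scored.
#'
#' @return A data frame with one row per measure and columns `measure`,
#'   `test`, `sign`, and `scored`.
#' @export
#' @examples
#' direction_convention()
direction_convention <- function() {
  data.frame(
    measure = c("epm_open_time_s", "epm_open_entries", "nsf_latency_s",
                "nsf_food_mg_per_g", "st_grooming_s"),
    test    = c("EPM", "EPM", "NSF", "NSF", "ST"),
    sign    = c(-1, -1, +1, 0, -1),
    scored  = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Standardize behavioral measures against a control group
#'
#' Computes per-measure z-scores `z = sign * (x - mu) / sigma`, where `mu`
#' and `sigma` are the mean and (n-1) standard deviation of the control
#' group *of the same session*, and `sign` is the emotionality direction of
#' the measure. Same-session referencing absorbs session-to-session drift in
#' the raw measures.
#'
#' @param records Data frame of behavioral records, one row per animal x
#'   session, with columns `animal_id`, `group`, `session` and the measure
#'   columns named in `convention`.
#' @param control_group Group label providing the reference statistics
#'   (default `"VEH/V"`).
#' @param convention Direction convention, see [direction_convention()].
#' @return A long data frame with columns `animal_id`, `group`, `session`,
#'   `test`, `measure`, `z`, `control_mu`, `control_sigma`.
#' @export
zscore_measures <- function(records, control_group = "VEH/V",
                            convention = direction_convention()) {
  stopifnot(is.data.frame(records),
            all(c("animal_id", "group", "session") %in% names(records)))
  conv <- convention[convention$scored, , drop = FALSE]
  missing_cols <- setdiff(conv$measure, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack measure column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!control_group %in% records$group) {
    stop("control group '", control_group, "' absent from records")
  }

  out <- vector("list", length(unique(records$session)) * nrow(conv))
  k <- 0L
  for (s in sort(unique(records$session))) {
    in_session <- records$session == s
    ctrl <- records[in_session & records$group == control_group, , drop = FALSE]
    if (nrow(ctrl) < 2L) {
      stop("control group has fewer than 2 animals in session ", s)
    }
    for (i in seq_len(nrow(conv))) {
      m <- conv$measure[i]
      x <- records[[m]][in_session]
      if (anyNA(x)) {
        stop("missing values in measure '", m, "' (session ", s,
             "); no silent imputation is performed")
      }
      mu <- mean(ctrl[[m]])
      sigma <- stats::sd(ctrl[[m]])
      if (!is.finite(sigma) || sigma == 0) {
        stop("degenerate reference: control sigma is zero for measure '",
             m, "' in session ", s)
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        animal_id = records$animal_id[in_session],
        group = records$group[in_session],
        session = s,
        test = conv$test[i],
        measure = m,
        z = conv$sign[i] * (x - mu) / sigma,
        control_mu = mu,
        control_sigma = sigma,
        stringsAsFactors = FALSE
      )
    }
  }
  z <- do.call(rbind, out[seq_len(k)])
  rownames(z) <- NULL
  z
}

#' Composite emotionality score
#'
#' Two-stage averaging of per-measure z-scores: z-scores are first averaged
#' within each test (EPM, NSF, ST) and the three per-test values are then
#' averaged with equal weight into the composite emotionality score. Equal
#' test weighting means a test contributing two measures does not dominate a
#' test contributing one.
#'
#' @param z_table Long z-score table from [zscore_measures()].
#' @param convention Direction convention, used to enumerate the expected
#'   tests.
#' @return Data frame with one row per animal x session and columns
#'   `animal_id`, `group`, `session`, one `z_<test>` column per test, and
#'   `emotionality`.
#' @export
emotionality <- function(z_table, convention = direction_convention()) {
  stopifnot(all(c("animal_id", "session", "test", "z") %in% names(z_table)))
  tests <- unique(convention$test[convention$scored])

  key <- interaction(z_table$animal_id, z_table$session, drop = TRUE)
  rows <- lapply(split(z_table, key), function(d) {
    per_test <- vapply(tests, function(tt) {
      zi <- d$z[d$test == tt]
      if (length(zi) == 0L) {
        stop("animal '", d$animal_id[1], "' session ", d$session[1],
             " has no scored measure for test ", tt)
      }
      mean(zi)
    }, numeric(1))
    res <- data.frame(animal_id = d$animal_id[1], group = d$group[1],
                      session = d$session[1], stringsAsFactors = FALSE)
    for (tt in tests) res[[paste0("z_", tolower(tt))]] <- per_test[[tt]]
    res$emotionality <- mean(per_test)
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$session, out$animal_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify fluoxetine response by the 50% improvement rule
#'
#' A treated animal is a responder when its emotionality score decreased by
#' at least `cutoff` (default 50%) between the pre-treatment and
#' post-treatment sessions: `(pre - post) / pre >= cutoff`. The relative
#' change is undefined for non-positive baselines, so animals with
#' `pre <= baseline_floor` are labeled `not_applicable`; by default they
#' stay in the cohort-rate denominator (counted as not responding), so the
#' rate is over all treated animals.
#'
#' @param scores Emotionality table from [emotionality()] holding both
#'   sessions.
#' @param treated_group Group receiving the antidepressant (default
#'   `"CORT/Flx"`).
#' @param cutoff Required fractional decrease (default 0.5).
#' @param baseline_floor Pre-treatment scores at or below this value make
#'   the relative change ill-defined (default 0).
#' @param exclusion_band Optional half-width of an "ambiguous" band around
#'   the cutoff; animals whose relative change falls within
#'   `cutoff +/- exclusion_band` are labeled `not_applicable` (default 0 =
#'   no exclusion).
#' @param na_in_denominator Keep `not_applicable` animals in the responder
#'   rate denominator (default `TRUE`).
#' @return Data frame with columns `animal_id`, `pre_score`, `post_score`,
#'   `relative_change`, `label`; the cohort responder rate (percent, one
#'   decimal) is attached as attribute `responder_rate_pct`.
#' @export
classify_response <- function(scores, treated_group = "CORT/Flx",
                              cutoff = 0.5, baseline_floor = 0,
                              exclusion_band = 0,
                              na_in_denominator = TRUE) {
  stopifnot(cutoff > 0, exclusion_band >= 0)
  tr <- scores[scores$group == treated_group, , drop = FALSE]
  pre <- tr[tr$session == 1L, c("animal_id", "emotionality")]
  post <- tr[tr$session == 2L, c("animal_id", "emotionality")]
  names(pre)[2] <- "pre_score"
  names(post)[2] <- "post_score"
  d <- merge(pre, post, by = "animal_id")
  if (nrow(d) < nrow(pre) || nrow(d) < nrow(post)) {
    stop("treated animals must be scored in both sessions")
  }
  d$relative_change <- (d$pre_score - d$post_score) / d$pre_score

  d$label <- "non_responder"
  d$label[d$relative_change >= cutoff] <- "responder"
  bad_pre <- d$pre_score <= baseline_floor
  if (any(bad_pre)) {
    warning(sum(bad_pre), " treated animal(s) at or below the baseline ",
            "floor; labeled not_applicable")
    d$label[bad_pre] <- "not_applicable"
    d$relative_change[bad_pre] <- NA_real_
  }
  if (exclusion_band > 0) {
    amb <- !bad_pre & abs(d$relative_change - cutoff) <= exclusion_band
    d$label[amb] <- "not_applicable"
  }

  denom <- if (na_in_denominator) nrow(d) else sum(d$label != "not_applicable")
  rate <- if (denom > 0) round(100 * sum(d$label == "responder") / denom, 1) else NA_real_
  d <- d[order(d$animal_id), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "responder_rate_pct") <- rate
  d
}

#' Cohort responder rate
#'
#' @param labels Result of [classify_response()].
#' @return Responder rate as a percentage rounded to one decimal.
#' @export
responder_rate <- function(labels) {
  attr(labels, "responder_rate_pct")
}

#' Select the most affected animals per proteomic group
#'
#' Picks the animals carried into the proteomic stage: the "most" affected
#' per group, with defaults matching 5 CORT/V, 7 responders, 6
#' non-responders. CORT/V and non-responders are ranked by descending
#' post-treatment emotionality (most affected = still most emotional);
#' responders by descending relative decrease (most affected = strongest
#' improvement). Ties are broken by `animal_id` so selection is
#' deterministic.
#'
#' @param scores Emotionality table with both sessions.
#' @param labels Response labels from [classify_response()].
#' @param k_per_group Named integer vector over `CORT/V`, `CORT/Flx-R`,
#'   `CORT/Flx-NR`.
#' @param ranking Named character vector mapping each proteomic group to
#'   `"post_score"` or `"relative_change"`.
#' @return Data frame with `animal_id`, `proteome_group`, `rank`.
#' @export
select_most_affected <- function(scores, labels,
                                 k_per_group = c("CORT/V" = 5,
                                                 "CORT/Flx-R" = 7,
                                                 "CORT/Flx-NR" = 6),
                                 ranking = c("CORT/V" = "post_score",
                                             "CORT/Flx-R" = "relative_change",
                                             "CORT/Flx-NR" = "post_score")) {
  post <- scores[scores$session == 2L, c("animal_id", "group", "emotionality")]
  names(post)[3] <- "post_score"

  pool <- list(
    "CORT/V" = post[post$group == "CORT/V", c("animal_id", "post_score")],
    "CORT/Flx-R" = merge(
      labels[labels$label == "responder",
             c("animal_id", "relative_change")],
      post[, c("animal_id", "post_score")], by = "animal_id"),
    "CORT/Flx-NR" = merge(
      labels[labels$label %in% c("non_responder", "not_applicable"),
             c("animal_id", "relative_change")],
      post[, c("animal_id", "post_score")], by = "animal_id")
  )

  out <- lapply(names(k_per_group), function(g) {
    k <- k_per_group[[g]]
    cand <- pool[[g]]
    if (is.null(cand)) stop("unknown proteomic group '", g, "'")
    if (k > nrow(cand)) {
      stop("k = ", k, " exceeds size ", nrow(cand), " of group ", g)
    }
    crit <- cand[[ranking[[g]]]]
    ord <- order(-crit, cand$animal_id)
    sel <- cand$animal_id[ord][seq_len(k)]
    data.frame(animal_id = sel, proteome_group = g, rank = seq_len(k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
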