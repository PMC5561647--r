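#' Poisson log-linear group-effect test for one protein
#'
#' Likelihood-ratio (deviance) test of a group effect on spectral counts:
#' counts are modeled Poisson with one rate per group (optionally scaled by
#' per-sample library sizes as an offset) against an intercept-only model.
#' Group maximum-likelihood rates are the (offset-weighted) group means, so
#' the fit is closed-form; the deviance is referred to chi-square with
#' (number of groups - 1) degrees of freedom.
#'
#' @param y Integer vector of spectral counts, one per sample.
#' @param groups Factor or character vector of group labels, same length.
#' @param offset_total Optional positive per-sample totals (library sizes);
#'   `NULL` (default) fits unnormalized counts.
#' @return List with `statistic`, `df`, `p_value`, `group_means`
#'   (rate per group), and `degenerate` (`TRUE` for an all-zero row, which
#'   carries no information and is reported at p = 1).
#' @export
fit_group_poisson <- function(y, groups, offset_total = NULL) {
  stopifnot(length(y) == length(groups), all(y >= 0),
            all(y == round(y)))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 groups")
  N <- if (is.null(offset_total)) rep(1, length(y)) else offset_total
  stopifnot(length(N) == length(y), all(N > 0))

  if (all(y == 0)) {
    return(list(statistic = 0, df = nlevels(droplevels(groups)) - 1L,
                p_value = 1, group_means = tapply(y, groups, mean),
                degenerate = TRUE))
  }
  lam0 <- sum(y) / sum(N)
  Sg <- tapply(y, groups, sum)
  Ng <- tapply(N, groups, sum)
  lamg <- Sg / Ng
  # 2 * sum y_i (log lam_g(i) - log lam0); groups with zero total contribute 0
  terms <- ifelse(Sg > 0, Sg * (log(lamg) - log(lam0)), 0)
  stat <- max(2 * sum(terms), 0)
  df <- length(Sg) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       group_means = tapply(y, groups, mean),
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values; a thin
#' validated wrapper around [stats::p.adjust()] preserving input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise Student's t-test on per-sample counts
#'
#' Two-sided pooled-variance (classical Student) t-test between two groups
#' of per-sample spectral counts. Degenerate rows are resolved without
#' error: zero pooled variance with equal means gives p = 1, zero pooled
#' variance with unequal means gives p = 0 (flagged).
#'
#' @param a,b Numeric vectors of counts for the two groups (each n >= 2).
#' @param size_factors_a,size_factors_b Optional positive scale factors
#'   dividing the counts before testing (library-size normalization).
#' @return List with `p_value`, `mean_diff` (mean(a) - mean(b)),
#'   `statistic`, and `degenerate`.
#' @export
pairwise_ttest <- function(a, b, size_factors_a = NULL,
                           size_factors_b = NULL) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 samples per group")
  if (!is.null(size_factors_a)) a <- a / size_factors_a
  if (!is.null(size_factors_b)) b <- b / size_factors_b
  md <- mean(a) - mean(b)
  s2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (s2 == 0) {
    return(list(p_value = if (md == 0) 1 else 0, mean_diff = md,
                statistic = if (md == 0) 0 else sign(md) * Inf,
                degenerate = TRUE))
  }
  se <- sqrt(s2 * (1 / length(a) + 1 / length(b)))
  tt <- md / se
  df <- length(a) + length(b) - 2
  list(p_value = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
       mean_diff = md, statistic = tt, degenerate = FALSE)
}

#' Pseudocounted log2 change between group means
#'
#' `delta = log2((mean_g + c) / (mean_ref + c))`; the pseudocount keeps the
#' ratio finite when either mean is zero.
#'
#' @param mean_g,mean_ref Group means (non-negative).
#' @param c Pseudocount (default 0.5, must be > 0).
#' @return The log2 change.
#' @export
log_change <- function(mean_g, mean_ref, c = 0.5) {
  stopifnot(c > 0)
  log2((mean_g + c) / (mean_ref + c))
}

#' Per-protein differential statistics over a spectral-count matrix
#'
#' Runs, for every protein row: the Poisson group-effect deviance test
#' (BH-adjusted across proteins), the three pairwise Student's t-tests
#' (responders vs CORT/V, non-responders vs CORT/V, responders vs
#' non-responders), and pseudocounted log2 changes of each fluoxetine arm
#' against CORT/V. BH is applied to the group-effect p-values only; the
#' pairwise tests are reported raw, the two-tier scheme used for
#' spectral-count screening.
#'
#' @param cm A `count_matrix` from [build_count_matrix()] (or a compatible
#'   list with `counts` and `samples`).
#' @param normalize `"none"` (default) or `"total-count"` to use per-sample
#'   total spectra as a Poisson offset / t-test size factor.
#' @param pseudocount Pseudocount for log2 changes (default 0.5).
#' @return Data frame, one row per protein: `accession`, `statistic`, `df`,
#'   `p_group`, `q_group`, `p_r_vs_cort`, `p_nr_vs_cort`, `p_r_vs_nr`,
#'   `delta_r`, `delta_nr`, `degenerate`.
#' @export
test_differential <- function(cm, normalize = c("none", "total-count"),
                              pseudocount = 0.5) {
  normalize <- match.arg(normalize)
  counts <- cm$counts
  grp <- cm$samples$group[match(colnames(counts), cm$samples$sample_id)]
  if (anyNA(grp)) stop("count matrix columns missing from the design")
  tab <- table(grp)
  if (any(tab[PROTEOME_GROUPS] < 2, na.rm = TRUE) ||
      !all(PROTEOME_GROUPS %in% names(tab))) {
    stop("each of ", paste(PROTEOME_GROUPS, collapse = ", "),
         " needs >= 2 samples")
  }
  off <- if (normalize == "total-count") colSums(counts) else NULL
  if (!is.null(off) && any(off == 0)) stop("a sample has zero total spectra")
  sf <- if (is.null(off)) NULL else off / mean(off)

  is_cv <- grp == "CORT/V"
  is_r <- grp == "CORT/Flx-R"
  is_nr <- grp == "CORT/Flx-NR"

  res <- lapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    fit <- fit_group_poisson(y, grp, offset_total = off)
    yn <- if (is.null(sf)) y else y / sf
    t_rc <- pairwise_ttest(yn[is_r], yn[is_cv])
    t_nc <- pairwise_ttest(yn[is_nr], yn[is_cv])
    t_rn <- pairwise_ttest(yn[is_r], yn[is_nr])
    data.frame(
      accession = rownames(counts)[i],
      statistic = fit$statistic, df = fit$df, p_group = fit$p_value,
      p_r_vs_cort = t_rc$p_value, p_nr_vs_cort = t_nc$p_value,
      p_r_vs_nr = t_rn$p_value,
      delta_r = log_change(mean(yn[is_r]), mean(yn[is_cv]), pseudocount),
      delta_nr = log_change(mean(yn[is_nr]), mean(yn[is_cv]), pseudocount),
      degenerate = fit$degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q_group <- adjust_bh(out$p_group)
  out <- out[, c("accession", "statistic", "df", "p_group", "q_group",
                 "p_r_vs_cort", "p_nr_vs_cort", "p_r_vs_nr",
                 "delta_r", "delta_nr", "degenerate")]
  rownames(out) <- NULL
  out
}
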