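#' Venn partition of the two fluoxetine-effect sets
#'
#' Exact set algebra over the proteins significantly changed by fluoxetine
#' in responders (`set_r`) and in non-responders (`set_nr`): the common
#' part, the solely-responder and solely-non-responder parts, and the union
#' count.
#'
#' @param set_r,set_nr Character vectors of protein identifiers.
#' @return A list of class `venn_partition` with `set_r`, `set_nr`,
#'   `common`, `solely_r`, `solely_nr` (memberships) and `counts` (named
#'   integer vector incl. `union`).
#' @export
venn_partition <- function(set_r, set_nr) {
  set_r <- unique(as.character(set_r))
  set_nr <- unique(as.character(set_nr))
  common <- intersect(set_r, set_nr)
  solely_r <- setdiff(set_r, set_nr)
  solely_nr <- setdiff(set_nr, set_r)
  counts <- c(set_r = length(set_r), set_nr = length(set_nr),
              common = length(common), solely_r = length(solely_r),
              solely_nr = length(solely_nr),
              union = length(union(set_r, set_nr)))
  structure(list(set_r = set_r, set_nr = set_nr, common = common,
                 solely_r = solely_r, solely_nr = solely_nr,
                 counts = counts),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Fluoxetine-effect Venn partition:\n")
  cat(sprintf("  R-significant %d | NR-significant %d | common %d\n",
              x$counts["set_r"], x$counts["set_nr"], x$counts["common"]))
  cat(sprintf("  solely-R %d | solely-NR %d | union %d\n",
              x$counts["solely_r"], x$counts["solely_nr"],
              x$counts["union"]))
  invisible(x)
}

#' Directional correlation of responder and non-responder changes
#'
#' Pearson correlation between the log2 changes (vs CORT/V) in responders
#' and non-responders over a protein subset — e.g. the solely-responder set,
#' to ask whether proteins significant in one arm trend the same way in the
#' other.
#'
#' @param deltas_r,deltas_nr Named numeric vectors of log2 changes.
#' @param subset Protein identifiers to correlate over (default: all shared
#'   names); must have length >= 3.
#' @return List with `r`, `p_value`, `n`.
#' @export
directional_correlation <- function(deltas_r, deltas_nr,
                                    subset = intersect(names(deltas_r),
                                                       names(deltas_nr))) {
  subset <- as.character(subset)
  if (length(subset) < 3L) stop("subset must contain >= 3 proteins")
  x <- deltas_r[subset]
  y <- deltas_nr[subset]
  if (anyNA(x) || anyNA(y)) stop("subset contains unknown proteins")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in the changes")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(subset))
}

#' Fraction of the detected proteome in a subset
#'
#' Reports the share of all detected proteins falling in a subset (e.g.
#' proteins differing between responders and non-responders), as a
#' percentage.
#'
#' @param n_subset,n_detected Subset and universe sizes.
#' @param digits Decimals to round the percentage to (default 0, how such
#'   shares are usually quoted).
#' @return Percentage of `n_detected`.
#' @export
detected_fraction <- function(n_subset, n_detected, digits = 0) {
  stopifnot(n_detected > 0, n_subset >= 0, n_subset <= n_detected)
  round(100 * n_subset / n_detected, digits)
}

#' Select the response-associated protein signature
#'
#' Applies the three-criterion signature rule to per-protein differential
#' results: a protein is response-associated when (1) it differs
#' significantly between responders and non-responders, (2) it differs
#' significantly between responders and CORT/V, and (3) its direction of
#' change is either opposite in the two arms, or of greater amplitude in
#' responders than in non-responders (same sign, larger |log2 change|).
#' Changes below `1e-12` in magnitude count as neither opposite nor
#' amplified. Output is ordered by the responder-vs-non-responder p-value,
#' ties by accession.
#'
#' @param results Differential table from [test_differential()].
#' @param alpha Significance level shared by both criteria (default 0.05).
#' @return Data frame with the per-protein statistics, the four criterion
#'   flags (`sig_r_vs_nr`, `sig_r_vs_cort`, `opposite_direction`,
#'   `greater_amplitude`) and `selected`.
#' @export
select_signature <- function(results, alpha = 0.05) {
  req <- c("accession", "p_r_vs_nr", "p_r_vs_cort", "delta_r", "delta_nr")
  missing_cols <- setdiff(req, names(results))
  if (length(missing_cols) > 0L) {
    stop("differential results lack column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !stats::complete.cases(results[, req])
  if (any(bad)) {
    stop("missing contrast for protein(s): ",
         paste(utils::head(results$accession[bad], 5), collapse = ", "))
  }
  eps <- 1e-12
  dr <- results$delta_r
  dnr <- results$delta_nr
  out <- results
  out$sig_r_vs_nr <- results$p_r_vs_nr < alpha
  out$sig_r_vs_cort <- results$p_r_vs_cort < alpha
  out$opposite_direction <- abs(dr) > eps & abs(dnr) > eps &
    sign(dr) * sign(dnr) < 0
  out$greater_amplitude <- abs(dr) > eps & abs(dnr) > eps &
    sign(dr) == sign(dnr) & abs(dr) > abs(dnr)
  out$selected <- out$sig_r_vs_nr & out$sig_r_vs_cort &
    (out$opposite_direction | out$greater_amplitude)
  out <- out[order(out$p_r_vs_nr, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
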