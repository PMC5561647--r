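#' Filter peptide-spectrum matches by identification thresholds
#'
#' Applies the identification criteria used for spectral-count proteomics:
#' peptide E-value strictly below `pep_e_max`, protein E-value strictly
#' below `prot_e_max`, and at least `min_peptides` distinct retained peptide
#' sequences per protein. Contaminant accessions (exact matches or prefix)
#' are removed before counting.
#'
#' @param psms Long PSM table with columns `peptide_sequence`,
#'   `peptide_evalue`, `protein_accession`, `protein_evalue`, `sample_id`,
#'   `spectra`.
#' @param pep_e_max Peptide E-value threshold (default 0.01, strict `<`).
#' @param prot_e_max Protein E-value threshold (default 1e-4, strict `<`).
#' @param min_peptides Minimum distinct retained peptides per protein
#'   (default 2).
#' @param contaminants Character vector of contaminant accessions to drop.
#' @param contaminant_prefix Optional accession prefix marking contaminants
#'   (e.g. `"CON_"`).
#' @return The filtered PSM table. If nothing survives, an empty table is
#'   returned with a warning (never a silent empty success).
#' @export
filter_identifications <- function(psms, pep_e_max = 0.01,
                                   prot_e_max = 1e-4, min_peptides = 2,
                                   contaminants = character(),
                                   contaminant_prefix = NULL) {
  stopifnot(pep_e_max > 0, prot_e_max > 0, min_peptides >= 1)
  req <- c("peptide_sequence", "peptide_evalue", "protein_accession",
           "protein_evalue", "sample_id", "spectra")
  missing_cols <- setdiff(req, names(psms))
  if (length(missing_cols) > 0L) {
    stop("PSM table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }

  keep <- psms$peptide_evalue < pep_e_max & psms$protein_evalue < prot_e_max
  keep <- keep & !(psms$protein_accession %in% contaminants)
  if (!is.null(contaminant_prefix)) {
    keep <- keep & !startsWith(psms$protein_accession, contaminant_prefix)
  }
  out <- psms[keep, , drop = FALSE]

  if (nrow(out) > 0L) {
    npep <- tapply(out$peptide_sequence, out$protein_accession,
                   function(p) length(unique(p)))
    ok_acc <- names(npep)[npep >= min_peptides]
    out <- out[out$protein_accession %in% ok_acc, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    warning("no PSMs survive identification filtering")
  }
  rownames(out) <- NULL
  out
}

#' Group proteins by shared peptides and flag subgroups
#'
#' Proteins sharing at least one retained peptide fall into the same group:
#' groups are the connected components of the bipartite protein-peptide
#' incidence graph. Within a group, a protein carrying at least one peptide
#' specific to it (mapping to no other retained protein) is reported as a
#' subgroup — the unit of quantification, one subgroup being one specific
#' protein. Group identifiers are assigned by sorting groups on their
#' lexicographically smallest member accession, so output is independent of
#' input row order.
#'
#' @param filtered A filtered PSM table from [filter_identifications()].
#' @return A list of class `protein_grouping` with `groups` (data frame:
#'   `accession`, `group_id`, `is_subgroup`, `n_specific_peptides`) and
#'   `peptide_map` (distinct `peptide_sequence` x `protein_accession`
#'   incidence with `n_proteins` mapped).
#' @export
group_proteins <- function(filtered) {
  if (nrow(filtered) == 0L) stop("cannot group an empty PSM table")
  inc <- unique(filtered[, c("peptide_sequence", "protein_accession")])
  accs <- sort(unique(inc$protein_accession))
  peps <- unique(inc$peptide_sequence)

  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("pep:", inc$peptide_sequence),
               to = paste0("acc:", inc$protein_accession)),
    directed = FALSE,
    vertices = data.frame(name = c(paste0("pep:", peps),
                                   paste0("acc:", accs)))
  )
  comp <- igraph::components(g)$membership
  acc_comp <- comp[paste0("acc:", accs)]

  # Deterministic group ids: order components by smallest member accession.
  first_acc <- tapply(accs, acc_comp, min)
  comp_rank <- rank(first_acc)
  group_id <- sprintf("G%04d", comp_rank[as.character(acc_comp)])

  pep_nprot <- tapply(inc$protein_accession, inc$peptide_sequence,
                      function(a) length(unique(a)))
  inc$n_proteins <- as.integer(pep_nprot[inc$peptide_sequence])
  specific <- inc[inc$n_proteins == 1L, , drop = FALSE]
  n_spec <- table(factor(specific$protein_accession, levels = accs))

  groups <- data.frame(
    accession = accs,
    group_id = unname(group_id),
    is_subgroup = as.integer(n_spec) > 0L,
    n_specific_peptides = as.integer(n_spec),
    stringsAsFactors = FALSE
  )
  groups <- groups[order(groups$group_id, groups$accession), , drop = FALSE]
  rownames(groups) <- NULL
  structure(list(groups = groups, peptide_map = inc),
            class = "protein_grouping")
}

#' Build the protein x sample spectral-count matrix
#'
#' Sums spectra into one row per subgroup (reported protein). In
#' `"unique-only"` mode (default), only peptides specific to a single
#' retained protein contribute, so no spectrum is counted twice; in
#' `"group-level"` mode, one row per group is added summing all its
#' peptides' spectra. Missing protein x sample combinations are zero.
#'
#' @param filtered Filtered PSM table.
#' @param grouping Result of [group_proteins()].
#' @param design Data frame with `sample_id` and `group` (one of `CORT/V`,
#'   `CORT/Flx-R`, `CORT/Flx-NR`) for every sample present.
#' @param shared `"unique-only"` (default) or `"group-level"`.
#' @return A list of class `count_matrix` with `counts` (integer matrix,
#'   rows = proteins), `samples` (the design), and `proteins` (row
#'   metadata: `accession`, `group_id`, `n_distinct_peptides`).
#' @export
build_count_matrix <- function(filtered, grouping, design,
                               shared = c("unique-only", "group-level")) {
  shared <- match.arg(shared)
  stopifnot(inherits(grouping, "protein_grouping"),
            all(c("sample_id", "group") %in% names(design)))
  samples <- unique(filtered$sample_id)
  unlabeled <- setdiff(samples, design$sample_id)
  if (length(unlabeled) > 0L) {
    stop("sample(s) without a group label: ",
         paste(unlabeled, collapse = ", "))
  }
  design <- design[design$sample_id %in% samples, , drop = FALSE]

  pepmap <- grouping$peptide_map
  subs <- grouping$groups[grouping$groups$is_subgroup, , drop = FALSE]

  # Spectra of peptides specific to one protein, per protein x sample.
  spec_pep <- pepmap$peptide_sequence[pepmap$n_proteins == 1L]
  d <- filtered[filtered$peptide_sequence %in% spec_pep, , drop = FALSE]
  d <- d[d$protein_accession %in% subs$accession, , drop = FALSE]
  mat <- matrix(0L, nrow = nrow(subs), ncol = nrow(design),
                dimnames = list(subs$accession, design$sample_id))
  if (nrow(d) > 0L) {
    agg <- stats::aggregate(spectra ~ protein_accession + sample_id,
                            data = d, FUN = sum)
    mat[cbind(agg$protein_accession, agg$sample_id)] <- agg$spectra
  }

  proteins <- subs[, c("accession", "group_id")]
  npep_all <- tapply(filtered$peptide_sequence, filtered$protein_accession,
                     function(p) length(unique(p)))
  proteins$n_distinct_peptides <- as.integer(npep_all[proteins$accession])

  if (shared == "group-level") {
    gmat <- rowsum(
      mat[proteins$accession, , drop = FALSE],
      group = proteins$group_id
    )
    # add spectra of shared peptides once per group
    sh <- filtered[!(filtered$peptide_sequence %in% spec_pep), , drop = FALSE]
    if (nrow(sh) > 0L) {
      gid <- grouping$groups$group_id[
        match(sh$protein_accession, grouping$groups$accession)]
      sh_key <- !duplicated(sh[, c("peptide_sequence", "sample_id")])
      shu <- sh[sh_key, , drop = FALSE]
      gidu <- gid[sh_key]
      agg <- stats::aggregate(shu$spectra,
                              by = list(group_id = gidu,
                                        sample_id = shu$sample_id),
                              FUN = sum)
      gmat[cbind(agg$group_id, agg$sample_id)] <-
        gmat[cbind(agg$group_id, agg$sample_id)] + agg$x
    }
    grows <- data.frame(accession = paste0("group:", rownames(gmat)),
                        group_id = rownames(gmat),
                        n_distinct_peptides = NA_integer_,
                        stringsAsFactors = FALSE)
    rownames(gmat) <- grows$accession
    mat <- rbind(mat, gmat)
    proteins <- rbind(proteins, grows)
  }

  structure(list(counts = mat, samples = design, proteins = proteins),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Spectral-count matrix:", nrow(x$counts), "proteins x",
      ncol(x$counts), "samples\n")
  cat("Groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}
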