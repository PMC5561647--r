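#' Pipeline run configuration
#'
#' Bundles every threshold and stage toggle of the end-to-end synthetic run:
#' simulate -> score -> classify -> select -> infer -> test -> signature ->
#' multivariate.
#'
#' @param out_dir Output directory; each stage writes to its own
#'   subdirectory.
#' @param seed Integer seed driving both simulators.
#' @param behavior_config,proteome_config Simulator configurations; their
#'   seeds are derived from `seed`.
#' @param responder_cutoff Fractional improvement defining response
#'   (default 0.5).
#' @param k_per_group Animals carried to proteomics per group.
#' @param pep_e_max,prot_e_max,min_peptides Identification thresholds.
#' @param alpha Significance level for pairwise tests and the signature
#'   rule.
#' @param normalize Count normalization mode, `"none"` or `"total-count"`.
#' @param stages Character vector of stages to run, a subset of
#'   `c("behavior", "proteome")`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       behavior_config = NULL, proteome_config = NULL,
                       responder_cutoff = 0.5,
                       k_per_group = c("CORT/V" = 5, "CORT/Flx-R" = 7,
                                       "CORT/Flx-NR" = 6),
                       pep_e_max = 0.01, prot_e_max = 1e-4,
                       min_peptides = 2, alpha = 0.05,
                       normalize = "none",
                       stages = c("behavior", "proteome")) {
  stopifnot(alpha > 0, alpha < 1,
            all(stages %in% c("behavior", "proteome")))
  seed <- as.integer(seed)
  if (is.null(behavior_config)) {
    behavior_config <- behavioral_sim_config(seed = seed)
  }
  if (is.null(proteome_config)) {
    proteome_config <- proteome_sim_config(seed = seed + 1000L)
  }
  structure(list(out_dir = out_dir, seed = seed,
                 behavior_config = behavior_config,
                 proteome_config = proteome_config,
                 responder_cutoff = responder_cutoff,
                 k_per_group = k_per_group, pep_e_max = pep_e_max,
                 prot_e_max = prot_e_max, min_peptides = min_peptides,
                 alpha = alpha, normalize = normalize, stages = stages),
            class = "run_config")
}

#' Run the full synthetic biosignature pipeline
#'
#' Executes the enabled stages in order, writing each stage's tables under
#' its own subdirectory of `config$out_dir`, and returns (and writes) a run
#' manifest recording the package version, a hash of the configuration, the
#' seed, and per-stage row counts. The manifest contains no timestamps, so
#' identical configuration and seed reproduce it byte-for-byte.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress to stderr (default `TRUE`).
#' @return The manifest, invisibly, as a character vector of lines (also
#'   written to `<out_dir>/manifest.txt`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[flxsig] ", ...)
  manifest <- c(
    paste0("flxsig_version\t", as.character(utils::packageVersion("flxsig"))),
    paste0("seed\t", config$seed),
    paste0("config_hash\t", .config_hash(config)),
    paste0("stages\t", paste(config$stages, collapse = ","))
  )
  stage_dir <- function(s) {
    d <- file.path(config$out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  add <- function(stage, what, n) {
    manifest <<- c(manifest, paste0(stage, ".", what, "\t", n))
  }

  if ("behavior" %in% config$stages) {
    say("simulating behavioral cohort")
    d <- stage_dir("behavior")
    sim <- simulate_behavior(config$behavior_config)
    write_flx_table(sim$records, file.path(d, "records.tsv"))
    write_flx_table(sim$truth, file.path(d, "latent_truth.tsv"))
    add("behavior", "records", nrow(sim$records))

    say("scoring emotionality")
    z <- zscore_measures(sim$records)
    scores <- emotionality(z)
    write_flx_table(scores, file.path(d, "emotionality.tsv"))
    add("behavior", "scored_animals", nrow(scores) / 2L)

    say("classifying response")
    labels <- classify_response(scores, cutoff = config$responder_cutoff)
    write_flx_table(labels, file.path(d, "response_labels.tsv"))
    add("behavior", "responders", sum(labels$label == "responder"))
    add("behavior", "responder_rate_pct", responder_rate(labels))

    sel <- select_most_affected(scores, labels,
                                k_per_group = config$k_per_group)
    write_flx_table(sel, file.path(d, "selected_animals.tsv"))
    add("behavior", "selected", nrow(sel))
  }

  if ("proteome" %in% config$stages) {
    say("simulating PSM tables")
    d <- stage_dir("proteome")
    sim <- simulate_psms(config$proteome_config)
    write_flx_table(sim$psms, file.path(d, "psms.tsv"))
    write_flx_table(sim$design, file.path(d, "design.tsv"))
    write_flx_table(sim$truth, file.path(d, "planted_truth.tsv"))
    add("proteome", "psm_rows", nrow(sim$psms))

    say("filtering and grouping identifications")
    filt <- filter_identifications(sim$psms, pep_e_max = config$pep_e_max,
                                   prot_e_max = config$prot_e_max,
                                   min_peptides = config$min_peptides)
    grouping <- group_proteins(filt)
    write_flx_table(grouping$groups, file.path(d, "protein_groups.tsv"))
    cm <- build_count_matrix(filt, grouping, sim$design)
    write_count_matrix(cm, file.path(d, "counts.tsv"),
                       file.path(d, "design_used.tsv"),
                       file.path(d, "proteins.tsv"))
    add("proteome", "proteins_quantified", nrow(cm$counts))

    say("differential testing")
    res <- test_differential(cm, normalize = config$normalize)
    write_flx_table(res, file.path(d, "differential.tsv"))
    add("proteome", "group_effect_sig",
        sum(res$p_group < config$alpha))

    say("signature selection")
    set_r <- res$accession[res$p_r_vs_cort < config$alpha]
    set_nr <- res$accession[res$p_nr_vs_cort < config$alpha]
    venn <- venn_partition(set_r, set_nr)
    venn_df <- data.frame(subset = names(venn$counts),
                          n = as.integer(venn$counts))
    write_flx_table(venn_df, file.path(d, "venn.tsv"))
    add("proteome", "venn_union", venn$counts[["union"]])

    sig <- select_signature(res, alpha = config$alpha)
    write_flx_table(sig, file.path(d, "signature.tsv"))
    add("proteome", "signature_selected", sum(sig$selected))

    say("multivariate summaries")
    keep <- rowSums(cm$counts) > 0
    cl <- bicluster(list(counts = cm$counts[keep, , drop = FALSE]))
    writeLines(c(dendrogram_text(cl$col_hclust),
                 dendrogram_text(cl$row_hclust)),
               file.path(d, "dendrograms.txt"))
    ord <- ordinate(cm)
    write_flx_table(
      data.frame(sample_id = rownames(ord$scores),
                 group = cm$samples$group,
                 pc1 = ord$scores[, 1], pc2 = ord$scores[, 2]),
      file.path(d, "pca_scores.tsv"))
    add("proteome", "pc1_explained_pct", round(100 * ord$explained[1], 2))
  }

  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  invisible(manifest)
}

# Hash of the configuration: md5 of its deterministic deparse. Output paths
# are excluded so the hash identifies the analysis, not where it ran.
.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  writeLines(deparse(cfg[order(names(cfg))]), tf)
  unname(tools::md5sum(tf))
}
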