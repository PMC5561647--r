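#!/usr/bin/env Rscript
# Stage 6 — hierarchical biclustering and PCA of the expression profiles.
#
# UPGMA / Euclidean clustering of row-standardized log2 abundances for
# proteins and animals, and a PCA of sample profiles with per-group
# bivariate-normal density parameters on the first two components.

suppressPackageStartupMessages(library(flxsig))
cm <- read_count_matrix("results/03_inference/counts.tsv",
                        "results/03_inference/design.tsv")

keep <- rowSums(cm$counts) > 0
cl <- bicluster(list(counts = cm$counts[keep, , drop = FALSE]))
ord <- ordinate(cm)

dir.create("results/06_multivariate", showWarnings = FALSE, recursive = TRUE)
writeLines(c(dendrogram_text(cl$col_hclust), dendrogram_text(cl$row_hclust)),
           "results/06_multivariate/dendrograms.txt")
write_flx_table(
  data.frame(sample_id = rownames(ord$scores), group = cm$samples$group,
             pc1 = ord$scores[, 1], pc2 = ord$scores[, 2]),
  "results/06_multivariate/pca_scores.tsv")
dens <- do.call(rbind, lapply(names(ord$group_density), function(g) {
  gd <- ord$group_density[[g]]
  data.frame(group = g, mean_pc1 = gd$mean[1], mean_pc2 = gd$mean[2],
             var_pc1 = gd$cov[1, 1], var_pc2 = gd$cov[2, 2],
             cov_pc12 = gd$cov[1, 2], n = gd$n)
}))
write_flx_table(dens, "results/06_multivariate/group_densities.tsv")

message(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of profile variance",
                100 * ord$explained[1], 100 * ord$explained[2]))
leaf_groups <- cm$samples$group[match(cl$col_hclust$labels[cl$col_order],
                                      cm$samples$sample_id)]
message("column dendrogram leaf order (groups): ",
        paste(leaf_groups, collapse = " "))
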