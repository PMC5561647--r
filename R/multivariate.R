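# log2(count + 0.5) abundance transform used before clustering/ordination.
.log_abundance <- function(counts) log2(counts + 0.5)

#' Hierarchical bivariate clustering of the count matrix
#'
#' Clusters proteins (rows) and samples (columns) independently with
#' Euclidean distances and unweighted pair-group average linkage (UPGMA).
#' Abundances are log2(count + 0.5) transformed and, when `standardize` is
#' on, row-standardized (centered and scaled per protein) so the heatmap
#' contrast is above- vs below-average expression per protein. Constant
#' rows standardize to zero rather than dividing by a zero spread.
#'
#' @param cm A `count_matrix` (or list with a `counts` matrix).
#' @param standardize Row-standardize the log abundances (default `TRUE`).
#' @return A list of class `clustering_result` with `row_hclust`,
#'   `col_hclust` (stats::hclust trees), `matrix` (the transformed matrix
#'   clustered), and `row_order` / `col_order` leaf orders.
#' @export
bicluster <- function(cm, standardize = TRUE) {
  counts <- if (is.list(cm)) cm$counts else cm
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("need >= 2 rows and >= 2 columns")
  }
  x <- .log_abundance(counts)
  if (standardize) {
    mu <- rowMeans(x)
    sdev <- apply(x, 1, stats::sd)
    x <- (x - mu) / ifelse(sdev > 0, sdev, 1)
  }
  row_hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                          method = "average")
  col_hc <- stats::hclust(stats::dist(t(x), method = "euclidean"),
                          method = "average")
  structure(list(row_hclust = row_hc, col_hclust = col_hc, matrix = x,
                 row_order = row_hc$order, col_order = col_hc$order),
            class = "clustering_result")
}

#' Principal component analysis with per-group bivariate-normal densities
#'
#' PCA of the sample expression profiles (samples as observations, proteins
#' as variables) on centered log2(count + 0.5) abundances, plus the
#' parameters of a bivariate normal fitted to each group's scores on the
#' first two components, from which group density contours can be drawn.
#'
#' @param cm A `count_matrix`.
#' @param groups Optional group label per sample; defaults to the matrix's
#'   own design.
#' @return A list of class `ordination_result` with `scores`, `loadings`,
#'   `explained` (variance fractions), and `group_density` (per group:
#'   `mean` and `cov` on PC1/PC2).
#' @export
ordinate <- function(cm, groups = NULL) {
  counts <- if (is.list(cm)) cm$counts else cm
  if (ncol(counts) < 3L) stop("need >= 3 samples for ordination")
  if (is.null(groups) && is.list(cm) && !is.null(cm$samples)) {
    groups <- cm$samples$group[match(colnames(counts),
                                     cm$samples$sample_id)]
  }
  x <- t(.log_abundance(counts))  # samples x proteins
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)

  group_density <- NULL
  if (!is.null(groups)) {
    sc2 <- pc$x[, 1:2, drop = FALSE]
    group_density <- lapply(split(seq_len(nrow(sc2)), groups), function(idx) {
      list(mean = colMeans(sc2[idx, , drop = FALSE]),
           cov = stats::cov(sc2[idx, , drop = FALSE]),
           n = length(idx))
    })
  }
  structure(list(scores = pc$x, loadings = pc$rotation, explained = expl,
                 group_density = group_density),
            class = "ordination_result")
}

#' Serialize a dendrogram as nested Newick-like text
#'
#' @param hc An `hclust` tree.
#' @return A single string, `(leaf,leaf):height` nested notation.
#' @export
dendrogram_text <- function(hc) {
  n <- length(hc$labels)
  build <- function(i) {
    if (i < 0) return(hc$labels[-i])
    m <- hc$merge[i, ]
    sprintf("(%s,%s):%.6g", build(m[1]), build(m[2]), hc$height[i])
  }
  paste0(build(nrow(hc$merge)), ";")
}
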