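# All stage products are plain tab-delimited files so any stage can be
# inspected or re-run independently.

#' Write a pipeline table
#' @param x Data frame.
#' @param path Output path (tab-delimited, header, no quoting of numbers).
#' @export
write_flx_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline table
#' @param path Tab-delimited file written by [write_flx_table()].
#' @return Data frame.
#' @export
read_flx_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a count matrix with its design as tab-delimited text
#' @param cm A `count_matrix`.
#' @param counts_path,design_path,proteins_path Output paths.
#' @export
write_count_matrix <- function(cm, counts_path, design_path,
                               proteins_path = NULL) {
  df <- data.frame(accession = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_flx_table(df, counts_path)
  write_flx_table(cm$samples, design_path)
  if (!is.null(proteins_path)) write_flx_table(cm$proteins, proteins_path)
  invisible(counts_path)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param counts_path,design_path Paths of the counts and design tables.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, design_path) {
  df <- read_flx_table(counts_path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$accession
  storage.mode(mat) <- "integer"
  design <- read_flx_table(design_path)
  structure(list(counts = mat, samples = design,
                 proteins = data.frame(accession = rownames(mat),
                                       stringsAsFactors = FALSE)),
            class = "count_matrix")
}
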