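#' Read and write tabular pipeline files
#'
#' All tables are tab-separated with a required header row; missing
#' optional fields are written as `.`.
#'
#' @param path file path.
#' @return `read_decay_table` returns a data.frame; `read_decay_course`
#'   additionally validates and classes it as a [decay_course].
#' @name pipeline_tables
NULL

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = ".",
                          check.names = FALSE, comment.char = "#")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' @rdname pipeline_tables
#' @export
read_decay_table <- function(path) {
  read_tsv_strict(path, c("condition", "replicate", "time_hr"))
}

#' @rdname pipeline_tables
#' @export
read_decay_course <- function(path) {
  df <- read_tsv_strict(path, c("condition", "replicate", "time_hr", "abundance"))
  decay_course(df$time_hr, df$abundance, df$replicate, df$condition[1])
}

#' @rdname pipeline_tables
#' @param course a [decay_course].
#' @export
write_decay_course <- function(course, path) {
  utils::write.table(as.data.frame(course), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene table
#'
#' @param path TSV with header `gene_id` plus a value column.
#' @param value_col name of the value column (`log2fc` or
#'   `fold_over_input`).
#' @return data.frame with `gene_id` and the value column.
#' @export
read_gene_table <- function(path, value_col) {
  read_tsv_strict(path, c("gene_id", value_col))
}

#' @rdname read_gene_table
#' @param table data.frame to write.
#' @export
write_gene_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
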