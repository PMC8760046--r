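#' Tab-separated table IO with documented headers
#'
#' Thin wrappers used for the pipeline's exchange formats: spike event
#' tables, trial tables, cell-odor pair tables and QC reports all travel as
#' plain TSV with a header row.
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` a data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a session summary as JSON
#'
#' @param summary A [summarize_session()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_summary <- function(summary, path) {
  summary$broadness <- as.list(summary$broadness)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
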