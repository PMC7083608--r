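#' Write / read a result table as TSV
#'
#' Plain tab-separated text with a header, deterministic column order (the
#' data.frame order) and `NA` for missing values. A written table re-read
#' and re-written reproduces the file byte for byte.
#'
#' @param table any result data.frame (DiffMeth, Channel, FST, feature
#'   tables ...).
#' @param path file path.
#' @return `write_results_table()` returns `path` invisibly;
#'   `read_results_table()` returns a data.frame.
#' @export
write_results_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("result table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
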