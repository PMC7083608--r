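#' Read a sample sheet
#'
#' Tab- or comma-separated with header columns `sample`, `cohort`, `group`,
#' `family`, `sex`. `cohort` must be `wild` or `experimental`; experimental
#' samples must carry a family id (the split-clutch design makes family a
#' covariate of every experimental comparison), wild samples may leave it
#' empty. `sex` is `F`, `M` or `unknown` (empty values become `unknown`).
#'
#' @param path sample sheet file.
#' @return a validated data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df a data.frame with the sample-sheet columns.
#' @export
sample_sheet <- function(df) {
  need <- c("sample", "cohort", "group", "family", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  df$family[!is.na(df$family) & !nzchar(df$family)] <- NA_character_
  df$sex[is.na(df$sex) | !nzchar(df$sex)] <- "unknown"
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id: ", df$sample[duplicated(df$sample)][1])
  }
  if (!all(df$cohort %in% c("wild", "experimental"))) {
    stop("cohort must be 'wild' or 'experimental'")
  }
  if (!all(df$sex %in% c("F", "M", "unknown"))) {
    stop("sex must be 'F', 'M' or 'unknown'")
  }
  noref <- df$cohort == "experimental" & is.na(df$family)
  if (any(noref)) {
    stop("experimental sample without family id: ", df$sample[noref][1])
  }
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname read_sample_sheet
#' @param sheet a `sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

## samples of one group, optionally restricted to those present in a matrix
sheet_samples <- function(sheet, group, within = NULL) {
  s <- sheet$sample[sheet$group == group]
  if (!is.null(within)) s <- intersect(s, within)
  s
}
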