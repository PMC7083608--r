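#' Read a Bismark-style coverage file for one sample
#'
#' Expects the six tab-separated columns of the Bismark coverage dialect:
#' chromosome, start, end, percent methylation, methylated count,
#' unmethylated count, with start == end (a single cytosine). Coverage is
#' reconstructed from the two counts; if the printed percentage disagrees
#' with the counts by more than 0.5 points a warning is emitted and the
#' counts win. Rows with zero total coverage are kept as sites but stored as
#' absent entries (logged).
#'
#' CpG calls are keyed by the forward-strand C. Coverage files carry no
#' strand, so destranding (folding reverse-strand G calls at pos+1 into the
#' C at pos) is only possible when the forward-C positions are known; pass
#' them via `destrand_positions` to enable it.
#'
#' @param path coverage file.
#' @param sample_id sample identifier for the resulting one-column matrix.
#' @param destrand_positions optional data.frame (`chrom`, `pos`) of known
#'   forward-strand C positions; rows at `pos + 1` of a known C (that are not
#'   themselves known Cs) are folded into it with counts summed.
#' @return a one-sample [meth_matrix()].
#' @export
read_coverage_file <- function(path, sample_id, destrand_positions = NULL) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lnum <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stop(sprintf("parse error in %s at line %d: expected 6 tab-separated fields, got %d",
                 path, lnum[which(nf != 6L)[1]], nf[nf != 6L][1]))
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  chrom <- m[, 1]
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  nmeth <- suppressWarnings(as.integer(m[, 5]))
  nunmeth <- suppressWarnings(as.integer(m[, 6]))
  bad <- !nzchar(chrom) | is.na(start) | is.na(end) | is.na(pct) |
    is.na(nmeth) | is.na(nunmeth) | nmeth < 0L | nunmeth < 0L
  if (any(bad)) {
    stop(sprintf("parse error in %s at line %d: non-numeric or negative field",
                 path, lnum[which(bad)[1]]))
  }
  if (any(start != end)) {
    stop(sprintf("parse error in %s at line %d: start != end (expected single cytosine)",
                 path, lnum[which(start != end)[1]]))
  }
  pos <- start
  cov <- nmeth + nunmeth
  implied <- ifelse(cov > 0L, 100 * nmeth / cov, 0)
  n_incons <- sum(abs(implied - pct) > 0.5)
  if (n_incons > 0) {
    warning(sprintf("%s: %d row(s) with %%meth inconsistent with counts by >0.5; counts win",
                    path, n_incons))
  }

  if (!is.null(destrand_positions)) {
    fwd <- site_key(destrand_positions$chrom, destrand_positions$pos)
    k <- site_key(chrom, pos)
    km1 <- site_key(chrom, pos - 1L)
    fold <- (km1 %in% fwd) & !(k %in% fwd)
    pos[fold] <- pos[fold] - 1L
    if (any(fold)) {
      k <- site_key(chrom, pos)
      agg_meth <- rowsum(nmeth, k, reorder = FALSE)
      agg_cov <- rowsum(cov, k, reorder = FALSE)
      first <- !duplicated(k)
      chrom <- chrom[first]
      pos <- pos[first]
      nmeth <- agg_meth[match(k[first], rownames(agg_meth)), 1]
      cov <- agg_cov[match(k[first], rownames(agg_cov)), 1]
    }
  }

  if (anyDuplicated(site_key(chrom, pos))) {
    stop(sprintf("duplicate site in %s: %s",
                 path, site_key(chrom, pos)[duplicated(site_key(chrom, pos))][1]))
  }

  zero <- cov == 0L
  if (any(zero)) {
    ec_log("%s: %d zero-coverage row(s) stored as absent entries",
           basename(path), sum(zero))
  }
  covm <- matrix(ifelse(zero, NA_integer_, as.integer(cov)), ncol = 1)
  metm <- matrix(ifelse(zero, NA_integer_, as.integer(nmeth)), ncol = 1)
  meth_matrix(chrom, pos, sample_id, covm, metm)
}

#' Read and merge coverage files for many samples
#'
#' @param paths character vector of coverage files.
#' @param sample_ids sample id per file.
#' @param destrand_positions see [read_coverage_file()].
#' @return a merged [meth_matrix()] over the union of sites.
#' @export
read_coverage_files <- function(paths, sample_ids, destrand_positions = NULL) {
  stopifnot(length(paths) == length(sample_ids))
  mats <- Map(read_coverage_file, paths, sample_ids,
              MoreArgs = list(destrand_positions = destrand_positions))
  merge_meth_matrices(unname(mats))
}

#' Write one Bismark-style coverage file per sample
#'
#' Inverse of [read_coverage_files()]: absent entries are omitted from the
#' file (not written as zero rows).
#'
#' @param M a `meth_matrix`.
#' @param dir output directory; files are named `<sample>.cov`.
#' @return invisibly, the written paths.
#' @export
write_coverage_files <- function(M, dir) {
  stopifnot(inherits(M, "meth_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(M$samples))
  for (j in seq_along(M$samples)) {
    s <- M$samples[j]
    pres <- !is.na(M$coverage[, j])
    cov <- M$coverage[pres, j]
    met <- M$methylated[pres, j]
    df <- data.frame(M$sites$chrom[pres], M$sites$pos[pres], M$sites$pos[pres],
                     formatC(100 * met / cov, format = "f", digits = 6),
                     met, cov - met)
    paths[j] <- file.path(dir, paste0(s, ".cov"))
    utils::write.table(df, paths[j], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
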