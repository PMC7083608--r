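#' Per-CpG, per-sample methylation count matrix
#'
#' The central container of the package: for every CpG site (keyed by the
#' forward-strand C position, 1-based) and sample it stores the read coverage
#' and the number of methylated reads. A site may be *absent* in a sample
#' (no usable reads after filtering); absence is represented explicitly as
#' `NA` in both matrices, never as zero coverage.
#'
#' Sites are kept sorted by (chromosome string, position); all downstream
#' modules rely on that total order.
#'
#' @param chrom,pos character/integer vectors of site coordinates.
#' @param samples character vector of sample ids.
#' @param coverage,methylated integer matrices (sites x samples);
#'   `NA` marks an absent entry and must occur in both or neither.
#'
#' @return An object of class `meth_matrix` with fields `sites`
#'   (data.frame `chrom`, `pos`), `samples`, `coverage`, `methylated`.
#' @export
meth_matrix <- function(chrom, pos, samples, coverage, methylated) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  samples <- as.character(samples)
  coverage <- as.matrix(coverage)
  methylated <- as.matrix(methylated)
  storage.mode(coverage) <- "integer"
  storage.mode(methylated) <- "integer"
  if (length(chrom) != length(pos)) stop("chrom/pos length mismatch")
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  if (any(pos < 1L, na.rm = TRUE) || anyNA(pos)) stop("positions must be >= 1")
  if (nrow(coverage) != length(pos) || ncol(coverage) != length(samples)) {
    stop("coverage dimensions inconsistent with sites/samples")
  }
  if (!identical(dim(coverage), dim(methylated))) {
    stop("coverage/methylated dimension mismatch")
  }
  if (!identical(unname(is.na(coverage)), unname(is.na(methylated)))) {
    stop("NA (absence) pattern differs between coverage and methylated")
  }
  if (any(coverage < 0L, na.rm = TRUE) || any(methylated < 0L, na.rm = TRUE)) {
    stop("negative counts")
  }
  if (any(methylated > coverage, na.rm = TRUE)) {
    stop("methylated exceeds coverage")
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(site_key(chrom, pos))) stop("duplicate (chrom,pos) sites")
  ord <- order_sites(chrom, pos)
  coverage <- coverage[ord, , drop = FALSE]
  methylated <- methylated[ord, , drop = FALSE]
  dimnames(coverage) <- dimnames(methylated) <- list(NULL, samples)
  structure(
    list(
      sites = data.frame(chrom = chrom[ord], pos = pos[ord],
                         stringsAsFactors = FALSE),
      samples = samples,
      coverage = coverage,
      methylated = methylated
    ),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  pres <- sum(!is.na(x$coverage))
  cat(sprintf(
    "<meth_matrix> %d CpG sites x %d samples (%.1f%% entries present)\n",
    nrow(x$sites), length(x$samples),
    100 * pres / max(1, length(x$coverage))
  ))
  invisible(x)
}

#' Number of CpG sites in a methylation matrix
#' @param M a `meth_matrix`.
#' @return integer count of sites.
#' @export
n_sites <- function(M) {
  stopifnot(inherits(M, "meth_matrix"))
  nrow(M$sites)
}

mm_site_keys <- function(M) site_key(M$sites$chrom, M$sites$pos)

## keep sites where `keep` is TRUE (logical or index vector)
mm_keep_sites <- function(M, keep) {
  M$sites <- M$sites[keep, , drop = FALSE]
  rownames(M$sites) <- NULL
  M$coverage <- M$coverage[keep, , drop = FALSE]
  M$methylated <- M$methylated[keep, , drop = FALSE]
  M
}

## drop sites that are absent in every sample; returns list(M, n_dropped)
mm_drop_empty_sites <- function(M) {
  keep <- rowSums(!is.na(M$coverage)) > 0L
  list(matrix = mm_keep_sites(M, keep), n_dropped = sum(!keep))
}

#' Merge per-sample methylation matrices over the union of sites
#'
#' Sites missing from a sample are absent (`NA`), not zero.
#'
#' @param mats list of `meth_matrix` objects with disjoint sample sets.
#' @return a single `meth_matrix`.
#' @export
merge_meth_matrices <- function(mats) {
  stopifnot(length(mats) >= 1, all(vapply(mats, inherits, TRUE, "meth_matrix")))
  keys <- unique(unlist(lapply(mats, mm_site_keys)))
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  chrom <- parts[, 1]
  pos <- as.integer(parts[, 2])
  ord <- order_sites(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  keys <- keys[ord]
  samples <- unlist(lapply(mats, `[[`, "samples"))
  if (anyDuplicated(samples)) stop("duplicate sample ids across matrices")
  cov <- matrix(NA_integer_, length(keys), length(samples),
                dimnames = list(NULL, samples))
  met <- cov
  for (m in mats) {
    idx <- match(mm_site_keys(m), keys)
    cov[idx, m$samples] <- m$coverage
    met[idx, m$samples] <- m$methylated
  }
  meth_matrix(chrom, pos, samples, cov, met)
}

#' Write / read a methylation matrix as TSV
#'
#' One row per site; per sample a `<id>.cov` and `<id>.meth` column pair with
#' `NA` marking absent entries. Writing then reading round-trips exactly.
#'
#' @param M a `meth_matrix`.
#' @param path file path.
#' @return `write_meth_matrix()` returns `path` invisibly;
#'   `read_meth_matrix()` returns a `meth_matrix`.
#' @export
write_meth_matrix <- function(M, path) {
  stopifnot(inherits(M, "meth_matrix"))
  df <- M$sites
  for (s in M$samples) {
    df[[paste0(s, ".cov")]] <- M$coverage[, s]
    df[[paste0(s, ".meth")]] <- M$methylated[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meth_matrix
#' @export
read_meth_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  covcols <- grep("\\.cov$", names(df), value = TRUE)
  samples <- sub("\\.cov$", "", covcols)
  cov <- as.matrix(df[, paste0(samples, ".cov"), drop = FALSE])
  met <- as.matrix(df[, paste0(samples, ".meth"), drop = FALSE])
  meth_matrix(df$chrom, df$pos, samples, cov, met)
}
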