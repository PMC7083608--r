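#' Biallelic variant table
#'
#' In-memory container for SNP genotypes: per record chromosome, 1-based
#' position, ref and alt allele; per sample a genotype in
#' \{"0/0","0/1","1/1"\} or `NA`, plus depth (`dp`) and genotype quality
#' (`gq`) matrices (may be `NA` when the VCF lacks the fields).
#'
#' @param chrom,pos,ref,alt per-record vectors.
#' @param gt character matrix (records x samples).
#' @param dp,gq numeric matrices or `NULL` (all-`NA`).
#' @param samples sample ids (column names).
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gt, dp = NULL, gq = NULL,
                          samples = colnames(gt)) {
  n <- length(chrom)
  pos <- as.integer(pos)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            nrow(gt) == n, all(pos >= 1L))
  if (any(grepl(",", alt, fixed = TRUE))) stop("multiallelic records not allowed")
  gt <- normalize_gt(as.matrix(gt))
  if (is.null(dp)) dp <- matrix(NA_real_, n, ncol(gt))
  if (is.null(gq)) gq <- matrix(NA_real_, n, ncol(gt))
  dp <- as.matrix(dp); gq <- as.matrix(gq)
  stopifnot(identical(dim(dp), dim(gt)), identical(dim(gq), dim(gt)))
  ord <- order_sites(as.character(chrom), pos)
  out <- list(
    chrom = as.character(chrom)[ord], pos = pos[ord],
    ref = as.character(ref)[ord], alt = as.character(alt)[ord],
    gt = gt[ord, , drop = FALSE], dp = dp[ord, , drop = FALSE],
    gq = gq[ord, , drop = FALSE], samples = as.character(samples)
  )
  colnames(out$gt) <- colnames(out$dp) <- colnames(out$gq) <- out$samples
  structure(out, class = "variant_table")
}

normalize_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt == "1/0"] <- "0/1"
  gt[!(gt %in% c("0/0", "0/1", "1/1"))] <- NA_character_
  gt
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d biallelic records x %d samples\n",
              length(x$pos), length(x$samples)))
  invisible(x)
}

#' Read genotypes from a VCF (GT, DP, GQ)
#'
#' Standard VCF 4.x via vcfR. Multiallelic records are skipped (count
#' logged); records are sorted by (chromosome, position). DP/GQ absent from
#' the FORMAT are treated as missing.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param samples optional sample subset; an error is raised when no VCF
#'   sample overlaps the request.
#' @return a [variant_table()].
#' @export
read_vcf_minimal <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(v@gt)[-1]
  if (!is.null(samples)) {
    hit <- intersect(samples, vcf_samples)
    if (!length(hit)) stop("no overlap between VCF samples and requested samples")
    samples <- hit
  } else {
    samples <- vcf_samples
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) | is.na(fix[, "ALT"])
  if (any(multi)) {
    ec_log("read_vcf_minimal: skipped %d multiallelic/invalid record(s)", sum(multi))
  }
  keep <- !multi
  extract_num <- function(elem) {
    out <- tryCatch(
      suppressWarnings(vcfR::extract.gt(v, element = elem, as.numeric = TRUE)),
      error = function(e) NULL
    )
    if (is.null(out)) return(NULL)
    out[keep, samples, drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, samples, drop = FALSE]
  variant_table(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
    gt = gt, dp = extract_num("DP"), gq = extract_num("GQ"),
    samples = samples
  )
}

#' Write a variant table as a minimal plain-text VCF 4.2
#'
#' Emits GT:DP:GQ per sample; missing genotypes become `./.`, missing DP/GQ
#' become `.`. Round-trips through [read_vcf_minimal()].
#'
#' @param V a `variant_table`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(V, path) {
  stopifnot(inherits(V, "variant_table"))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))
  gt <- V$gt
  gt[is.na(gt)] <- "./."
  cells <- matrix(paste(gt, fmt_num(V$dp), fmt_num(V$gq), sep = ":"),
                  nrow = nrow(gt))
  body <- paste(V$chrom, V$pos, ".", V$ref, V$alt, ".", "PASS", ".",
                "GT:DP:GQ",
                apply(cells, 1, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", V$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

## per-record alt-allele sample frequency and mean GQ over genotyped samples
variant_stats <- function(V, samples = V$samples) {
  gt <- V$gt[, samples, drop = FALSE]
  gq <- V$gq[, samples, drop = FALSE]
  nalt <- matrix(match(gt, c("0/0", "0/1", "1/1")) - 1L, nrow = nrow(gt))
  genotyped <- !is.na(nalt)
  n_gen <- rowSums(genotyped)
  f_alt <- ifelse(n_gen > 0, rowSums(nalt, na.rm = TRUE) / (2 * n_gen), NA_real_)
  gq_gen <- ifelse(genotyped, gq, NA_real_)
  mean_gq <- rowMeans(gq_gen, na.rm = TRUE)
  mean_gq[!is.finite(mean_gq)] <- NA_real_
  data.frame(n_genotyped = n_gen, f_alt = f_alt,
             maf = pmin(f_alt, 1 - f_alt), mean_gq = mean_gq)
}
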