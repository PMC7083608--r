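#' Gene models with transcription start sites
#'
#' Container for gene annotation: one row per gene (`gene_id`, `chrom`,
#' `strand`, `start`, `end`, `tss`) plus an exon table (`gene_id`, `chrom`,
#' `start`, `end`). Coordinates are 1-based inclusive; the TSS is the gene
#' start on `+` and the gene end on `-`.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (tss is derived).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   genes with no exon row get a single implicit exon spanning the gene.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, exons = NULL) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  stopifnot(all(need %in% names(genes)))
  genes <- genes[, need]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$end < genes$start)) stop("gene end before start")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene id")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  if (is.null(exons) || nrow(exons) == 0) {
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  }
  exons <- exons[, c("gene_id", "chrom", "start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  bad <- !(exons$gene_id %in% genes$gene_id)
  if (any(bad)) stop("exon without parent gene: ", exons$gene_id[bad][1])
  gi <- match(exons$gene_id, genes$gene_id)
  if (any(exons$start < genes$start[gi] | exons$end > genes$end[gi])) {
    stop("exon outside gene span")
  }
  ## implicit single exon for exon-less genes
  no_ex <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_ex)) {
    gi <- match(no_ex, genes$gene_id)
    exons <- rbind(exons, data.frame(
      gene_id = no_ex, chrom = genes$chrom[gi],
      start = genes$start[gi], end = genes$end[gi],
      stringsAsFactors = FALSE
    ))
  }
  ord <- order(genes$gene_id, method = "radix")
  genes <- genes[ord, ]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Uses `gene` and `exon` features; exons are attached to genes through
#' their `Parent` attribute (an exon whose parent is not a `gene` record is
#' an error). Genes without exon rows get a single implicit exon spanning
#' the gene.
#'
#' @param path GFF3 file.
#' @return a [gene_models()] object.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  gid <- as.character(g$ID)
  gn <- g[type == "gene"]
  if (!length(gn)) stop("no gene features in ", path)
  genes <- data.frame(
    gene_id = as.character(gn$ID),
    chrom = as.character(GenomicRanges::seqnames(gn)),
    strand = as.character(GenomicRanges::strand(gn)),
    start = GenomicRanges::start(gn),
    end = GenomicRanges::end(gn),
    stringsAsFactors = FALSE
  )
  ex <- g[type == "exon"]
  exons <- NULL
  if (length(ex)) {
    parent <- vapply(as.list(ex$Parent), function(p) {
      if (!length(p)) NA_character_ else as.character(p[[1]])
    }, character(1))
    if (anyNA(parent)) stop("exon without Parent attribute in ", path)
    exons <- data.frame(
      gene_id = parent,
      chrom = as.character(GenomicRanges::seqnames(ex)),
      start = GenomicRanges::start(ex),
      end = GenomicRanges::end(ex),
      stringsAsFactors = FALSE
    )
  }
  gene_models(genes, exons)
}

#' Write gene models as GFF3
#'
#' @param gm a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  gi <- match(gm$exons$gene_id, gm$genes$gene_id)
  gene_rows <- paste(gm$genes$chrom, "epichannels", "gene",
                     gm$genes$start, gm$genes$end, ".", gm$genes$strand, ".",
                     paste0("ID=", gm$genes$gene_id), sep = "\t")
  exon_rows <- paste(gm$exons$chrom, "epichannels", "exon",
                     gm$exons$start, gm$exons$end, ".",
                     gm$genes$strand[gi], ".",
                     paste0("Parent=", gm$exons$gene_id), sep = "\t")
  writeLines(c("##gff-version 3", gene_rows, exon_rows), path)
  invisible(path)
}
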