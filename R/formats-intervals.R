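#' Read a BED file of scored intervals
#'
#' BED intervals (0-based half-open) are imported with \pkg{rtracklayer} and
#' returned as a `GRanges` carrying `name` and `score` columns — the container
#' used for ChIP-Seq peaks, where `score` is the peak height.
#'
#' @param path Path to a BED3/BED5/BED6 file.
#' @return A [GenomicRanges::GRanges] with `name` and `score` metadata.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) gr$name <- sprintf("interval_%d", seq_along(gr))
  if (is.null(gr$score)) gr$score <- NA_real_
  gr
}

#' Write intervals to a BED file
#'
#' @param gr A `GRanges` with optional `name`/`score` metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = gr$name %||% sprintf("interval_%d", seq_along(gr)),
                   score = gr$score %||% 0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a gene model
#'
#' A gene model holds, per gene, the transcript structures the genomic-context
#' classifier needs: transcript bounds, CDS bounds (absent for non-coding
#' transcripts) and sorted non-overlapping exons. All coordinates are 0-based
#' half-open.
#'
#' @param gene_id Gene identifier.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts List of lists with elements `tx_start`, `tx_end`,
#'   `cds_start`, `cds_end` (may be `NA` for non-coding) and `exons`, a
#'   two-column matrix of exon `start`,`end` pairs.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"))
  for (tx in transcripts) {
    ex <- tx$exons
    if (is.unsorted(ex[, 1]))
      stop_regsnp("regsnp_format_error", "exons must be sorted: ", gene_id)
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
      stop_regsnp("regsnp_format_error", "exons must not overlap: ", gene_id)
    if (!is.na(tx$cds_start) &&
        (tx$cds_start < tx$tx_start || tx$cds_end > tx$tx_end))
      stop_regsnp("regsnp_format_error", "CDS outside transcript bounds: ", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "GeneModel")
}

#' Read gene models from a GTF file
#'
#' Imports a GTF with \pkg{rtracklayer} and assembles one [gene_model()] per
#' gene from its `transcript`, `exon` and `CDS` records. Stop codons, UTR
#' features and other record types are ignored; UTRs are derived from the
#' exon/CDS geometry by the classifier instead.
#'
#' @param path Path to a GTF file.
#' @return A list of `GeneModel` objects, named by gene id.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(type = as.character(gr$type),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gr$gene_id,
                   tx_id = gr$transcript_id %||% NA_character_,
                   stringsAsFactors = FALSE)
  out <- list()
  for (g in unique(df$gene_id)) {
    dg <- df[df$gene_id == g, ]
    txs <- list()
    for (t in unique(stats::na.omit(dg$tx_id))) {
      dt <- dg[!is.na(dg$tx_id) & dg$tx_id == t, ]
      ex <- dt[dt$type == "exon", c("start", "end")]
      if (nrow(ex) == 0) next
      ex <- as.matrix(ex[order(ex$start), ])
      cds <- dt[dt$type == "CDS", c("start", "end")]
      txs[[t]] <- list(tx_start = min(ex[, 1]), tx_end = max(ex[, 2]),
                       cds_start = if (nrow(cds)) min(cds$start) else NA_integer_,
                       cds_end = if (nrow(cds)) max(cds$end) else NA_integer_,
                       exons = ex)
    }
    out[[g]] <- gene_model(g, dg$chrom[1], dg$strand[1], txs)
  }
  out
}
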