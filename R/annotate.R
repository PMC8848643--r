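#' Classify a variant's genomic context against gene models
#'
#' ANNOVAR-style location classification with documented precedence:
#' `exonic > UTR5/UTR3 > intronic > upstream/downstream > intergenic`. A
#' variant inside an exon but outside the CDS is a UTR hit, assigned 5' or 3'
#' by strand; exonic hits in transcripts without a CDS are labeled exonic
#' with a `noncoding` flag. Upstream/downstream means within `flank_bp` of
#' the transcript start/end (strand-aware) but outside the transcript. When
#' transcripts (or genes) disagree, the highest-precedence category wins;
#' classification does not depend on input order.
#'
#' @param variant One-row variant table; the position of the first ref base
#'   is classified.
#' @param genes List of [gene_model()] objects.
#' @param flank_bp Upstream/downstream window (default 1000).
#' @return A list with `variant_id`, `category`, `gene_id` (`NA` iff
#'   intergenic), and `noncoding` flag.
#' @export
classify_location <- function(variant, genes, flank_bp = 1000L) {
  pos0 <- variant$pos - 1L   # 0-based point of the first ref base
  precedence <- c(exonic = 1, UTR5 = 2, UTR3 = 2, intronic = 3,
                  upstream = 4, downstream = 4, intergenic = 5)
  best <- list(category = "intergenic", gene_id = NA_character_,
               noncoding = FALSE)
  consider <- function(category, gene_id, noncoding = FALSE) {
    if (precedence[[category]] < precedence[[best$category]] ||
        (precedence[[category]] == precedence[[best$category]] &&
         is.na(best$gene_id) && !is.na(gene_id)))
      best <<- list(category = category, gene_id = gene_id,
                    noncoding = noncoding)
  }
  for (g in genes) {
    if (g$chrom != variant$chrom) next
    for (tx in g$transcripts) {
      inside_tx <- pos0 >= tx$tx_start && pos0 < tx$tx_end
      if (inside_tx) {
        in_exon <- any(pos0 >= tx$exons[, 1] & pos0 < tx$exons[, 2])
        if (in_exon) {
          if (is.na(tx$cds_start)) {
            consider("exonic", g$gene_id, noncoding = TRUE)
          } else if (pos0 >= tx$cds_start && pos0 < tx$cds_end) {
            consider("exonic", g$gene_id)
          } else {
            before_cds <- pos0 < tx$cds_start
            utr5 <- (g$strand == "+") == before_cds
            consider(if (utr5) "UTR5" else "UTR3", g$gene_id)
          }
        } else {
          consider("intronic", g$gene_id)
        }
      } else {
        # strand-aware flanks: TSS is tx_start on +, tx_end on -
        if (g$strand == "+") {
          if (pos0 >= tx$tx_start - flank_bp && pos0 < tx$tx_start)
            consider("upstream", g$gene_id)
          if (pos0 >= tx$tx_end && pos0 < tx$tx_end + flank_bp)
            consider("downstream", g$gene_id)
        } else {
          if (pos0 >= tx$tx_end && pos0 < tx$tx_end + flank_bp)
            consider("upstream", g$gene_id)
          if (pos0 >= tx$tx_start - flank_bp && pos0 < tx$tx_start)
            consider("downstream", g$gene_id)
        }
      }
    }
  }
  list(variant_id = variant$id, category = best$category,
       gene_id = best$gene_id, noncoding = best$noncoding)
}

#' Classify many variants
#'
#' @param variants Variant table.
#' @param genes List of `GeneModel` objects.
#' @param flank_bp Upstream/downstream window (default 1000).
#' @return A `data.frame` with columns `variant_id`, `category`, `gene_id`,
#'   `noncoding`.
#' @export
classify_locations <- function(variants, genes, flank_bp = 1000L) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    as.data.frame(classify_location(variants[i, ], genes, flank_bp),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate location categories
#'
#' @param calls Data frame from [classify_locations()] (needs a `category`
#'   column).
#' @return A `data.frame` with `category`, `count`, `proportion` over the
#'   fixed category set; empty input yields zero counts and `NaN`-free empty
#'   proportions.
#' @export
location_summary <- function(calls) {
  cats <- c("exonic", "UTR5", "UTR3", "intronic", "upstream", "downstream",
            "intergenic")
  n <- nrow(calls)
  counts <- vapply(cats, function(ct) sum(calls$category == ct), integer(1))
  data.frame(category = cats, count = counts,
             proportion = if (n > 0) counts / n else rep(NA_real_, length(cats)),
             stringsAsFactors = FALSE)
}
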