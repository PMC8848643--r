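#' Read genotypes from a VCF file
#'
#' Loads a VCF 4.x file (via \pkg{vcfR}) into a [genotype_matrix()].
#' Biallelic records are loaded directly; multiallelic records are either
#' decomposed into one biallelic variant per alternate allele (default) or
#' skipped, with the count reported via `attr(x, "multiallelic")`. Phase is
#' preserved (a haplotype matrix is attached) only when every genotype call
#' uses the `|` separator. Missing genotypes become `NA` dosages and are
#' tallied in `attr(x, "missingness")`.
#'
#' @param path Path to a VCF file.
#' @param multiallelic `"split"` (default) or `"skip"`.
#' @return A `GenotypeMatrix` with attributes `missingness` (per-variant NA
#'   counts) and `multiallelic` (number of multiallelic source records).
#' @export
read_vcf <- function(path, multiallelic = c("split", "skip")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt))
    stop_regsnp("regsnp_format_error", "VCF has no GT field: ", path)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)

  chrom <- character(0); pos <- integer(0); id <- character(0)
  ref <- character(0); alt <- character(0)
  alt_index <- integer(0)  # which ALT allele each output variant came from
  src_row <- integer(0)
  n_multi <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1L) {
      n_multi <- n_multi + 1L
      if (multiallelic == "skip") next
    }
    for (k in seq_along(alts)) {
      chrom <- c(chrom, fix[i, "CHROM"]); pos <- c(pos, as.integer(fix[i, "POS"]))
      vid <- fix[i, "ID"]
      if (is.na(vid) || vid == ".") vid <- sprintf("%s_%s", fix[i, "CHROM"], fix[i, "POS"])
      if (length(alts) > 1L) vid <- sprintf("%s_alt%d", vid, k)
      id <- c(id, vid); ref <- c(ref, fix[i, "REF"]); alt <- c(alt, alts[k])
      alt_index <- c(alt_index, k); src_row <- c(src_row, i)
    }
  }
  variants <- variant_table(chrom, pos, id, ref, alt)

  n <- length(samples); m <- nrow(variants)
  dos <- matrix(NA_integer_, n, m)
  hap <- matrix(NA_integer_, 2L * n, m)
  phased <- TRUE
  for (j in seq_len(m)) {
    g <- gt[src_row[j], ]
    g[is.na(g)] <- "./."
    sep_pipe <- grepl("|", g, fixed = TRUE)
    miss <- g %in% c("./.", ".|.", ".")
    phased <- phased && all(sep_pipe | miss)
    al <- strsplit(g, "[/|]")
    for (s in seq_len(n)) {
      a <- al[[s]]
      if (length(a) != 2L || any(a == "."))  next
      a_num <- suppressWarnings(as.integer(a))
      if (any(is.na(a_num)))
        stop_regsnp("regsnp_format_error",
                    sprintf("malformed GT '%s' at record %d", g[s], src_row[j]))
      h <- as.integer(a_num == alt_index[j])
      hap[2L * s - 1L, j] <- h[1]; hap[2L * s, j] <- h[2]
      dos[s, j] <- sum(h)
    }
  }
  gm <- genotype_matrix(samples, variants, dos,
                        haplotypes = if (phased && !anyNA(hap)) hap else NULL)
  attr(gm, "missingness") <- colSums(is.na(dos))
  attr(gm, "multiallelic") <- n_multi
  gm
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF 4.2 file with GT fields. Phased haplotypes are written
#' with `|` separators when present, otherwise unphased `/` genotypes
#' (heterozygotes as `0/1`).
#'
#' @param gm A `GenotypeMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")), con)
  for (j in seq_len(nrow(v))) {
    if (!is.null(gm$haplotypes)) {
      h1 <- gm$haplotypes[seq(1, nrow(gm$haplotypes), 2), j]
      h2 <- gm$haplotypes[seq(2, nrow(gm$haplotypes), 2), j]
      g <- paste(h1, h2, sep = "|")
    } else {
      d <- gm$dosages[, j]
      g <- c("0/0", "0/1", "1/1")[d + 1L]
      g[is.na(d)] <- "./."
    }
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".",
                       "PASS", ".", "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}
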