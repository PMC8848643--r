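#' Construct a variant table
#'
#' Variants are kept as a plain data frame with one row per biallelic SNV or
#' indel, VCF-style: `pos` is the 1-based position of the first reference
#' base, and indels may share a leading base between `ref` and `alt`.
#'
#' @param chrom Character vector of contig names.
#' @param pos Integer vector, 1-based position of the first ref base.
#' @param id Character vector of variant identifiers.
#' @param ref,alt Allele strings over A/C/G/T; `ref != alt`, both non-empty.
#' @return A `data.frame` with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
variant_table <- function(chrom, pos, id, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(pos < 1)) stop_regsnp("regsnp_format_error", "variant pos must be >= 1")
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop_regsnp("regsnp_format_error", "ref and alt alleles must be non-empty")
  if (any(ref == alt))
    stop_regsnp("regsnp_format_error", "ref and alt alleles must differ")
  bad <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt)
  if (any(bad))
    stop_regsnp("regsnp_format_error", "alleles must be strings over {A,C,G,T}: ",
                paste(id[bad], collapse = ", "))
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             id = as.character(id), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' Container for diploid genotypes of `n` samples at `m` biallelic variants.
#' `dosages` counts alternate alleles (0/1/2, `NA` for missing). When the
#' source genotypes were fully phased, `haplotypes` holds the `2n x m` binary
#' haplotype matrix (rows `2i-1`, `2i` are the two haplotypes of sample `i`)
#' whose per-sample column sums reproduce `dosages`.
#'
#' @param sample_ids Character vector of length `n`.
#' @param variants Variant table (see [variant_table()]) with `m` rows.
#' @param dosages `n x m` integer matrix in `{0,1,2,NA}`.
#' @param haplotypes Optional `2n x m` 0/1 matrix.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(sample_ids, variants, dosages, haplotypes = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != nrow(variants))
    stop_regsnp("regsnp_format_error", "dosage dimensions do not match samples/variants")
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (nrow(haplotypes) != 2L * length(sample_ids) ||
        ncol(haplotypes) != nrow(variants))
      stop_regsnp("regsnp_format_error", "haplotype dimensions must be 2n x m")
    agg <- haplotypes[seq(1, nrow(haplotypes), 2), , drop = FALSE] +
      haplotypes[seq(2, nrow(haplotypes), 2), , drop = FALSE]
    ok <- is.na(dosages) | agg == dosages
    if (!all(ok))
      stop_regsnp("regsnp_format_error", "haplotypes do not aggregate to dosages")
  }
  colnames(dosages) <- variants$id
  rownames(dosages) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids), variants = variants,
                 dosages = dosages, haplotypes = haplotypes),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants (%s)\n",
              length(x$sample_ids), nrow(x$variants),
              if (is.null(x$haplotypes)) "unphased" else "phased"))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosages)
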