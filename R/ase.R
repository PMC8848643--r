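#' Exact binomial test of allele-specific expression at one SNP
#'
#' Tests whether the reference/alternate read-count ratio at a heterozygous
#' transcribed SNP departs from the expected null ratio, with the standard
#' two-sided exact convention (summing the probabilities of all outcomes at
#' most as likely as the observed one, as `stats::binom.test` does). SNPs
#' with fewer than `min_reads` total reads are filtered: they receive no
#' p-value and `passed_depth = FALSE`.
#'
#' @param ref_count,alt_count Non-negative integer read counts.
#' @param null_ratio Expected null reference-allele fraction in (0,1);
#'   default 0.5 (a reference-bias-adjusted ratio may be supplied per SNP).
#' @param min_reads Minimum total depth to test (default 8).
#' @param variant_id Optional identifier carried through.
#' @return One-row `data.frame`: `variant_id`, `ref_count`, `alt_count`,
#'   `null_ratio`, `pvalue` (`NA` below depth), `passed_depth`.
#' @export
ase_binomial <- function(ref_count, alt_count, null_ratio = 0.5,
                         min_reads = 8L, variant_id = NA_character_) {
  if (ref_count < 0 || alt_count < 0 ||
      ref_count != round(ref_count) || alt_count != round(alt_count))
    stop_regsnp("regsnp_input_error", "read counts must be non-negative integers")
  if (null_ratio <= 0 || null_ratio >= 1)
    stop_regsnp("regsnp_input_error", "null_ratio must lie in (0,1)")
  n <- ref_count + alt_count
  passed <- n >= min_reads
  p <- if (passed)
    stats::binom.test(ref_count, n, p = null_ratio)$p.value
  else NA_real_
  data.frame(variant_id = variant_id, ref_count = as.integer(ref_count),
             alt_count = as.integer(alt_count), null_ratio = null_ratio,
             pvalue = p, passed_depth = passed, stringsAsFactors = FALSE)
}

#' Run the ASE binomial test over a count table
#'
#' @param counts Data frame with columns `variant_id`, `ref_count`,
#'   `alt_count`, and optionally `null_ratio` (default 0.5 per SNP).
#' @param null_ratio Fallback null ratio for rows without their own.
#' @param min_reads Minimum total depth (default 8).
#' @return Data frame of [ase_binomial()] records, one row per SNP.
#' @export
ase_test <- function(counts, null_ratio = 0.5, min_reads = 8L) {
  nr <- counts$null_ratio %||% rep(null_ratio, nrow(counts))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    ase_binomial(counts$ref_count[i], counts$alt_count[i], nr[i], min_reads,
                 variant_id = counts$variant_id[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Catalogue SNPs showing allele-specific expression
#'
#' @param records Data frame of ASE records (see [ase_test()]).
#' @param alpha Significance threshold on the binomial p (default 0.05).
#' @return List with `ase_snps` (ids with `p < alpha` among depth-passing
#'   records), `n_tested`, `n_total`, and `n_significant`.
#' @export
ase_catalogue <- function(records, alpha = 0.05) {
  tested <- records[records$passed_depth & !is.na(records$pvalue), , drop = FALSE]
  sig <- tested[tested$pvalue < alpha, , drop = FALSE]
  list(ase_snps = sig$variant_id, n_total = nrow(records),
       n_tested = nrow(tested), n_significant = nrow(sig))
}
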