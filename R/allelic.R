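#' Build the two allelic flank sequences of a variant
#'
#' Extracts `flank_bp` bases either side of the variant and substitutes each
#' allele, yielding the reference-allele and alternate-allele sequences (41 bp
#' each for SNVs at the default flank; lengths differ for indels). The
#' variant's span within each sequence (0-based half-open) is recorded for
#' the overlap rule.
#'
#' @param variant One-row variant table (see [variant_table()]) or a list with
#'   `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param genome A `SequenceStore`.
#' @param flank_bp Flank width (default 20).
#' @return An object of class `AllelicSequences`.
#' @export
allelic_sequences <- function(variant, genome, flank_bp = 20L) {
  pos0 <- variant$pos - 1L
  ref <- variant$ref; alt <- variant$alt
  L <- genome$lengths[[variant$chrom]]
  if (is.null(L))
    stop_regsnp("regsnp_key_error", "unknown contig: ", variant$chrom)
  if (pos0 - flank_bp < 0 || pos0 + nchar(ref) + flank_bp > L)
    stop_regsnp("regsnp_boundary_error",
                "flank runs off contig for variant ", variant$id)
  genome_ref <- fetch_seq(genome, variant$chrom, pos0, pos0 + nchar(ref))
  if (genome_ref != ref)
    stop_regsnp("regsnp_reference_mismatch_error",
                sprintf("variant %s: ref allele '%s' disagrees with genome '%s'",
                        variant$id, ref, genome_ref))
  left <- fetch_seq(genome, variant$chrom, pos0 - flank_bp, pos0)
  right <- fetch_seq(genome, variant$chrom, pos0 + nchar(ref),
                     pos0 + nchar(ref) + flank_bp)
  structure(list(variant = variant,
                 ref_seq = paste0(left, ref, right),
                 alt_seq = paste0(left, alt, right),
                 ref_snp_span = c(flank_bp, flank_bp + nchar(ref)),
                 alt_snp_span = c(flank_bp, flank_bp + nchar(alt)),
                 flank_bp = flank_bp),
            class = "AllelicSequences")
}

# Best variant-overlapping match on one allelic sequence.
best_overlapping_match <- function(pwm, seq, span, allele, dist = NULL) {
  sw <- score_windows(pwm, seq)
  keep <- sw$offset < span[2] & sw$offset + pwm$width > span[1]
  sw <- sw[keep, , drop = FALSE]
  if (nrow(sw) == 0) return(NULL)
  sw$pvalue <- score_pvalue(pwm, sw$score, dist = dist)
  ord <- order(sw$pvalue, -sw$score, sw$offset, sw$strand)
  b <- sw[ord[1], ]
  list(motif = pwm$tf_name, allele = allele, offset = b$offset,
       strand = b$strand, llr = b$score, pvalue = b$pvalue,
       overlaps_variant = TRUE)
}

# Map a window offset from one allelic sequence onto the other: offsets left
# of the variant span are shared; offsets past it shift by the allele length
# difference.
map_offset <- function(offset, span_start, from_len, to_len) {
  if (offset <= span_start) offset else offset + (to_len - from_len)
}

# LLR of the window at (offset, strand) on seq, or NA if out of range.
llr_at <- function(pwm, seq, offset, strand) {
  if (offset < 0 || offset + pwm$width > nchar(seq)) return(NA_real_)
  sw <- score_windows(pwm, seq)
  sw$score[sw$offset == offset & sw$strand == strand]
}

#' Scan both alleles of a variant against one PWM
#'
#' Scores every window on both strands of each allelic sequence, keeps the
#' windows overlapping the variant span by at least one base, and returns the
#' minimum-p match per allele (regardless of threshold; ties broken by higher
#' LLR, then leftmost offset, then + strand). Also reports `delta_llr`, the
#' reference-minus-alternate LLR evaluated at the better (smaller p) allele's
#' window position, mapped across any indel length change.
#'
#' @param pwm A `PWM`.
#' @param seqs An [allelic_sequences()] result.
#' @param p_threshold Recorded on the result for downstream calling.
#' @return List with `ref` and `alt` matches (each a list or `NULL`),
#'   `delta_llr`, and `p_threshold`.
#' @export
scan_alleles <- function(pwm, seqs, p_threshold = 1e-3) {
  if (is.null(pwm$cache$dist)) pwm$cache$dist <- build_score_distribution(pwm)
  dist <- pwm$cache$dist
  ref <- best_overlapping_match(pwm, seqs$ref_seq, seqs$ref_snp_span, "ref", dist)
  alt <- best_overlapping_match(pwm, seqs$alt_seq, seqs$alt_snp_span, "alt", dist)
  delta <- NA_real_
  if (!is.null(ref) && !is.null(alt)) {
    if (ref$pvalue <= alt$pvalue) {
      o <- map_offset(ref$offset, seqs$ref_snp_span[1],
                      nchar(seqs$ref_seq), nchar(seqs$alt_seq))
      other <- llr_at(pwm, seqs$alt_seq, o, ref$strand)
      delta <- if (is.na(other)) ref$llr - alt$llr else ref$llr - other
    } else {
      o <- map_offset(alt$offset, seqs$alt_snp_span[1],
                      nchar(seqs$alt_seq), nchar(seqs$ref_seq))
      other <- llr_at(pwm, seqs$ref_seq, o, alt$strand)
      delta <- if (is.na(other)) ref$llr - alt$llr else other - alt$llr
    }
  }
  list(ref = ref, alt = alt, delta_llr = delta, p_threshold = p_threshold)
}

#' Call whether a variant disrupts a TF's binding site
#'
#' In `one_pass` mode (default) a variant is disrupting iff exactly one
#' allele's best overlapping match is significant at `p_threshold`; the
#' direction is `loss` when the reference allele passes and `gain` when the
#' alternate does. In `delta` mode the variant is disrupting iff either
#' allele passes and `|delta_llr| > delta_min`.
#'
#' @param ref_match,alt_match Matches from [scan_alleles()] (may be `NULL`).
#' @param p_threshold Match significance threshold (default 1e-3).
#' @param mode `"one_pass"` or `"delta"`.
#' @param delta_min Minimum |LLR difference| in `delta` mode.
#' @param delta_llr Optional LLR difference at the better allele's window (as
#'   computed by [scan_alleles()]); defaults to the difference of the two
#'   best-match LLRs.
#' @return An object of class `DisruptionCall`: list with `tf_name`,
#'   `best_ref_match`, `best_alt_match`, `delta_llr`, `disrupting`,
#'   `direction` (`"loss"`, `"gain"`, or `"none"`), and `mode`.
#' @export
call_disruption <- function(ref_match, alt_match, p_threshold = 1e-3,
                            mode = c("one_pass", "delta"), delta_min = 0,
                            delta_llr = NULL) {
  mode <- match.arg(mode)
  p_ref <- if (is.null(ref_match)) 1 else ref_match$pvalue
  p_alt <- if (is.null(alt_match)) 1 else alt_match$pvalue
  llr_ref <- if (is.null(ref_match)) -Inf else ref_match$llr
  llr_alt <- if (is.null(alt_match)) -Inf else alt_match$llr
  if (is.null(delta_llr) || is.na(delta_llr)) delta_llr <- llr_ref - llr_alt
  ref_pass <- p_ref < p_threshold
  alt_pass <- p_alt < p_threshold
  if (mode == "one_pass") {
    disrupting <- xor(ref_pass, alt_pass)
    direction <- if (!disrupting) "none" else if (ref_pass) "loss" else "gain"
  } else {
    disrupting <- (ref_pass || alt_pass) && abs(delta_llr) > delta_min
    direction <- if (!disrupting) "none" else if (delta_llr > 0) "loss" else "gain"
  }
  structure(list(tf_name = if (!is.null(ref_match)) ref_match$motif
                 else if (!is.null(alt_match)) alt_match$motif else NA_character_,
                 best_ref_match = ref_match, best_alt_match = alt_match,
                 delta_llr = delta_llr, disrupting = disrupting,
                 direction = direction, mode = mode),
            class = "DisruptionCall")
}

#' Scan a set of variants against a set of PWMs and call disruptions
#'
#' Convenience driver over [allelic_sequences()], [scan_alleles()] and
#' [call_disruption()]: one row per variant x motif.
#'
#' @param variants Variant table.
#' @param genome A `SequenceStore`.
#' @param pwms List of `PWM` objects (or `PFM`s, converted with defaults).
#' @param flank_bp Flank width (default 20).
#' @param p_threshold Match significance threshold (default 1e-3).
#' @param mode Calling mode, see [call_disruption()].
#' @param delta_min Minimum |LLR difference| in `delta` mode.
#' @return A `data.frame` with columns `variant_id`, `tf`, `p_ref`, `p_alt`,
#'   `llr_ref`, `llr_alt`, `delta_llr`, `direction`, `disrupting`.
#' @export
scan_variants <- function(variants, genome, pwms, flank_bp = 20L,
                          p_threshold = 1e-3, mode = "one_pass",
                          delta_min = 0) {
  pwms <- lapply(pwms, function(p) if (inherits(p, "PFM")) pwm_from_pfm(p) else p)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    seqs <- allelic_sequences(variants[i, ], genome, flank_bp)
    for (p in pwms) {
      sc <- scan_alleles(p, seqs, p_threshold)
      call <- call_disruption(sc$ref, sc$alt, p_threshold, mode, delta_min,
                              delta_llr = sc$delta_llr)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = variants$id[i], tf = p$tf_name,
        p_ref = if (is.null(sc$ref)) NA_real_ else sc$ref$pvalue,
        p_alt = if (is.null(sc$alt)) NA_real_ else sc$alt$pvalue,
        llr_ref = if (is.null(sc$ref)) NA_real_ else sc$ref$llr,
        llr_alt = if (is.null(sc$alt)) NA_real_ else sc$alt$llr,
        delta_llr = call$delta_llr, direction = call$direction,
        disrupting = call$disrupting, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize disruption calls
#'
#' @param calls Data frame as produced by [scan_variants()].
#' @return List with `per_tf` (named vector: number of disrupting SNPs per
#'   TF), `per_snp` (named vector: number of TFs disrupted per SNP, over SNPs
#'   with at least one call), and `co_matrix` (symmetric TF x TF matrix whose
#'   off-diagonal cells count SNPs disrupting both TFs; diagonal = `per_tf`).
#' @export
summarize_disruptions <- function(calls) {
  tfs <- sort(unique(calls$tf))
  if (nrow(calls) == 0 || length(tfs) == 0)
    return(list(per_tf = integer(0), per_snp = integer(0),
                co_matrix = matrix(0L, 0, 0)))
  d <- calls[calls$disrupting, , drop = FALSE]
  per_tf <- vapply(tfs, function(tf) length(unique(d$variant_id[d$tf == tf])),
                   integer(1))
  snps <- sort(unique(d$variant_id))
  per_snp <- vapply(snps, function(s) length(unique(d$tf[d$variant_id == s])),
                    integer(1))
  co <- matrix(0L, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (s in snps) {
    hit <- sort(unique(d$tf[d$variant_id == s]))
    for (a in hit) for (b in hit) co[a, b] <- co[a, b] + 1L
  }
  list(per_tf = per_tf, per_snp = per_snp, co_matrix = co)
}
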