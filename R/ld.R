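#' EM estimate of two-site haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic sites
#' from unphased dosage vectors, by the classic two-locus EM: every genotype
#' combination except the double heterozygote determines its two haplotypes;
#' the double heterozygotes are split between the cis (`AB/ab`) and trans
#' (`Ab/aB`) configurations by their expected frequencies at each iteration.
#' `A`/`B` denote the alternate allele at the first/second site.
#'
#' The two-locus likelihood can have a second stationary point, so the EM is
#' restarted from linkage equilibrium and from both maximal-|D| corners; the
#' fixed point with the highest observed-data likelihood is returned.
#'
#' @param dosages_a,dosages_b Integer vectors in `{0,1,2,NA}` of equal length
#'   (alternate-allele dosages). Missing entries are removed pairwise.
#' @param tol Convergence tolerance on the maximum absolute frequency change.
#' @param max_iter Iteration cap.
#' @return Named numeric vector `c(pAB, pAb, paB, pab)` summing to 1.
#' @export
em_haplotype_freqs <- function(dosages_a, dosages_b, tol = 1e-8, max_iter = 1000L) {
  if (length(dosages_a) != length(dosages_b))
    stop_regsnp("regsnp_input_error", "dosage vectors must have equal length")
  keep <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[keep]; b <- dosages_b[keep]
  if (length(a) < 2L)
    stop_regsnp("regsnp_insufficient_data_error",
                "fewer than 2 pairwise-complete samples")
  pA <- mean(a) / 2; pB <- mean(b) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop_regsnp("regsnp_undefined_ld_error",
                "monomorphic site: haplotype frequencies/LD undefined")

  # Determined haplotype counts from the 3x3 genotype table (double het aside)
  tab <- matrix(0, 3, 3)
  for (k in seq_along(a)) tab[a[k] + 1L, b[k] + 1L] <- tab[a[k] + 1L, b[k] + 1L] + 1
  base <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in 0:2) for (j in 0:2) {
    n_ij <- tab[i + 1L, j + 1L]
    if (n_ij == 0 || (i == 1 && j == 1)) next
    # alleles carried by the two haplotypes at each site
    ha <- if (i == 1) c(1, 0) else c(i / 2, i / 2)
    hb <- if (j == 1) c(1, 0) else c(j / 2, j / 2)
    for (h in 1:2) {
      key <- paste0(if (ha[h] == 1) "A" else "a", if (hb[h] == 1) "B" else "b")
      base[key] <- base[key] + n_ij
    }
  }
  n_dh <- tab[2, 2]
  n_hap <- 2 * length(a)

  from_pAB <- function(pAB) c(AB = pAB, Ab = pA - pAB, aB = pB - pAB,
                              ab = 1 - pA - pB + pAB)
  run_em <- function(p) {
    for (it in seq_len(max_iter)) {
      cis <- p["AB"] * p["ab"]; trans <- p["Ab"] * p["aB"]
      w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
      cnt <- base + n_dh * c(w, 1 - w, 1 - w, w)
      p_new <- cnt / n_hap
      if (max(abs(p_new - p)) < tol) return(p_new)
      p <- p_new
    }
    p
  }
  loglik <- function(p) {
    # observed-data likelihood of the 3x3 genotype table under random pairing
    P <- matrix(0, 3, 3)
    hapA <- c(1, 1, 0, 0); hapB <- c(1, 0, 1, 0)
    for (h1 in 1:4) for (h2 in 1:4)
      P[hapA[h1] + hapA[h2] + 1L, hapB[h1] + hapB[h2] + 1L] <-
        P[hapA[h1] + hapA[h2] + 1L, hapB[h1] + hapB[h2] + 1L] + p[h1] * p[h2]
    sum(tab * log(P + 1e-300))
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  starts <- list(from_pAB(pA * pB),
                 from_pAB(lo + 0.98 * (hi - lo)),
                 from_pAB(lo + 0.02 * (hi - lo)))
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, loglik, numeric(1)))]]
  stats::setNames(as.numeric(best), c("pAB", "pAb", "paB", "pab"))
}

#' Haplotype frequencies by direct counting of phased haplotypes
#'
#' @param hap_a,hap_b Binary haplotype vectors (one entry per chromosome).
#' @return Named numeric vector `c(pAB, pAb, paB, pab)`.
#' @export
count_haplotype_freqs <- function(hap_a, hap_b) {
  keep <- !is.na(hap_a) & !is.na(hap_b)
  a <- hap_a[keep]; b <- hap_b[keep]
  if (length(a) < 2L)
    stop_regsnp("regsnp_insufficient_data_error", "too few phased haplotypes")
  c(pAB = mean(a == 1 & b == 1), pAb = mean(a == 1 & b == 0),
    paB = mean(a == 0 & b == 1), pab = mean(a == 0 & b == 0))
}

#' Squared correlation r^2 from haplotype frequencies
#'
#' `r2 = D^2 / (pA pa pB pb)` with `D = pAB - pA pB`, clipped to `[0, 1]`
#' against rounding.
#'
#' @param freqs Named vector `c(pAB, pAb, paB, pab)` summing to 1.
#' @return r^2 in `[0, 1]`.
#' @export
r2_from_freqs <- function(freqs) {
  pA <- freqs[["pAB"]] + freqs[["pAb"]]
  pB <- freqs[["pAB"]] + freqs[["paB"]]
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0)
    stop_regsnp("regsnp_undefined_ld_error", "zero allele-frequency margin")
  D <- freqs[["pAB"]] - pA * pB
  min(max(D^2 / denom, 0), 1)
}

#' Pairwise r^2 between two variants of a genotype matrix
#'
#' @param gm A `GenotypeMatrix`.
#' @param i,j Variant ids or column indices.
#' @param method `"em"` (EM haplotype frequencies, the default and the
#'   behavior of standard LD software on unphased data), `"phased"` (direct
#'   haplotype counting; requires phased input), or `"genotype"` (squared
#'   Pearson correlation of dosages, offered as a cross-check).
#' @return r^2 in `[0, 1]`.
#' @export
ld_r2 <- function(gm, i, j, method = c("em", "phased", "genotype")) {
  method <- match.arg(method)
  if (is.character(i)) i <- match(i, gm$variants$id)
  if (is.character(j)) j <- match(j, gm$variants$id)
  if (method == "genotype") {
    ok <- stats::complete.cases(gm$dosages[, c(i, j)])
    return(stats::cor(gm$dosages[ok, i], gm$dosages[ok, j])^2)
  }
  if (method == "phased") {
    if (is.null(gm$haplotypes))
      stop_regsnp("regsnp_input_error", "no phased haplotypes available")
    return(r2_from_freqs(count_haplotype_freqs(gm$haplotypes[, i],
                                               gm$haplotypes[, j])))
  }
  r2_from_freqs(em_haplotype_freqs(gm$dosages[, i], gm$dosages[, j]))
}

#' Expand index SNPs to LD proxies
#'
#' For each index SNP, returns every variant whose position lies within
#' `window_kb` kilobases and whose r^2 with the index strictly exceeds
#' `r2_min` (the index SNP itself is always returned with r^2 = 1). Pairs for
#' which LD is undefined (monomorphic proxy) are skipped. Output is ordered by
#' index (input order) then proxy position.
#'
#' @param index_ids Character vector of index SNP ids present in `genotypes`.
#' @param genotypes A `GenotypeMatrix`.
#' @param window_kb Window half-width in kb, measured index position to proxy
#'   position (default 1000, i.e. 1 Mb).
#' @param r2_min Strict lower r^2 cutoff (default 0.6).
#' @param method r^2 method passed to [ld_r2()]; the default `"auto"` counts
#'   haplotypes directly when the genotypes are phased (as reference-panel
#'   data are) and falls back to the two-site EM otherwise.
#' @return A `data.frame` with columns `index_id`, `proxy_id`, `r2`,
#'   `distance_bp`.
#' @export
expand_index_snps <- function(index_ids, genotypes, window_kb = 1000,
                              r2_min = 0.6, method = c("auto", "em", "phased",
                                                       "genotype")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (is.null(genotypes$haplotypes)) "em" else "phased"
  v <- genotypes$variants
  missing_ids <- setdiff(index_ids, v$id)
  if (length(missing_ids))
    stop_regsnp("regsnp_lookup_error", "index SNP(s) not in genotypes: ",
                paste(missing_ids, collapse = ", "))
  out <- list()
  for (ix in index_ids) {
    i <- match(ix, v$id)
    near <- which(v$chrom == v$chrom[i] &
                    abs(v$pos - v$pos[i]) <= window_kb * 1000)
    near <- near[order(v$pos[near])]
    rows <- lapply(near, function(j) {
      if (j == i)
        return(data.frame(index_id = ix, proxy_id = v$id[j], r2 = 1,
                          distance_bp = 0L))
      r2 <- tryCatch(ld_r2(genotypes, i, j, method = method),
                     regsnp_undefined_ld_error = function(e) NA_real_,
                     regsnp_insufficient_data_error = function(e) NA_real_)
      if (is.na(r2) || r2 <= r2_min) return(NULL)
      data.frame(index_id = ix, proxy_id = v$id[j], r2 = r2,
                 distance_bp = abs(v$pos[j] - v$pos[i]))
    })
    out <- c(out, rows)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
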