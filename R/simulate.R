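#' Simulate a haplotype block with controlled pairwise r^2
#'
#' Generates `2*n_samples` haplotypes by copy-with-recombination: the index
#' SNP's haplotype column is drawn Bernoulli at a MAF sampled from
#' `maf_range`, and each proxy copies the index allele with probability
#' `sqrt(target_r2)` (else redraws from the index allele frequency), which
#' yields haplotype correlation `r = sqrt(target_r2)` in expectation. Targets
#' of 0 get an independent column at its own MAF. Each proxy is redrawn up to
#' `max_tries` times and the draw whose realized r^2 is closest to target is
#' kept. Diploids are formed by pairing consecutive haplotypes; the result is
#' phased.
#'
#' @param n_samples Number of diploid samples (default 503).
#' @param n_snps Total SNPs including the index (first SNP).
#' @param target_r2_profile Numeric vector in `[0,1]` of target r^2 values for
#'   the `n_snps - 1` proxies (recycled).
#' @param maf_range Length-2 range of minor-allele frequencies.
#' @param seed Integer seed.
#' @param chrom Contig name for the variant table.
#' @param start_pos Position of the index SNP (1-based).
#' @param spacing_bp Distance between consecutive SNPs (default 1000).
#' @return List with `genotypes` (phased `GenotypeMatrix`, index SNP first)
#'   and `truth` (`index_id`, data frame `planted_ld` with target and
#'   realized haplotype r^2 per proxy, `seed`).
#' @export
simulate_haplotype_block <- function(n_samples = 503L, n_snps = 10L,
                                     target_r2_profile = c(0.2, 0.61, 0.9),
                                     maf_range = c(0.1, 0.5), seed = 1L,
                                     chrom = "chr1", start_pos = 500000L,
                                     spacing_bp = 1000L) {
  targets <- rep_len(target_r2_profile, n_snps - 1L)
  if (any(targets < 0 | targets > 1))
    stop_regsnp("regsnp_feasibility_error", "target r^2 must lie in [0,1]")
  set.seed(derive_seed(seed, 1L))
  n_hap <- 2L * n_samples
  draw_poly <- function(p) {
    for (i in 1:100) {
      h <- stats::rbinom(n_hap, 1L, p)
      if (sum(h) > 0 && sum(h) < n_hap) return(h)
    }
    stop_regsnp("regsnp_feasibility_error", "could not draw a polymorphic column")
  }
  p0 <- stats::runif(1, maf_range[1], maf_range[2])
  h0 <- draw_poly(p0)
  H <- matrix(0L, n_hap, n_snps)
  H[, 1] <- h0
  realized <- numeric(n_snps - 1L)
  max_tries <- 50L
  for (k in seq_len(n_snps - 1L)) {
    t <- targets[k]
    best <- NULL
    for (try in seq_len(max_tries)) {
      if (t == 0) {
        pk <- stats::runif(1, maf_range[1], maf_range[2])
        y <- draw_poly(pk)
      } else if (t == 1) {
        y <- h0
      } else {
        rho <- sqrt(t)
        copy <- stats::runif(n_hap) < rho
        y <- ifelse(copy, h0, stats::rbinom(n_hap, 1L, p0))
        if (sum(y) == 0 || sum(y) == n_hap) next
      }
      r2 <- suppressWarnings(stats::cor(h0, y)^2)
      if (is.na(r2)) r2 <- if (identical(y, h0)) 1 else 0
      if (is.null(best) || abs(r2 - t) < abs(best$r2 - t)) best <- list(y = y, r2 = r2)
      if (abs(best$r2 - t) < 0.005) break
    }
    H[, k + 1L] <- best$y
    realized[k] <- best$r2
  }
  ids <- c("snp_index", sprintf("snp_%02d", seq_len(n_snps - 1L)))
  v <- variant_table(chrom, start_pos + (0:(n_snps - 1L)) * spacing_bp, ids,
                     rep("A", n_snps), rep("G", n_snps))
  dos <- H[seq(1, n_hap, 2), , drop = FALSE] + H[seq(2, n_hap, 2), , drop = FALSE]
  gm <- genotype_matrix(sprintf("sample_%03d", seq_len(n_samples)), v, dos, H)
  list(genotypes = gm,
       truth = list(index_id = ids[1],
                    planted_ld = data.frame(index_id = ids[1],
                                            proxy_id = ids[-1],
                                            target_r2 = targets,
                                            realized_r2 = realized),
                    seed = seed))
}

#' Generate a random position frequency matrix
#'
#' Two regimes: with `consensus_prob` set, each column gives that probability
#' to a uniformly drawn consensus base and splits the rest evenly (an
#' informative, binding-site-like motif: `consensus_prob = 0.88` is about
#' 1.28 bits per column); otherwise column probabilities are drawn from a
#' symmetric Dirichlet with concentration `alpha` (a generic random motif).
#'
#' @param width Motif width.
#' @param n_sites Site count scaling the counts matrix (default 20).
#' @param consensus_prob Probability of the consensus base per column, or
#'   `NULL` for the Dirichlet regime.
#' @param alpha Dirichlet concentration (default 0.5).
#' @param seed Integer seed.
#' @return A [pfm()].
#' @export
random_pfm <- function(width = 12L, n_sites = 20, consensus_prob = 0.88,
                       alpha = 0.5, seed = 1L) {
  set.seed(derive_seed(seed, 9L))
  probs <- matrix(0, 4, width)
  if (!is.null(consensus_prob)) {
    cons <- sample.int(4L, width, replace = TRUE)
    probs[] <- (1 - consensus_prob) / 3
    probs[cbind(cons, seq_len(width))] <- consensus_prob
  } else {
    for (j in seq_len(width)) {
      g <- stats::rgamma(4, alpha)
      probs[, j] <- g / sum(g)
    }
  }
  pfm(probs * n_sites, tf_name = sprintf("TF_w%d_s%d", width, seed),
      n_sites = n_sites)
}

# Sample one site from a PFM's column frequencies.
sample_site <- function(freqs) {
  paste(apply(freqs, 2, function(p) sample(DNA_BASES, 1L, prob = p)),
        collapse = "")
}

random_dna <- function(n, background = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = background), collapse = "")
}

#' Simulate peak-flank sequences under a ZOOPS model
#'
#' Each sequence is i.i.d. background; with probability `zoops_prob` one site
#' sampled from the motif's column frequencies is planted at a uniform
#' offset.
#'
#' @param pfm_obj Planted motif, a [pfm()].
#' @param n_seqs Number of sequences (default 500).
#' @param seq_len Sequence length (default 41, a summit +/- 20 bp flank).
#' @param zoops_prob Per-sequence site probability (default 0.9).
#' @param background Background base probabilities.
#' @param seed Integer seed.
#' @return List with `seqs` (character vector) and `truth` (`planted_pfm`,
#'   data frame `sites` of per-sequence 0-based offsets, `NA` when absent,
#'   `seed`).
#' @export
simulate_peak_set <- function(pfm_obj, n_seqs = 500L, seq_len = 41L,
                              zoops_prob = 0.9, background = rep(0.25, 4),
                              seed = 1L) {
  w <- ncol(pfm_obj$counts)
  if (seq_len < w)
    stop_regsnp("regsnp_input_error", "seq_len shorter than motif width")
  set.seed(derive_seed(seed, 2L))
  f <- pfm_freqs(pfm_obj)
  seqs <- character(n_seqs)
  offsets <- rep(NA_integer_, n_seqs)
  for (i in seq_along(seqs)) {
    s <- random_dna(seq_len, background)
    if (stats::runif(1) < zoops_prob) {
      off <- sample.int(seq_len - w + 1L, 1L) - 1L
      site <- sample_site(f)
      substr(s, off + 1L, off + w) <- site
      offsets[i] <- off
    }
    seqs[i] <- s
  }
  names(seqs) <- sprintf("seq_%03d", seq_along(seqs))
  list(seqs = seqs,
       truth = list(planted_pfm = pfm_obj,
                    sites = data.frame(seq = names(seqs), offset = offsets),
                    seed = seed))
}

#' Simulate scored ChIP-Seq peaks on a synthetic genome
#'
#' Builds one background contig, places non-overlapping peak intervals on it,
#' plants one motif consensus-sampled site near each peak summit (within the
#' summit +/- `flank_bp` window that [top_peak_flanks()] extracts), and
#' assigns random peak heights.
#'
#' @param pfm_obj Planted motif.
#' @param n_peaks Number of peaks (default 500).
#' @param peak_width Width of each peak interval (default 200).
#' @param gap_bp Gap between peaks (default 100).
#' @param flank_bp Summit flank inside which the site is planted (default 20).
#' @param seed Integer seed.
#' @return List with `genome` (`SequenceStore`), `peaks` (`GRanges` with
#'   `name`/`score`), and `truth` (planted site offsets relative to contig).
#' @export
simulate_chipseq_peaks <- function(pfm_obj, n_peaks = 500L, peak_width = 200L,
                                   gap_bp = 100L, flank_bp = 20L, seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  w <- ncol(pfm_obj$counts)
  f <- pfm_freqs(pfm_obj)
  step <- peak_width + gap_bp
  total <- n_peaks * step + gap_bp
  genome <- random_dna(total)
  starts <- gap_bp + (0:(n_peaks - 1L)) * step   # 0-based
  site_pos <- integer(n_peaks)
  for (i in seq_len(n_peaks)) {
    summit <- starts[i] + peak_width %/% 2L
    lo <- summit - flank_bp; hi <- summit + flank_bp + 1L - w
    pos <- sample(lo:hi, 1L)
    substr(genome, pos + 1L, pos + w) <- sample_site(f)
    site_pos[i] <- pos
  }
  gr <- GenomicRanges::GRanges("chrSim",
                               IRanges::IRanges(start = starts + 1L,
                                                width = peak_width))
  gr$name <- sprintf("peak_%03d", seq_len(n_peaks))
  gr$score <- round(stats::runif(n_peaks, 10, 1000), 1)
  list(genome = sequence_store(c(chrSim = genome)), peaks = gr,
       truth = list(planted_pfm = pfm_obj, site_pos = site_pos, seed = seed))
}

#' Simulate binding-disrupting and null variants with their genome
#'
#' Lays variants on a background contig, one per `block_bp` block. Disrupting
#' variants get a motif consensus written into the genome so that the variant
#' position coincides with the motif's most informative column; the reference
#' allele is the consensus base there and the alternate allele is the base
#' with the lowest log-odds in that column (direction `loss`). Null variants
#' sit in motif-free background with a random alternate allele.
#'
#' @param pfm_obj Planted motif.
#' @param n_disrupting,n_null Variant counts (defaults 200 and 2000).
#' @param block_bp Block length per variant (default 120).
#' @param seed Integer seed.
#' @param target_column `"max_ic"` (default) or an explicit column index, for
#'   sensitivity curves at weaker columns.
#' @param chrom Contig name (default `"chrSim"`).
#' @param id_prefix Variant id prefix (default `"var"`).
#' @return List with `genome` (`SequenceStore`), `variants` (variant table,
#'   shuffled), and `truth` (data frame `id`, `type`, `direction`).
#' @export
simulate_disruption_variants <- function(pfm_obj, n_disrupting = 200L,
                                         n_null = 2000L, block_bp = 120L,
                                         seed = 1L, target_column = "max_ic",
                                         chrom = "chrSim", id_prefix = "var") {
  set.seed(derive_seed(seed, 4L))
  w <- ncol(pfm_obj$counts)
  stopifnot(block_bp >= 2L * (w + 25L))
  n <- n_disrupting + n_null
  genome <- random_dna(n * block_bp)
  consensus <- pfm_consensus(pfm_obj)
  ic <- pfm_information(pfm_obj)
  jstar <- if (identical(target_column, "max_ic")) which.max(ic)
           else as.integer(target_column)
  lo <- pwm_from_pfm(pfm_obj)$log_odds
  worst <- DNA_BASES[which.min(lo[, jstar])]
  type <- sample(rep(c("disrupting", "null"), c(n_disrupting, n_null)))
  centers <- (seq_len(n) - 1L) * block_bp + block_bp %/% 2L   # 0-based
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    c0 <- centers[i]
    if (type[i] == "disrupting") {
      off <- c0 - (jstar - 1L)               # motif start so col jstar sits on c0
      substr(genome, off + 1L, off + w) <- consensus
      ref[i] <- substr(consensus, jstar, jstar)
      alt[i] <- worst
    } else {
      ref[i] <- substr(genome, c0 + 1L, c0 + 1L)
      alt[i] <- sample(setdiff(DNA_BASES, ref[i]), 1L)
    }
  }
  v <- variant_table(chrom, centers + 1L,
                     sprintf("%s_%04d", id_prefix, seq_len(n)), ref, alt)
  genome_store <- stats::setNames(list(genome), chrom)
  list(genome = sequence_store(unlist(genome_store)), variants = v,
       truth = data.frame(id = v$id, type = type,
                          direction = ifelse(type == "disrupting", "loss", "none"),
                          stringsAsFactors = FALSE))
}

#' Simulate allelic read counts for ASE testing
#'
#' Reference counts are drawn `Binomial(depth, imbalance)` per SNP with
#' depths from `depth_sampler`.
#'
#' @param n_snps Number of SNPs.
#' @param depth_sampler Function `n -> integer depths` (default
#'   `Poisson(50)`), or a numeric vector sampled with replacement.
#' @param imbalance True reference-allele fraction(s), recycled (default 0.5,
#'   i.e. no ASE).
#' @param seed Integer seed.
#' @return List with `counts` (data frame `variant_id`, `ref_count`,
#'   `alt_count`) and `truth` (planted imbalance per SNP, `seed`).
#' @export
simulate_ase_counts <- function(n_snps = 100L,
                                depth_sampler = function(n) stats::rpois(n, 50),
                                imbalance = 0.5, seed = 1L) {
  set.seed(derive_seed(seed, 5L))
  depths <- if (is.function(depth_sampler)) depth_sampler(n_snps)
            else sample(depth_sampler, n_snps, replace = TRUE)
  imb <- rep_len(imbalance, n_snps)
  ref <- stats::rbinom(n_snps, depths, imb)
  counts <- data.frame(variant_id = sprintf("ase_%04d", seq_len(n_snps)),
                       ref_count = ref, alt_count = depths - ref,
                       stringsAsFactors = FALSE)
  list(counts = counts,
       truth = data.frame(variant_id = counts$variant_id, imbalance = imb,
                          depth = depths, seed = seed))
}

#' Simulate a cis-eQTL dataset
#'
#' Dosages are `Binomial(2, maf)`; gene 1's expression is
#' `beta * dosage + Normal(0, noise_sd)`, further genes (if any) are pure
#' noise.
#'
#' @param n_samples Number of samples (default 400).
#' @param maf Minor-allele frequency (default 0.3).
#' @param beta Effect size on gene 1, in expression units per allele.
#' @param noise_sd Residual standard deviation (default 1).
#' @param n_genes Number of genes (default 1).
#' @param seed Integer seed.
#' @param dataset Dataset label carried into the outputs.
#' @return List with `genotypes` (`GenotypeMatrix`, one variant),
#'   `expression` (genes x samples matrix), `dataset`, and `truth`.
#' @export
simulate_eqtl_dataset <- function(n_samples = 400L, maf = 0.3, beta = 0.5,
                                  noise_sd = 1, n_genes = 1L, seed = 1L,
                                  dataset = "sim") {
  set.seed(derive_seed(seed, 6L))
  repeat {
    dos <- stats::rbinom(n_samples, 2L, maf)
    if (length(unique(dos)) > 1) break
  }
  expr <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes,
                 n_samples, dimnames = list(sprintf("gene_%02d", seq_len(n_genes)),
                                            sprintf("s_%03d", seq_len(n_samples))))
  expr[1, ] <- expr[1, ] + beta * dos
  v <- variant_table("chr1", 1000L, "eqtl_snp", "A", "G")
  gm <- genotype_matrix(colnames(expr), v, matrix(dos, ncol = 1))
  list(genotypes = gm, expression = expr, dataset = dataset,
       truth = list(beta = beta, maf = maf, noise_sd = noise_sd, seed = seed))
}

#' Simulate a multi-dataset eQTL block with a planted support pattern
#'
#' Builds `n_datasets` independent eQTL datasets over the same `k` SNPs and
#' `k` genes, where SNP `i` drives gene `i` in its first `support_plan[i]`
#' datasets. With `exact_null = TRUE` (default) the planted effect uses the
#' dosage component orthogonal to all other SNPs and the noise is
#' residualized against the full dosage matrix, so every unplanted SNP-gene
#' marginal regression has a coefficient of exactly zero: the realized
#' support tiers equal the planted plan by construction, which is what an
#' integration test needs. Set it to `FALSE` for honestly noisy null cells
#' (used by the calibration tests).
#'
#' @param support_plan Integer vector: per SNP, in how many datasets it is an
#'   eQTL (values in `0..n_datasets`).
#' @param n_datasets Number of datasets (default 4).
#' @param n_samples Samples per dataset (default 200).
#' @param maf,beta,noise_sd Genetics and effect parameters.
#' @param seed Integer seed.
#' @param exact_null Orthogonalize null SNP-gene pairs (default TRUE).
#' @return List with `datasets` (per dataset: `genotypes`, `expression`,
#'   `name`) and `truth` (`support_plan`, `tier_sizes` for >=1/2/3/all).
#' @export
simulate_eqtl_block <- function(support_plan = c(4, 3, 2, 1), n_datasets = 4L,
                                n_samples = 200L, maf = 0.3, beta = 1,
                                noise_sd = 1, seed = 1L, exact_null = TRUE) {
  if (any(support_plan < 0 | support_plan > n_datasets))
    stop_regsnp("regsnp_input_error", "support_plan entries must lie in 0..n_datasets")
  set.seed(derive_seed(seed, 10L))
  k <- length(support_plan)
  ids <- sprintf("snp_%02d", seq_len(k))
  datasets <- list()
  for (d in seq_len(n_datasets)) {
    repeat {
      D <- matrix(stats::rbinom(n_samples * k, 2L, maf), n_samples, k)
      if (all(apply(D, 2, function(x) length(unique(x)) > 1))) break
    }
    E <- matrix(stats::rnorm(n_samples * k, 0, noise_sd), n_samples, k)
    if (exact_null) {
      E <- stats::lm.fit(cbind(1, D), E)$residuals
      Dp <- vapply(seq_len(k), function(i)
        stats::lm.fit(cbind(1, D[, -i, drop = FALSE]), D[, i])$residuals,
        numeric(n_samples))
    } else Dp <- D
    expr <- t(E)
    for (i in seq_len(k))
      if (support_plan[i] >= d) expr[i, ] <- expr[i, ] + beta * Dp[, i]
    rownames(expr) <- sprintf("gene_%02d", seq_len(k))
    colnames(expr) <- sprintf("s_%03d", seq_len(n_samples))
    v <- variant_table("chr1", 1000L + seq_len(k) * 100L, ids,
                       rep("A", k), rep("G", k))
    gm <- genotype_matrix(colnames(expr), v, D)
    datasets[[d]] <- list(genotypes = gm, expression = expr,
                          name = sprintf("dataset_%d", d))
  }
  tier_sizes <- c(ge1 = sum(support_plan >= 1), ge2 = sum(support_plan >= 2),
                  ge3 = sum(support_plan >= 3),
                  all = sum(support_plan == n_datasets))
  list(datasets = datasets,
       truth = list(support_plan = stats::setNames(support_plan, ids),
                    tier_sizes = tier_sizes, seed = seed))
}

#' Simulate case-control expression with planted differential genes
#'
#' Expression is lognormal around a per-gene baseline; the first `n_de` genes
#' are shifted `fold`-fold in cases.
#'
#' @param n_genes Number of genes (default 100).
#' @param n_cases,n_controls Group sizes (defaults 24 and 12).
#' @param n_de Number of differentially expressed genes (default 4).
#' @param fold Fold change planted in cases (default 2).
#' @param cv Coefficient of variation of the lognormal noise (default 0.2).
#' @param seed Integer seed.
#' @return List with `expression` (genes x samples), `labels`
#'   (`"case"`/`"control"`), and `truth` (`de_genes`, `fold`, `seed`).
#' @export
simulate_case_control_expr <- function(n_genes = 100L, n_cases = 24L,
                                       n_controls = 12L, n_de = 4L, fold = 2,
                                       cv = 0.2, seed = 1L) {
  set.seed(derive_seed(seed, 8L))
  n <- n_cases + n_controls
  base <- stats::runif(n_genes, 50, 500)
  sdlog <- sqrt(log(1 + cv^2))
  expr <- matrix(0, n_genes, n)
  for (i in seq_len(n_genes))
    expr[i, ] <- base[i] * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  labels <- rep(c("case", "control"), c(n_cases, n_controls))
  de <- seq_len(min(n_de, n_genes))
  expr[de, labels == "case"] <- expr[de, labels == "case"] * fold
  rownames(expr) <- sprintf("gene_%03d", seq_len(n_genes))
  colnames(expr) <- sprintf("s_%02d", seq_len(n))
  list(expression = expr, labels = labels,
       truth = list(de_genes = rownames(expr)[de], fold = fold, seed = seed))
}
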