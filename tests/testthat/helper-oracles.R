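# Independent oracles used to freeze expected values. Each deliberately uses
# a different algorithm than the implementation it checks.

# Brute-force PWM match p-value: enumerate all 4^w windows by taking outer
# sums column by column (no convolution DP involved).
enum_pvalue <- function(pwm, score) {
  sc <- 0
  pr <- 1
  for (j in seq_len(pwm$width)) {
    sc <- as.vector(outer(sc, pwm$log_odds[, j], "+"))
    pr <- as.vector(outer(pr, pwm$background, "*"))
  }
  vapply(score, function(t) sum(pr[sc >= t - 1e-9]), numeric(1))
}

# Grid-search maximizer of the two-locus genotype multinomial likelihood.
# Margins are fixed at the observed allele frequencies (they are sufficient);
# pAB is scanned over its feasible range at the given step.
grid_haplotype_freqs <- function(da, db, step = 1e-4) {
  keep <- !is.na(da) & !is.na(db)
  da <- da[keep]; db <- db[keep]
  pA <- mean(da) / 2; pB <- mean(db) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  n_tab <- table(factor(da, 0:2), factor(db, 0:2))
  ll <- vapply(grid, function(pAB) {
    h <- c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
    if (any(h < -1e-12)) return(-Inf)
    h <- pmax(h, 1e-300)
    # genotype-combination probabilities under random pairing of haplotypes
    P <- matrix(0, 3, 3)
    combos <- expand.grid(h1 = names(h), h2 = names(h))
    p2 <- h[combos$h1] * h[combos$h2]
    ga <- (combos$h1 %in% c("AB", "Ab")) + (combos$h2 %in% c("AB", "Ab"))
    gb <- (combos$h1 %in% c("AB", "aB")) + (combos$h2 %in% c("AB", "aB"))
    for (r in seq_along(p2)) P[ga[r] + 1, gb[r] + 1] <- P[ga[r] + 1, gb[r] + 1] + p2[r]
    sum(n_tab * log(P + 1e-300))
  }, numeric(1))
  pAB <- grid[which.max(ll)]
  c(pAB = pAB, pAb = pA - pAB, paB = pB - pAB, pab = 1 - pA - pB + pAB)
}

# Closed-form two-sided exact binomial p: sum the probabilities of all
# outcomes whose density does not exceed the observed one.
binom_twosided_oracle <- function(x, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Hand BH step-up.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Random unphased two-site genotype table drawn from random haplotype
# frequencies, guaranteed polymorphic at both sites.
random_geno_pair <- function(n = 20) {
  repeat {
    h <- stats::rgamma(4, 1); h <- h / sum(h)
    hap1 <- sample(1:4, n, replace = TRUE, prob = h)
    hap2 <- sample(1:4, n, replace = TRUE, prob = h)
    a1 <- as.integer(hap1 %in% c(1, 2)); b1 <- as.integer(hap1 %in% c(1, 3))
    a2 <- as.integer(hap2 %in% c(1, 2)); b2 <- as.integer(hap2 %in% c(1, 3))
    da <- a1 + a2; db <- b1 + b2
    if (length(unique(da)) > 1 && length(unique(db)) > 1)
      return(list(da = da, db = db))
  }
}

# Tiny deterministic genome + gene model fixture used by annotation and
# pipeline tests. Coordinates are 0-based half-open.
make_test_gene <- function(gene_id = "geneA", chrom = "chr1", strand = "+",
                           tx = c(1000, 5000), cds = c(1500, 4200),
                           exons = rbind(c(1000, 2000), c(3000, 5000))) {
  gene_model(gene_id, chrom, strand,
             list(tx1 = list(tx_start = tx[1], tx_end = tx[2],
                             cds_start = cds[1], cds_end = cds[2],
                             exons = exons)))
}
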