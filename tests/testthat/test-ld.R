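test_that("EM equals direct haplotype counting when phase is unambiguous", {
  # no double heterozygotes: every genotype combination resolves its haplotypes
  da <- c(0, 0, 2, 2, 1, 1, 0, 2)
  db <- c(0, 0, 2, 2, 0, 2, 0, 2)
  f <- em_haplotype_freqs(da, db)
  # direct counting: (1,0) -> haplotypes Ab? here allele A/B = alternate
  hap_a <- c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0, 1, 0, 0, 0, 1, 1)
  hap_b <- c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1)
  expect_equal(f, count_haplotype_freqs(hap_a, hap_b), tolerance = 1e-9)
})

test_that("a site in perfect LD with itself has pAB = MAF", {
  # 10 diploids, alt-allele frequency 0.3
  d <- c(2, 2, 1, 1, 0, 0, 0, 0, 0, 0)
  f <- em_haplotype_freqs(d, d)
  expect_equal(f[["pAB"]], 0.3, tolerance = 1e-7)
  expect_equal(f[["pab"]], 0.7, tolerance = 1e-7)
  expect_equal(f[["pAb"]], 0, tolerance = 1e-7)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_equal(r2_from_freqs(f), 1, tolerance = 1e-7)
})

test_that("r2 follows the closed form and its degenerate cases", {
  expect_equal(r2_from_freqs(c(pAB = 0.5, pAb = 0, paB = 0, pab = 0.5)), 1)
  expect_equal(r2_from_freqs(c(pAB = 0.4, pAb = 0.1, paB = 0.1, pab = 0.4)), 0.36)
  # independent margins: D = 0
  expect_equal(r2_from_freqs(c(pAB = 0.06, pAb = 0.24, paB = 0.14, pab = 0.56)),
               0, tolerance = 1e-12)
  expect_error(r2_from_freqs(c(pAB = 0.5, pAb = 0.5, paB = 0, pab = 0)),
               class = "regsnp_undefined_ld_error")
})

test_that("EM errors on monomorphic or insufficient input", {
  expect_error(em_haplotype_freqs(c(0, 0, 0), c(0, 1, 2)),
               class = "regsnp_undefined_ld_error")
  expect_error(em_haplotype_freqs(c(NA, 1, NA), c(0, NA, 1)),
               class = "regsnp_insufficient_data_error")
})

test_that("EM frequencies maximize the multinomial likelihood (grid oracle)", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    g <- random_geno_pair(20)
    f_em <- tryCatch(em_haplotype_freqs(g$da, g$db),
                     regsnp_undefined_ld_error = function(e) NULL)
    if (is.null(f_em)) next
    f_grid <- grid_haplotype_freqs(g$da, g$db, step = 1e-4)
    worst <- max(worst, max(abs(f_em - f_grid)))
  }
  expect_lt(worst, 2e-4)
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  set.seed(11)
  for (i in 1:20) {
    g <- random_geno_pair(40)
    r <- tryCatch(r2_from_freqs(em_haplotype_freqs(g$da, g$db)),
                  regsnp_undefined_ld_error = function(e) NULL)
    if (is.null(r)) next
    expect_equal(r2_from_freqs(em_haplotype_freqs(g$db, g$da)), r,
                 tolerance = 1e-6)
    expect_equal(r2_from_freqs(em_haplotype_freqs(2 - g$da, g$db)), r,
                 tolerance = 1e-6)
    expect_equal(r2_from_freqs(em_haplotype_freqs(g$da, 2 - g$db)), r,
                 tolerance = 1e-6)
  }
})

test_that("EM r2 tracks the generating haplotype r2 closely at n = 500", {
  targets <- seq(0.1, 0.9, by = 0.1)
  sim <- simulate_haplotype_block(n_samples = 500, n_snps = length(targets) + 1,
                                  target_r2_profile = targets, seed = 7)
  gm <- sim$genotypes
  err <- vapply(seq_along(targets), function(k) {
    em <- ld_r2(gm, 1L, k + 1L, method = "em")
    em - sim$truth$planted_ld$realized_r2[k]
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), 0.02)
})

test_that("phased r2 equals EM r2 on data generated without missingness", {
  sim <- simulate_haplotype_block(n_samples = 400, n_snps = 4,
                                  target_r2_profile = c(0.3, 0.7, 0.95),
                                  seed = 9)
  for (j in 2:4)
    expect_lt(abs(ld_r2(sim$genotypes, 1L, j, method = "em") -
                    ld_r2(sim$genotypes, 1L, j, method = "phased")), 0.02)
})

test_that("expansion returns exactly the proxies above the strict cutoff", {
  sim <- simulate_haplotype_block(n_samples = 503, n_snps = 10,
                                  target_r2_profile = c(0.2, 0.61, 0.9),
                                  seed = 5)
  pairs <- expand_index_snps("snp_index", sim$genotypes,
                             window_kb = 1000, r2_min = 0.6)
  truth <- sim$truth$planted_ld
  expected <- c("snp_index", truth$proxy_id[truth$realized_r2 > 0.6])
  expect_setequal(pairs$proxy_id, expected)
  expect_equal(pairs$r2[pairs$proxy_id == "snp_index"], 1)
  # deterministic order: by proxy position
  expect_equal(pairs$proxy_id, pairs$proxy_id[order(pairs$distance_bp)])
})

test_that("the LD window bound excludes distant perfect proxies", {
  v <- variant_table("chr1", c(1000, 1000 + 1000001), c("idx", "far"),
                     c("A", "A"), c("G", "G"))
  d <- cbind(c(0, 1, 2, 1, 0, 2, 1, 1), c(0, 1, 2, 1, 0, 2, 1, 1))
  gm <- genotype_matrix(sprintf("s%d", 1:8), v, d)
  pairs <- expand_index_snps("idx", gm, window_kb = 1000, r2_min = 0.6)
  expect_equal(pairs$proxy_id, "idx")   # r2 = 0.99+ proxy outside the 1 Mb window
})

test_that("an index with no polymorphic neighbors yields only the self pair", {
  v <- variant_table("chr1", c(1000, 2000), c("idx", "mono"),
                     c("A", "A"), c("G", "G"))
  d <- cbind(c(0, 1, 2, 1), c(0, 0, 0, 0))
  gm <- genotype_matrix(sprintf("s%d", 1:4), v, d)
  pairs <- expand_index_snps("idx", gm)
  expect_equal(pairs$proxy_id, "idx")
  expect_error(expand_index_snps("nope", gm), class = "regsnp_lookup_error")
})
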