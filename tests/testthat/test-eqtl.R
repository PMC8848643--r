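test_that("a noiseless additive effect is recovered exactly", {
  dos <- rep(c(0, 1, 2), 20)
  res <- suppressWarnings(eqtl_association(dos, 2 * dos))
  expect_equal(res$beta, 2, tolerance = 1e-9)
  expect_lt(res$pvalue, 1e-10)
  expect_equal(res$n, 60L)
  expect_error(eqtl_association(rep(1, 10), rnorm(10)),
               class = "regsnp_undefined_association_error")
})

test_that("association is invariant to affine rescaling of expression", {
  set.seed(3)
  dos <- rbinom(100, 2, 0.3)
  e <- 0.5 * dos + rnorm(100)
  a <- eqtl_association(dos, e)
  b <- eqtl_association(dos, 3 * e + 7)
  expect_equal(b$beta, 3 * a$beta, tolerance = 1e-9)
  expect_equal(b$pvalue, a$pvalue, tolerance = 1e-9)
})

test_that("missing values are removed pairwise and covariates are honored", {
  set.seed(4)
  dos <- rbinom(50, 2, 0.4); dos[3] <- NA
  cov <- rnorm(50)
  e <- 0.5 * dos + 2 * cov + rnorm(50, 0, 0.1)
  res <- eqtl_association(dos, e, covariates = cbind(cov))
  expect_equal(res$n, 49L)
  expect_equal(res$beta, 0.5, tolerance = 0.1)
})

test_that("effect-size recovery and null calibration match the model", {
  set.seed(5)
  betas <- vapply(1:200, function(i) {
    s <- simulate_eqtl_dataset(n_samples = 400, maf = 0.3, beta = 0.5,
                               noise_sd = 1, seed = 5000 + i)
    eqtl_association(s$genotypes$dosages[, 1], s$expression[1, ])$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.5) / 0.5, 0.05)
  p_null <- vapply(1:400, function(i) {
    s <- simulate_eqtl_dataset(n_samples = 200, maf = 0.3, beta = 0,
                               seed = 9000 + i)
    eqtl_association(s$genotypes$dosages[, 1], s$expression[1, ])$pvalue
  }, numeric(1))
  frac <- mean(p_null < 0.05)
  # exact binomial 99% envelope around 0.05 at 400 draws
  env <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(frac, env[1])
  expect_lte(frac, env[2])
})

test_that("cross-dataset support counts and tiers are nested", {
  res <- data.frame(
    variant_id = rep(c("v1", "v2", "v3"), each = 4),
    gene_id = "g",
    dataset = rep(c("d1", "d2", "d3", "d4"), 3),
    pvalue = c(0.01, 0.02, 0.03, 0.04,   # v1: all four
               0.01, 0.5, 0.04, 0.9,     # v2: two
               0.6, 0.7, 0.8, 0.9))      # v3: none
  s <- cross_dataset_support(res, alpha = 0.05)
  expect_equal(s$support$n_datasets_significant[s$support$variant_id == "v1"], 4L)
  expect_equal(s$support$n_datasets_significant[s$support$variant_id == "v3"], 0L)
  expect_setequal(s$tiers$ge1, c("v1", "v2"))
  expect_setequal(s$tiers$all, "v1")
  expect_true(all(s$tiers$all %in% s$tiers$ge3))
  expect_true(all(s$tiers$ge3 %in% s$tiers$ge2))
  expect_true(all(s$tiers$ge2 %in% s$tiers$ge1))
  expect_error(cross_dataset_support(data.frame(variant_id = "v", pvalue = 0.01)),
               class = "regsnp_input_error")
})

test_that("a planted support pattern is recovered exactly with orthogonal nulls", {
  blk <- simulate_eqtl_block(support_plan = c(4, 3, 2, 1, 0), n_samples = 150,
                             beta = 1, seed = 6)
  rows <- list()
  for (d in blk$datasets)
    for (vi in 1:5) for (gi in 1:5)
      rows[[length(rows) + 1]] <- eqtl_association(
        d$genotypes$dosages[, vi], d$expression[gi, ],
        variant_id = d$genotypes$variants$id[vi],
        gene_id = rownames(d$expression)[gi], dataset = d$name)
  res <- do.call(rbind, rows)
  s <- cross_dataset_support(res, alpha = 0.05)
  got <- s$support$n_datasets_significant[
    match(names(blk$truth$support_plan), s$support$variant_id)]
  expect_equal(unname(got), unname(blk$truth$support_plan))
  expect_equal(vapply(s$tiers, length, integer(1)),
               c(ge1 = 4L, ge2 = 3L, ge3 = 2L, all = 1L))
})

test_that("BH q-values follow the step-up rule and bound their p-values", {
  set.seed(7)
  sim <- simulate_case_control_expr(n_genes = 40, n_cases = 10, n_controls = 8,
                                    n_de = 3, fold = 3, seed = 7)
  de <- case_control_de(sim$expression, sim$labels)
  expect_true(all(de$qvalue >= de$pvalue - 1e-12))
  expect_equal(de$qvalue, bh_oracle(de$pvalue), tolerance = 1e-12)
  # the hand BH case: every p steps up to 0.04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("identical group means are not flagged", {
  expr <- matrix(5, nrow = 3, ncol = 10,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  labels <- rep(c("case", "control"), c(6, 4))
  de <- case_control_de(expr, labels)
  expect_true(all(de$pvalue == 1))
  expect_false(any(de$significant))
  expect_error(case_control_de(expr, rep("case", 10)),
               class = "regsnp_input_error")
  expect_error(case_control_de(expr, c(rep("case", 9), "control")),
               class = "regsnp_input_error")
})

test_that("planted two-fold genes dominate the ranking at the study design", {
  hits <- vapply(1:200, function(i) {
    sim <- simulate_case_control_expr(n_genes = 100, n_cases = 24,
                                      n_controls = 12, n_de = 4, fold = 2,
                                      seed = 100 + i)
    de <- case_control_de(sim$expression, sim$labels)
    top4 <- de$gene_id[order(de$pvalue)][1:4]
    all(sort(top4) == sort(sim$truth$de_genes))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
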