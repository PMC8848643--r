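make_allelic_fixture <- function() {
  planted <- random_pfm(width = 7, consensus_prob = 0.88, seed = 11)
  sim <- simulate_disruption_variants(planted, n_disrupting = 5, n_null = 5,
                                      seed = 2)
  list(pfm = planted, pwm = pwm_from_pfm(planted), sim = sim)
}

test_that("allelic sequences are flank + allele + flank with recorded spans", {
  store <- sequence_store(c(chr1 = paste(rep("ACGTT", 20), collapse = "")))
  v <- variant_table("chr1", 50, "snv", "T", "C")   # genome base 50 is T
  as <- allelic_sequences(v, store, flank_bp = 20)
  expect_equal(nchar(as$ref_seq), 41L)
  expect_equal(nchar(as$alt_seq), 41L)
  expect_equal(substr(as$ref_seq, 21, 21), "T")
  expect_equal(substr(as$alt_seq, 21, 21), "C")
  # the two sequences differ exactly at the variant base (0-based index 20)
  d <- which(strsplit(as$ref_seq, "")[[1]] != strsplit(as$alt_seq, "")[[1]])
  expect_equal(d, 21L)
  expect_equal(as$ref_snp_span, c(20, 21))
})

test_that("insertion alleles lengthen the alternate sequence and its span", {
  store <- sequence_store(c(chr1 = paste(rep("ACGTT", 20), collapse = "")))
  v <- variant_table("chr1", 48, "ins", "G", "GGA")
  as <- allelic_sequences(v, store, flank_bp = 20)
  expect_equal(nchar(as$ref_seq), 41L)
  expect_equal(nchar(as$alt_seq), 43L)
  expect_equal(as$alt_snp_span, c(20, 23))
  expect_equal(substr(as$alt_seq, 21, 23), "GGA")
  # substituting ref by alt at the span reproduces alt_seq
  expect_equal(paste0(substr(as$ref_seq, 1, 20), "GGA",
                      substr(as$ref_seq, 22, 41)), as$alt_seq)
})

test_that("reference mismatches and contig boundaries are errors", {
  store <- sequence_store(c(chr1 = paste(rep("A", 100), collapse = "")))
  bad <- variant_table("chr1", 50, "bad", "T", "C")
  expect_error(allelic_sequences(bad, store),
               class = "regsnp_reference_mismatch_error")
  edge <- variant_table("chr1", 5, "edge", "A", "C")
  expect_error(allelic_sequences(edge, store), class = "regsnp_boundary_error")
})

test_that("a planted consensus site is significant on the ref allele only", {
  fx <- make_allelic_fixture()
  dis <- fx$sim$truth$id[fx$sim$truth$type == "disrupting"]
  for (id in dis) {
    v <- fx$sim$variants[fx$sim$variants$id == id, ]
    sc <- scan_alleles(fx$pwm, allelic_sequences(v, fx$sim$genome))
    expect_lt(sc$ref$pvalue, 1e-3)
    expect_gte(sc$alt$pvalue, 1e-3)
    expect_gt(sc$delta_llr, 0)
  }
})

test_that("an uninformative motif matches both alleles with llr 0 and p 1", {
  store <- sequence_store(c(chr1 = paste(rep("ACGTT", 20), collapse = "")))
  v <- variant_table("chr1", 50, "snv", "T", "C")
  uni <- pwm_from_pfm(pfm(matrix(5, 4, 5), "uniform"))
  sc <- scan_alleles(uni, allelic_sequences(v, store))
  expect_equal(sc$ref$llr, 0)
  expect_equal(sc$ref$pvalue, 1)
  expect_equal(sc$alt$pvalue, 1)
})

test_that("matches that do not overlap the variant are ignored for calling", {
  # plant a perfect site entirely inside the left flank, far from the variant
  fx <- make_allelic_fixture()
  cons <- pfm_consensus(fx$pfm)
  left <- paste0("ACGTA", cons, paste(rep("A", 8), collapse = ""))  # 20 bp
  genome <- paste0(left, "T", paste(rep("CA", 10), collapse = ""))
  store <- sequence_store(c(chr1 = genome))
  v <- variant_table("chr1", 21, "v", "T", "G")
  as <- allelic_sequences(v, store, flank_bp = 20)
  sc <- scan_alleles(fx$pwm, as)
  # the planted flank site itself would pass the threshold...
  best_anywhere <- max(score_windows(fx$pwm, as$ref_seq)$score)
  expect_lt(score_pvalue(fx$pwm, best_anywhere), 1e-3)
  # ...but it does not overlap the variant, so the overlapping best is weaker
  expect_gt(sc$ref$pvalue, score_pvalue(fx$pwm, best_anywhere))
  expect_true(sc$ref$offset + fx$pwm$width > 20)   # overlap rule respected
  expect_true(sc$ref$offset < 21)
})

test_that("one_pass calling follows the exactly-one-allele rule", {
  mk <- function(p, llr) list(motif = "TF", allele = "x", offset = 0L,
                              strand = "+", llr = llr, pvalue = p,
                              overlaps_variant = TRUE)
  loss <- call_disruption(mk(1e-5, 10), mk(0.2, 2))
  expect_true(loss$disrupting)
  expect_equal(loss$direction, "loss")
  gain <- call_disruption(mk(0.2, 2), mk(1e-5, 10))
  expect_true(gain$disrupting)
  expect_equal(gain$direction, "gain")
  both <- call_disruption(mk(1e-5, 10), mk(1e-5, 10))
  expect_false(both$disrupting)
  neither <- call_disruption(mk(0.01, 3), mk(0.5, 1))
  expect_false(neither$disrupting)
})

test_that("delta mode requires one passing allele and a large LLR change", {
  mk <- function(p, llr) list(motif = "TF", allele = "x", offset = 0L,
                              strand = "+", llr = llr, pvalue = p,
                              overlaps_variant = TRUE)
  hit <- call_disruption(mk(1e-5, 10), mk(1e-4, 4), mode = "delta", delta_min = 2)
  expect_true(hit$disrupting)
  expect_equal(hit$direction, "loss")
  small <- call_disruption(mk(1e-5, 10), mk(1e-5, 9.5), mode = "delta",
                           delta_min = 2)
  expect_false(small$disrupting)
})

test_that("swapping allele labels flips direction but not the call", {
  fx <- make_allelic_fixture()
  v <- fx$sim$variants[match(fx$sim$truth$id[fx$sim$truth$type == "disrupting"][1],
                             fx$sim$variants$id), ]
  as <- allelic_sequences(v, fx$sim$genome)
  swapped <- as
  swapped$ref_seq <- as$alt_seq; swapped$alt_seq <- as$ref_seq
  swapped$ref_snp_span <- as$alt_snp_span; swapped$alt_snp_span <- as$ref_snp_span
  sc <- scan_alleles(fx$pwm, as)
  sc_sw <- scan_alleles(fx$pwm, swapped)
  call <- call_disruption(sc$ref, sc$alt, delta_llr = sc$delta_llr)
  call_sw <- call_disruption(sc_sw$ref, sc_sw$alt, delta_llr = sc_sw$delta_llr)
  expect_equal(call$disrupting, call_sw$disrupting)
  expect_equal(call$direction, "loss")
  expect_equal(call_sw$direction, "gain")
  expect_equal(call_sw$delta_llr, -call$delta_llr, tolerance = 1e-9)
})

test_that("reverse-complementing the sequences flips strands only", {
  fx <- make_allelic_fixture()
  v <- fx$sim$variants[match(fx$sim$truth$id[fx$sim$truth$type == "disrupting"][1],
                             fx$sim$variants$id), ]
  as <- allelic_sequences(v, fx$sim$genome)
  rc <- as
  rc$ref_seq <- revcomp(as$ref_seq); rc$alt_seq <- revcomp(as$alt_seq)
  n <- nchar(as$ref_seq)
  rc$ref_snp_span <- c(n - as$ref_snp_span[2], n - as$ref_snp_span[1])
  rc$alt_snp_span <- c(n - as$alt_snp_span[2], n - as$alt_snp_span[1])
  a <- scan_alleles(fx$pwm, as)
  b <- scan_alleles(fx$pwm, rc)
  expect_equal(b$ref$llr, a$ref$llr, tolerance = 1e-9)
  expect_equal(b$ref$pvalue, a$ref$pvalue, tolerance = 1e-12)
  expect_false(b$ref$strand == a$ref$strand)
})

test_that("disruption summaries count TFs, SNPs and co-disruptions", {
  calls <- data.frame(
    variant_id = c("v1", "v1", "v2", "v3", "v3"),
    tf = c("CTCF", "RAD21", "CTCF", "REST", "CTCF"),
    disrupting = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  s <- summarize_disruptions(calls)
  expect_equal(s$per_tf[["CTCF"]], 3L)
  expect_equal(s$per_tf[["RAD21"]], 1L)
  expect_equal(s$per_tf[["REST"]], 0L)
  expect_equal(s$per_snp[["v1"]], 2L)
  expect_equal(s$co_matrix["CTCF", "RAD21"], 1L)
  expect_equal(s$co_matrix["RAD21", "CTCF"], 1L)
  expect_true(isSymmetric(s$co_matrix))
  # consistency: diagonal equals per-TF counts
  expect_equal(unname(diag(s$co_matrix)), unname(s$per_tf))
  empty <- summarize_disruptions(calls[0, ])
  expect_length(empty$per_tf, 0L)
})
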