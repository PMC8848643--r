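test_that("variant table validation rejects malformed alleles", {
  expect_silent(variant_table("chr1", 10, "v1", "A", "G"))
  expect_error(variant_table("chr1", 10, "v1", "A", "A"), class = "regsnp_format_error")
  expect_error(variant_table("chr1", 10, "v1", "", "G"), class = "regsnp_format_error")
  expect_error(variant_table("chr1", 0, "v1", "A", "G"), class = "regsnp_format_error")
  expect_error(variant_table("chr1", 10, "v1", "A", "N"), class = "regsnp_format_error")
  # VCF-style indel with shared leading base is fine
  expect_silent(variant_table("chr1", 10, "ins", "G", "GGA"))
})

test_that("VCF genotypes decode to dosages and phased haplotypes", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1"), vcf)
  gm <- read_vcf(vcf)
  expect_equal(unname(gm$dosages[, 1]), c(1L, 2L))
  expect_equal(unname(gm$haplotypes[, 1]), c(0L, 1L, 1L, 1L))
  expect_equal(gm$variants$id, "rs1")
})

test_that("missing genotypes become NA dosages and are counted", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t./.\t0/1"), vcf)
  gm <- read_vcf(vcf)
  expect_true(is.na(gm$dosages[1, 1]))
  expect_equal(gm$dosages[2, 1], 1L)
  expect_equal(unname(attr(gm, "missingness")), 1L)
})

test_that("multiallelic records are split by default and skippable", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0/1"), vcf)
  gm <- read_vcf(vcf)
  expect_equal(nrow(gm$variants), 2L)
  expect_equal(unname(gm$dosages[, 1]), c(1L, 1L))  # G allele
  expect_equal(unname(gm$dosages[, 2]), c(1L, 0L))  # T allele
  expect_equal(attr(gm, "multiallelic"), 1L)
  gm2 <- read_vcf(vcf, multiallelic = "skip")
  expect_equal(nrow(gm2$variants), 0L)
})

test_that("VCF round-trip preserves dosages and phase", {
  sim <- simulate_haplotype_block(n_samples = 30, n_snps = 5, seed = 42)
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, path)
  back <- read_vcf(path)
  expect_equal(unname(back$dosages), unname(sim$genotypes$dosages))
  expect_equal(unname(back$haplotypes), unname(sim$genotypes$haplotypes))
  expect_equal(back$variants$pos, sim$genotypes$variants$pos)
})

test_that("FASTA fetch is 0-based half-open with strand support", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 description", "ACGTACGTGG"), fa)
  store <- read_fasta(fa)
  expect_equal(fetch_seq(store, "chr1", 0, 5), "ACGTA")
  expect_equal(nchar(fetch_seq(store, "chr1", 2, 9)), 7L)
  expect_equal(fetch_seq(store, "chr1", 0, 4, strand = "-"), "ACGT")
  expect_equal(fetch_seq(store, "chr1", 4, 8, strand = "-"),
               revcomp(fetch_seq(store, "chr1", 4, 8)))
  expect_error(fetch_seq(store, "chrX", 0, 5), class = "regsnp_key_error")
  expect_error(fetch_seq(store, "chr1", 5, 11), class = "regsnp_range_error")
})

test_that("reverse complement is an involution and soft-masking is uppercased", {
  expect_equal(revcomp(revcomp("ACGTTGCA")), "ACGTTGCA")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c", "acgtn"), fa)
  expect_equal(fetch_seq(read_fasta(fa), "c", 0, 5), "ACGTN")
})

test_that("BED fields map to 0-based intervals with name and score", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t141\tpeak1\t200", bed)
  gr <- read_bed(bed)
  expect_equal(GenomicRanges::start(gr) - 1L, 99L)
  expect_equal(GenomicRanges::end(gr), 141L)
  expect_equal(gr$name, "peak1")
  expect_equal(gr$score, 200)
  out <- tempfile(fileext = ".bed")
  write_bed(gr, out)
  gr2 <- read_bed(out)
  expect_equal(GenomicRanges::start(gr2), GenomicRanges::start(gr))
  expect_equal(gr2$score, gr$score)
})

test_that("MEME motif files round-trip to printed precision", {
  m1 <- random_pfm(width = 8, consensus_prob = 0.85, seed = 2)
  m2 <- random_pfm(width = 6, consensus_prob = NULL, alpha = 1, seed = 3)
  m2$tf_name <- "dirichlet_motif"
  path <- tempfile(fileext = ".meme")
  write_meme_motifs(list(m1, m2), path, background = c(0.3, 0.2, 0.2, 0.3))
  back <- read_meme_motifs(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$tf_name, m1$tf_name)
  expect_equal(attr(back, "background"), c(0.3, 0.2, 0.2, 0.3))
  expect_equal(pfm_freqs(back[[1]]), pfm_freqs(m1), tolerance = 1e-5)
  expect_equal(pfm_freqs(back[[2]]), pfm_freqs(m2), tolerance = 1e-5)
  expect_equal(back[[2]]$n_sites, m2$n_sites)
})

test_that("GTF gene models carry transcript, CDS and exon structure", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1\tsrc\ttranscript\t1001\t5000\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1\tsrc\texon\t1001\t2000\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1\tsrc\texon\t3001\t5000\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1\tsrc\tCDS\t1501\t4200\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), gtf)
  genes <- read_gtf(gtf)
  expect_named(genes, "g1")
  tx <- genes$g1$transcripts[[1]]
  expect_equal(tx$tx_start, 1000)
  expect_equal(tx$tx_end, 5000)
  expect_equal(tx$cds_start, 1500)
  expect_equal(unname(tx$exons[, 1]), c(1000, 3000))
})
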