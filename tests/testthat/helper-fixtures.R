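# End-to-end fixture: three TFs (B is the reverse complement of A, so every
# A-disrupting SNP also disrupts B on the other strand; C is independent),
# planted LD block, gene models with known categories, hand-built ASE counts,
# and an orthogonalized eQTL block with an exact planted support pattern.
build_pipeline_fixture <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)

  tf_a <- random_pfm(width = 7, consensus_prob = 0.88, seed = 101)
  tf_a$tf_name <- "TFA"
  tf_b <- pfm_revcomp(tf_a); tf_b$tf_name <- "TFB"
  tf_c <- random_pfm(width = 7, consensus_prob = 0.88, seed = 202)
  tf_c$tf_name <- "TFC"
  write_meme_motifs(list(tf_a, tf_b, tf_c), path("motifs.meme"))

  sim_a <- simulate_disruption_variants(tf_a, n_disrupting = 12, n_null = 0,
                                        seed = seed, chrom = "chrA",
                                        id_prefix = "avar")
  sim_c <- simulate_disruption_variants(tf_c, n_disrupting = 8, n_null = 0,
                                        seed = seed + 1, chrom = "chrC",
                                        id_prefix = "cvar")
  genome <- sequence_store(c(chrA = as.character(sim_a$genome$seqs[["chrA"]]),
                             chrC = as.character(sim_c$genome$seqs[["chrC"]])))
  write_fasta(genome, path("genome.fa"))
  variants <- rbind(sim_a$variants, sim_c$variants)
  gm <- genotype_matrix(c("s1", "s2"), variants,
                        matrix(1L, 2, nrow(variants)))
  write_vcf(gm, path("candidates.vcf"))

  # LD block for the expansion stage
  ld <- simulate_haplotype_block(n_samples = 200, n_snps = 6,
                                 target_r2_profile = c(0.2, 0.61, 0.9, 0.75, 0.1),
                                 seed = seed + 2)
  write_vcf(ld$genotypes, path("genotypes.vcf"))
  writeLines("snp_index", path("index_snps.txt"))

  # gene models on chrA (1-based GTF): tx 31..350, exons 31..100 and 291..350,
  # CDS 41..95. Variant centers sit at 61, 181, 301, 421, ... per 120 bp block.
  gtf <- c(
    paste("chrA\tsim\ttranscript\t31\t350\t.\t+\t.",
          'gene_id "gA"; transcript_id "tA";', sep = "\t"),
    paste("chrA\tsim\texon\t31\t100\t.\t+\t.",
          'gene_id "gA"; transcript_id "tA";', sep = "\t"),
    paste("chrA\tsim\texon\t291\t350\t.\t+\t.",
          'gene_id "gA"; transcript_id "tA";', sep = "\t"),
    paste("chrA\tsim\tCDS\t41\t95\t.\t+\t.",
          'gene_id "gA"; transcript_id "tA";', sep = "\t"))
  writeLines(gtf, path("genes.gtf"))

  # ASE counts: one clear ASE SNP, one balanced, one under depth
  write.table(data.frame(variant_id = c("avar_0001", "avar_0002", "avar_0003"),
                         ref_count = c(20L, 5L, 4L),
                         alt_count = c(2L, 5L, 2L)),
              path("ase_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # eQTL block with exact planted support
  blk <- simulate_eqtl_block(support_plan = c(4, 3, 2, 1, 0), n_datasets = 4,
                             n_samples = 120, beta = 1, seed = seed + 3)
  eqtl_cfg <- list()
  for (i in seq_along(blk$datasets)) {
    d <- blk$datasets[[i]]
    write_vcf(d$genotypes, path(sprintf("eqtl_%d.vcf", i)))
    write_expr_tsv(d$expression, path(sprintf("eqtl_%d.tsv", i)))
    eqtl_cfg[[i]] <- list(name = d$name, vcf = path(sprintf("eqtl_%d.vcf", i)),
                          expr = path(sprintf("eqtl_%d.tsv", i)))
  }

  # case/control expression
  cc <- simulate_case_control_expr(n_genes = 30, n_cases = 24, n_controls = 12,
                                   n_de = 3, fold = 2.5, seed = seed + 4)
  write_expr_tsv(cc$expression, path("cc_expr.tsv"))
  write.table(data.frame(sample = colnames(cc$expression), label = cc$labels),
              path("cc_labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(dir = dir,
       config = list(seed = seed,
                     ld = list(vcf = path("genotypes.vcf"),
                               index_snps = path("index_snps.txt")),
                     motifs = list(meme = path("motifs.meme")),
                     scan = list(vcf = path("candidates.vcf"),
                                 fasta = path("genome.fa")),
                     annotate = list(gtf = path("genes.gtf")),
                     ase = list(counts = path("ase_counts.tsv")),
                     eqtl = list(datasets = eqtl_cfg),
                     de = list(expr = path("cc_expr.tsv"),
                               labels = path("cc_labels.tsv"))),
       truth = list(ld = ld$truth, a = sim_a$truth, c = sim_c$truth,
                    eqtl = blk$truth, de = cc$truth))
}

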