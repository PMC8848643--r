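#' Validate a pipeline configuration
#'
#' Fills in the default thresholds (the values used throughout the package:
#' `window_kb = 1000`, `r2_min = 0.6`, `flank_bp = 20`, `p_threshold = 1e-3`,
#' `min_reads = 8`, `alpha = 0.05`, `alpha_q = 0.05`), checks ranges, and
#' checks that every referenced input file exists. Fails before any compute.
#'
#' @param config A named list, or the path of a YAML file holding one.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  th_defaults <- list(window_kb = 1000, r2_min = 0.6, flank_bp = 20,
                      p_threshold = 1e-3, min_reads = 8, alpha = 0.05,
                      alpha_q = 0.05)
  th <- utils::modifyList(th_defaults, config$thresholds %||% list())
  if (any(unlist(th) <= 0))
    stop_regsnp("regsnp_config_error", "all thresholds must be positive")
  if (th$r2_min > 1)
    stop_regsnp("regsnp_config_error", "r2_min must lie in (0, 1]")
  if (th$p_threshold > 1 || th$alpha > 1 || th$alpha_q > 1)
    stop_regsnp("regsnp_config_error", "probability thresholds must be <= 1")
  config$thresholds <- th
  config$seed <- config$seed %||% 1L
  files <- c(config$ld$vcf, config$ld$index_snps, config$motifs$meme,
             config$motifs$db_meme, config$motifs$peaks_bed,
             config$motifs$genome_fasta, config$scan$vcf, config$scan$fasta,
             config$annotate$gtf, config$ase$counts,
             unlist(lapply(config$eqtl$datasets, function(d) c(d$vcf, d$expr))),
             config$de$expr, config$de$labels)
  missing <- if (length(files)) files[!file.exists(files)] else character(0)
  if (length(missing))
    stop_regsnp("regsnp_config_error", "missing input file(s): ",
                paste(missing, collapse = ", "))
  config
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_expr_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an expression matrix as TSV (genes in rows)
#' @param m Genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full variant-prioritization pipeline
#'
#' Executes, in dependency order, whichever stages the config describes: LD
#' expansion of index SNPs; motif acquisition (read a MEME file, or discover
#' motifs from peak flanks, optionally matched against a MEME database);
#' allele-aware disruption scanning; genomic-context annotation; ASE testing;
#' per-dataset eQTL association with cross-dataset support; and case-control
#' differential expression. Every output table is written under
#' `config$out_dir` together with a `manifest.yaml` recording package
#' version, seed, thresholds and input checksums. The run is deterministic:
#' identical config and inputs give byte-identical outputs.
#'
#' @param config Config list or YAML path, see [validate_config()].
#' @return Invisibly, the result bundle (a named list of the stage outputs
#'   plus `manifest`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  th <- config$thresholds
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if (!is.null(config$ld)) {
    gm <- read_vcf(config$ld$vcf)
    index_ids <- readLines(config$ld$index_snps)
    index_ids <- index_ids[nzchar(index_ids)]
    res$ld_pairs <- expand_index_snps(index_ids, gm,
                                      window_kb = th$window_kb,
                                      r2_min = th$r2_min)
    write_tsv(res$ld_pairs, file.path(out_dir, "ld_pairs.tsv"))
  }

  pwms <- NULL
  if (!is.null(config$motifs)) {
    if (!is.null(config$motifs$meme)) {
      motifs <- read_meme_motifs(config$motifs$meme)
    } else {
      peaks <- read_bed(config$motifs$peaks_bed)
      genome <- read_fasta(config$motifs$genome_fasta)
      flanks <- top_peak_flanks(peaks, genome,
                                n_top = config$motifs$n_top %||% 500L,
                                flank_bp = th$flank_bp)
      motifs <- discover_motifs_zoops(flanks,
                                      n_motifs = config$motifs$n_motifs %||% 5L,
                                      min_w = config$motifs$min_w %||% 6L,
                                      max_w = config$motifs$max_w %||% 20L,
                                      seed = config$seed)
    }
    if (!is.null(config$motifs$db_meme)) {
      db <- read_meme_motifs(config$motifs$db_meme)
      matches <- lapply(motifs, match_to_database, db = db)
      res$motif_matches <- data.frame(
        query = vapply(motifs, function(m) m$tf_name, character(1)),
        best_match = vapply(matches, function(m) m$tf_name, character(1)),
        similarity = vapply(matches, function(m) m$similarity, numeric(1)),
        orientation = vapply(matches, function(m) m$orientation, character(1)),
        offset = vapply(matches, function(m) m$offset, integer(1) + 0))
      write_tsv(res$motif_matches, file.path(out_dir, "motif_matches.tsv"))
      # downstream stages use the best-matched database motif's identity
      for (i in seq_along(motifs))
        motifs[[i]]$tf_name <- matches[[i]]$tf_name
    }
    res$motifs <- motifs
    write_meme_motifs(motifs, file.path(out_dir, "motifs.meme"))
    pwms <- lapply(motifs, pwm_from_pfm)
  }

  if (!is.null(config$scan)) {
    if (is.null(pwms))
      stop_regsnp("regsnp_config_error", "scan stage requires a motifs stage")
    genome <- read_fasta(config$scan$fasta)
    cand <- read_vcf(config$scan$vcf)
    res$calls <- scan_variants(cand$variants, genome, pwms,
                               flank_bp = th$flank_bp,
                               p_threshold = th$p_threshold,
                               mode = config$scan$mode %||% "one_pass")
    write_tsv(res$calls, file.path(out_dir, "disruption_calls.tsv"))
    res$disruption_summary <- summarize_disruptions(res$calls)
    write_tsv(data.frame(tf = names(res$disruption_summary$per_tf),
                         n_snps = as.integer(res$disruption_summary$per_tf)),
              file.path(out_dir, "disruption_per_tf.tsv"))
    co <- res$disruption_summary$co_matrix
    utils::write.table(co, file.path(out_dir, "co_disruption_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(config$annotate)) {
      genes <- read_gtf(config$annotate$gtf)
      disrupted <- unique(res$calls$variant_id[res$calls$disrupting])
      vv <- cand$variants[cand$variants$id %in% disrupted, , drop = FALSE]
      res$locations <- classify_locations(vv, genes,
                                          flank_bp = config$annotate$flank_bp %||% 1000L)
      write_tsv(res$locations, file.path(out_dir, "locations.tsv"))
      res$location_summary <- location_summary(res$locations)
      write_tsv(res$location_summary, file.path(out_dir, "location_summary.tsv"))
    }
  }

  if (!is.null(config$ase)) {
    counts <- utils::read.delim(config$ase$counts)
    res$ase <- ase_test(counts, min_reads = th$min_reads)
    write_tsv(res$ase, file.path(out_dir, "ase.tsv"))
    res$ase_catalogue <- ase_catalogue(res$ase, alpha = th$alpha)
  }

  if (!is.null(config$eqtl)) {
    all_rows <- list()
    for (d in config$eqtl$datasets) {
      gm <- read_vcf(d$vcf)
      expr <- read_expr_tsv(d$expr)
      for (vi in seq_len(nrow(gm$variants))) for (gi in seq_len(nrow(expr))) {
        row <- tryCatch(
          eqtl_association(gm$dosages[, vi], expr[gi, ],
                           variant_id = gm$variants$id[vi],
                           gene_id = rownames(expr)[gi], dataset = d$name),
          regsnp_undefined_association_error = function(e) NULL)
        if (!is.null(row)) all_rows[[length(all_rows) + 1L]] <- row
      }
    }
    res$eqtl <- do.call(rbind, all_rows)
    write_tsv(res$eqtl, file.path(out_dir, "eqtl.tsv"))
    res$eqtl_support <- cross_dataset_support(res$eqtl, alpha = th$alpha)
    write_tsv(res$eqtl_support$support, file.path(out_dir, "eqtl_support.tsv"))
  }

  if (!is.null(config$de)) {
    expr <- read_expr_tsv(config$de$expr)
    labels_df <- utils::read.delim(config$de$labels)
    labels <- labels_df$label[match(colnames(expr), labels_df$sample)]
    res$de <- case_control_de(expr, labels, alpha_q = th$alpha_q)
    write_tsv(res$de, file.path(out_dir, "de.tsv"))
  }

  files <- c(config$ld$vcf, config$ld$index_snps, config$motifs$meme,
             config$motifs$db_meme, config$motifs$peaks_bed,
             config$motifs$genome_fasta, config$scan$vcf, config$scan$fasta,
             config$annotate$gtf, config$ase$counts,
             unlist(lapply(config$eqtl$datasets, function(d) c(d$vcf, d$expr))),
             config$de$expr, config$de$labels)
  files <- as.character(files)
  manifest <- list(package = "regsnp",
                   version = as.character(utils::packageVersion("regsnp")),
                   seed = config$seed, thresholds = th,
                   input_md5 = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
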