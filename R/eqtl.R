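#' cis-eQTL association of one variant with one gene
#'
#' Ordinary least squares of expression on alternate-allele dosage (plus
#' optional covariates), with the usual two-sided t test on the dosage
#' coefficient. Rows with missing dosage or expression are dropped pairwise.
#'
#' @param dosages Numeric vector of dosages in `{0,1,2}` (NA allowed).
#' @param expression Numeric vector, same length.
#' @param covariates Optional numeric matrix of covariates (one row per
#'   sample).
#' @param variant_id,gene_id,dataset Labels carried into the result.
#' @return One-row `data.frame`: `variant_id`, `gene_id`, `dataset`, `beta`,
#'   `se`, `pvalue`, `n`.
#' @export
eqtl_association <- function(dosages, expression, covariates = NULL,
                             variant_id = NA_character_,
                             gene_id = NA_character_,
                             dataset = NA_character_) {
  if (length(dosages) != length(expression))
    stop_regsnp("regsnp_input_error", "dosage and expression lengths differ")
  keep <- !is.na(dosages) & !is.na(expression)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  d <- dosages[keep]; e <- expression[keep]
  if (length(unique(d)) < 2)
    stop_regsnp("regsnp_undefined_association_error",
                "dosage is constant after filtering: ", variant_id)
  df <- data.frame(expr = e, dosage = d)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates[keep, , drop = FALSE])
    names(cv) <- paste0("cov", seq_len(ncol(cv)))
    df <- cbind(df, cv)
  }
  fit <- stats::lm(expr ~ ., data = df)
  co <- summary(fit)$coefficients["dosage", ]
  data.frame(variant_id = variant_id, gene_id = gene_id, dataset = dataset,
             beta = unname(co[1]), se = unname(co[2]),
             pvalue = unname(co[4]), n = length(d), stringsAsFactors = FALSE)
}

#' Count cross-dataset eQTL support per SNP
#'
#' For each variant, counts in how many distinct datasets it has at least one
#' gene association with `p < alpha` (uncorrected), and reports the nested
#' support tiers (at least 1, 2, 3 datasets, and all datasets).
#'
#' @param results Data frame of [eqtl_association()] rows across datasets.
#' @param alpha Nominal significance threshold (default 0.05).
#' @return List with `support` (data frame `variant_id`,
#'   `n_datasets_significant`, `genes`) and `tiers` (named list of variant id
#'   vectors: `ge1`, `ge2`, `ge3`, `all`).
#' @export
cross_dataset_support <- function(results, alpha = 0.05) {
  if (is.null(results$dataset) || any(is.na(results$dataset)))
    stop_regsnp("regsnp_input_error", "dataset labels are required")
  datasets <- unique(results$dataset)
  ids <- unique(results$variant_id)
  rows <- lapply(ids, function(v) {
    rv <- results[results$variant_id == v & results$pvalue < alpha, , drop = FALSE]
    data.frame(variant_id = v,
               n_datasets_significant = length(unique(rv$dataset)),
               genes = paste(sort(unique(rv$gene_id)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  support <- do.call(rbind, rows)
  tiers <- list(ge1 = support$variant_id[support$n_datasets_significant >= 1],
                ge2 = support$variant_id[support$n_datasets_significant >= 2],
                ge3 = support$variant_id[support$n_datasets_significant >= 3],
                all = support$variant_id[support$n_datasets_significant ==
                                           length(datasets)])
  list(support = support, tiers = tiers, n_datasets = length(datasets))
}

#' Case-control differential expression of candidate target genes
#'
#' Per-gene two-sided Welch t test on `log2(expression + 1)` between case and
#' control samples, with Benjamini-Hochberg q-values; genes with
#' `q < alpha_q` are flagged.
#'
#' @param expression Genes x samples numeric matrix (rownames = gene ids).
#' @param labels Character/factor vector per sample with two levels, the
#'   first level (or `"case"` if present) treated as cases.
#' @param alpha_q FDR threshold (default 0.05).
#' @return Data frame `gene_id`, `log_fold_change` (case minus control mean
#'   of log2(x+1)), `pvalue`, `qvalue`, `significant`, ordered as input.
#' @export
case_control_de <- function(expression, labels, alpha_q = 0.05) {
  expression <- as.matrix(expression)
  labels <- as.character(labels)
  if (length(labels) != ncol(expression))
    stop_regsnp("regsnp_input_error", "one label per sample is required")
  lv <- unique(labels)
  if (length(lv) != 2)
    stop_regsnp("regsnp_input_error", "labels must have exactly two groups")
  case_lv <- if ("case" %in% lv) "case" else lv[1]
  case <- labels == case_lv
  if (sum(case) < 2 || sum(!case) < 2)
    stop_regsnp("regsnp_input_error", "need at least 2 samples per group")
  lx <- log2(expression + 1)
  gid <- rownames(lx)
  if (is.null(gid)) gid <- as.character(seq_len(nrow(lx)))
  stats_rows <- lapply(seq_len(nrow(lx)), function(i) {
    a <- lx[i, case]; b <- lx[i, !case]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else stats::t.test(a, b)$p.value
    data.frame(gene_id = gid[i],
               log_fold_change = mean(a) - mean(b), pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats_rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- out$qvalue < alpha_q
  rownames(out) <- NULL
  out
}
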