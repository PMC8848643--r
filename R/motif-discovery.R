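#' Extract summit-flank sequences of the strongest peaks
#'
#' Ranks peaks by descending score (peak height; ties broken by lower
#' `(chrom, start)`), takes the top `n_top`, and returns the sequence
#' `summit - flank_bp .. summit + flank_bp` (the summit is the interval
#' midpoint), i.e. `2*flank_bp + 1` bases per peak. Peaks whose window runs
#' off the contig are dropped; the count is reported via `attr(x, "dropped")`
#' and a message.
#'
#' @param peaks `GRanges` with a numeric `score` column.
#' @param genome A `SequenceStore` covering the peak contigs.
#' @param n_top Number of top peaks to use (default 500).
#' @param flank_bp Flank half-width around the summit (default 20).
#' @return Named character vector of sequences.
#' @export
top_peak_flanks <- function(peaks, genome, n_top = 500L, flank_bp = 20L) {
  sc <- peaks$score
  if (length(peaks) == 0 || all(is.na(sc)))
    stop_regsnp("regsnp_input_error", "peaks carry no usable score")
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  ord <- order(-sc, chrom, start0)
  ord <- ord[seq_len(min(n_top, length(ord)))]
  seqs <- character(0)
  dropped <- 0L
  for (k in ord) {
    summit <- (start0[k] + end0[k]) %/% 2L
    s <- summit - flank_bp; e <- summit + flank_bp + 1L
    if (s < 0 || e > genome$lengths[[chrom[k]]] %||% -1) { dropped <- dropped + 1L; next }
    nm <- peaks$name[k] %||% sprintf("peak_%d", k)
    seqs[nm] <- fetch_seq(genome, chrom[k], s, e)
  }
  if (dropped > 0)
    message(sprintf("top_peak_flanks: dropped %d peak(s) truncated by contig ends", dropped))
  attr(seqs, "dropped") <- dropped
  seqs
}

# --- ZOOPS EM internals -----------------------------------------------------

# Window index matrix for one width: codes, sequence index, start offset.
zoops_windows <- function(codes_list, w) {
  parts <- lapply(seq_along(codes_list), function(i) {
    cc <- codes_list[[i]]
    L <- length(cc)
    if (L < w) return(NULL)
    offs <- seq_len(L - w + 1L)
    list(W = matrix(cc[outer(offs, 0:(w - 1L), "+")], length(offs), w),
         seq = rep(i, length(offs)), off = offs)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  W <- do.call(rbind, lapply(parts, `[[`, "W"))
  list(W = W, seq = unlist(lapply(parts, `[[`, "seq")),
       off = unlist(lapply(parts, `[[`, "off")),
       key = do.call(paste0, as.data.frame(W)))
}

# One EM pass: returns updated f, lambda, objective (ZOOPS LLR vs background).
zoops_em_step <- function(win, f, lambda, bg, avail, n_seqs, m_per_seq) {
  loglr <- numeric(nrow(win$W))
  for (j in seq_len(ncol(win$W)))
    loglr <- loglr + log(f[win$W[, j] + (j - 1L) * 4L]) - log(bg[win$W[, j]])
  lr <- exp(loglr) * avail
  seq_sum <- as.numeric(rowsum(lr, win$seq, reorder = TRUE))
  m_i <- m_per_seq
  denom_i <- (1 - lambda) + lambda / m_i * seq_sum
  obj <- sum(log(denom_i))
  # window posteriors
  z <- (lambda / m_i[win$seq]) * lr / denom_i[win$seq]
  pres_i <- (lambda / m_i * seq_sum) / denom_i
  # M step
  counts <- matrix(0, 4, ncol(win$W))
  for (j in seq_len(ncol(win$W))) {
    cs <- rowsum(z, win$W[, j], reorder = FALSE)
    counts[as.integer(rownames(cs)), j] <- counts[as.integer(rownames(cs)), j] + cs
  }
  tot <- sum(z)
  f_new <- sweep(counts + bg, 2, tot + 1, "/")   # Dirichlet smoothing, total 1
  lambda_new <- min(max(mean(pres_i), 1e-3), 1 - 1e-3)
  list(f = f_new, lambda = lambda_new, obj = obj, z = z, counts = counts,
       n_sites = tot)
}

# Seed starting matrices from the most background-enriched w-mers.
zoops_seeds <- function(win, bg, avail, n_starts, match_prob = 0.7) {
  key <- win$key
  lbg <- numeric(nrow(win$W))
  for (j in seq_len(ncol(win$W))) lbg <- lbg + log(bg[win$W[, j]])
  wt <- rowsum(avail, key)
  lp <- lbg[match(rownames(wt), key)]
  enr <- log(wt[, 1] + 1e-9) - lp
  ord <- order(-enr, rownames(wt))   # deterministic tie-break
  picks <- rownames(wt)[ord][seq_len(min(n_starts, nrow(wt)))]
  lapply(picks, function(kmer) {
    codes <- as.integer(strsplit(kmer, "")[[1]])
    f <- matrix((1 - match_prob) / 3, 4, length(codes))
    f[cbind(codes, seq_along(codes))] <- match_prob
    f
  })
}

#' Discover motifs from sequences by ZOOPS EM
#'
#' Expectation-maximization under a ZOOPS model (each sequence carries zero
#' or one motif site at a uniform offset, with per-sequence site probability
#' `lambda`). For each candidate width, EM restarts are seeded from the most
#' background-enriched w-mers, each seed is refined for two iterations, and
#' the best seed is run to convergence; the width maximizing a BIC-penalized
#' log-likelihood ratio against the 0-order background is reported. The
#' reported motif's sites are probabilistically erased (positions are
#' down-weighted by their posterior site coverage) and discovery repeats
#' `n_motifs` times. Deterministic given `seed`.
#'
#' @param seqs Character vector of at least 20 DNA sequences.
#' @param n_motifs Number of motifs to report (default 5).
#' @param min_w,max_w Candidate motif width range (defaults 6 and 20).
#' @param seed Integer seed (the algorithm is deterministic; the seed guards
#'   any tie-breaking randomness).
#' @param background Optional background base probabilities; by default the
#'   0-order composition of `seqs`.
#' @param n_starts Seeded restarts per width (default 20).
#' @param tol Relative convergence tolerance on the expected log-likelihood.
#' @param max_iter EM iteration cap per start (default 200).
#' @return List of [pfm()] objects (soft-count matrices), each carrying
#'   attributes `lambda`, `objective`, and `width`.
#' @export
discover_motifs_zoops <- function(seqs, n_motifs = 5L, min_w = 6L, max_w = 20L,
                                  seed = 1L, background = NULL, n_starts = 20L,
                                  tol = 1e-6, max_iter = 200L) {
  if (length(seqs) < 20L)
    stop_regsnp("regsnp_input_error", "need at least 20 sequences")
  codes_list <- lapply(seqs, encode_dna)
  lens <- lengths(codes_list)
  if (any(lens < min_w))
    stop_regsnp("regsnp_input_error", "sequences shorter than min_w present")
  max_w <- min(max_w, min(lens))
  if (any(vapply(codes_list, anyNA, logical(1))))
    codes_list <- lapply(codes_list, function(x) { x[is.na(x)] <- 1L; x })  # N -> A
  set.seed(derive_seed(seed, 7L))
  if (is.null(background)) {
    tabs <- table(factor(unlist(codes_list), levels = 1:4))
    background <- as.numeric(tabs / sum(tabs))
    background <- pmax(background, 1e-3); background <- background / sum(background)
  }
  n_seqs <- length(seqs)
  V <- matrix(1, n_seqs, max(lens))          # per-position availability
  widths <- min_w:max_w
  wins <- lapply(widths, function(w) zoops_windows(codes_list, w))

  motifs <- list()
  for (rep_i in seq_len(n_motifs)) {
    best <- NULL
    for (wi in seq_along(widths)) {
      w <- widths[wi]; win <- wins[[wi]]
      avail <- rep(1, nrow(win$W))
      for (j in seq_len(w))
        avail <- avail * V[cbind(win$seq, win$off + j - 1L)]
      m_per_seq <- as.numeric(table(factor(win$seq, levels = seq_len(n_seqs))))
      seeds <- zoops_seeds(win, background, avail, n_starts)
      # two refinement iterations per seed, keep the best objective
      seed_runs <- lapply(seeds, function(f0) {
        st <- list(f = f0, lambda = 0.5)
        for (it in 1:2)
          st <- zoops_em_step(win, st$f, st$lambda, background, avail,
                              n_seqs, m_per_seq)
        st
      })
      objs <- vapply(seed_runs, function(s) s$obj, numeric(1))
      st <- seed_runs[[which.max(objs)]]
      prev <- st$obj
      for (it in seq_len(max_iter)) {
        st <- zoops_em_step(win, st$f, st$lambda, background, avail,
                            n_seqs, m_per_seq)
        if (abs(st$obj - prev) < tol * (abs(prev) + 1)) break
        prev <- st$obj
      }
      penalized <- st$obj - 0.5 * (3 * w + 1) * log(n_seqs)
      if (is.null(best) || penalized > best$penalized)
        best <- c(st, list(w = w, win = win, penalized = penalized))
    }
    counts <- best$counts
    # guard against an all-zero motif (no sites assigned)
    if (best$n_sites < 1e-6) counts <- counts + background
    m <- pfm(sweep(counts, 2, colSums(counts), "/") * max(best$n_sites, 1),
             sprintf("motif_%d", rep_i), n_sites = max(best$n_sites, 1))
    attr(m, "lambda") <- best$lambda
    attr(m, "objective") <- best$penalized
    attr(m, "width") <- best$w
    motifs[[rep_i]] <- m
    # probabilistic erasure of the found sites
    z <- best$z
    for (j in seq_len(best$w)) {
      idx <- cbind(best$win$seq, best$win$off + j - 1L)
      V[idx] <- V[idx] * (1 - z)
    }
  }
  motifs
}

#' Match a query motif against a PWM database
#'
#' Similarity is the maximum, over relative offsets with at least
#' `min_overlap` aligned columns and both orientations, of the mean
#' per-column Pearson correlation between the frequency columns of query and
#' database motif. Ties are broken by smaller absolute offset, forward
#' orientation, then database order.
#'
#' @param query A `PFM`.
#' @param db Non-empty list of `PFM` objects.
#' @param min_overlap Minimum aligned columns (default 4).
#' @return A list with `tf_name`, `index` (position in `db`), `similarity`,
#'   `orientation` (`"+"`/`"-"`), `offset` (db start minus query start), and
#'   `motif` (the matched `PFM`).
#' @export
match_to_database <- function(query, db, min_overlap = 4L) {
  if (length(db) == 0)
    stop_regsnp("regsnp_input_error", "motif database is empty")
  qf <- pfm_freqs(query)
  col_cor <- function(a, b) {
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 && sb == 0) return(1)
    if (sa == 0 || sb == 0) return(0)
    stats::cor(a, b)
  }
  best <- NULL
  for (d in seq_along(db)) {
    for (orient in c("+", "-")) {
      m <- if (orient == "+") db[[d]] else pfm_revcomp(db[[d]])
      mf <- pfm_freqs(m)
      w1 <- ncol(qf); w2 <- ncol(mf)
      for (offset in (-(w2 - min_overlap)):(w1 - min_overlap)) {
        qcols <- max(1, 1 + offset):min(w1, w2 + offset)
        if (length(qcols) < min_overlap) next
        dcols <- qcols - offset
        sim <- mean(vapply(seq_along(qcols),
                           function(k) col_cor(qf[, qcols[k]], mf[, dcols[k]]),
                           numeric(1)))
        cand <- list(tf_name = db[[d]]$tf_name, index = d, similarity = sim,
                     orientation = orient, offset = offset, motif = db[[d]])
        if (is.null(best) || sim > best$similarity + 1e-12 ||
            (abs(sim - best$similarity) <= 1e-12 &&
             abs(offset) < abs(best$offset)))
          best <- cand
      }
    }
  }
  best
}
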