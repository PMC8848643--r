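#' Construct a position frequency matrix (PFM)
#'
#' @param counts Numeric `4 x w` matrix of per-position base counts, rows in
#'   A, C, G, T order. Column sums must be equal across positions.
#' @param tf_name Motif / transcription factor name.
#' @param n_sites Number of sites the counts were derived from; defaults to
#'   the common column sum.
#' @return An object of class `PFM`.
#' @export
pfm <- function(counts, tf_name = "motif", n_sites = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop_regsnp("regsnp_format_error", "PFM counts must have 4 rows (A,C,G,T)")
  if (any(counts < 0))
    stop_regsnp("regsnp_format_error", "PFM counts must be non-negative")
  cs <- colSums(counts)
  if (diff(range(cs)) > 1e-6 * max(cs, 1))
    stop_regsnp("regsnp_format_error", "PFM column sums must be equal")
  rownames(counts) <- DNA_BASES
  structure(list(tf_name = tf_name, counts = counts,
                 n_sites = n_sites %||% cs[1]),
            class = "PFM")
}

#' @export
print.PFM <- function(x, ...) {
  cat(sprintf("PFM '%s': width %d, %.6g sites, consensus %s\n", x$tf_name,
              ncol(x$counts), x$n_sites, pfm_consensus(x)))
  invisible(x)
}

#' Column frequencies of a PFM
#' @param x A `PFM`.
#' @return `4 x w` matrix of per-position base probabilities.
#' @export
pfm_freqs <- function(x) sweep(x$counts, 2, colSums(x$counts), "/")

#' Consensus string of a PFM
#' @param x A `PFM`.
#' @return Character string of the modal base per position.
#' @export
pfm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Reverse complement of a PFM or PWM matrix
#' @param x A `PFM`.
#' @return A `PFM` for the opposite strand.
#' @export
pfm_revcomp <- function(x) {
  pfm(x$counts[4:1, ncol(x$counts):1, drop = FALSE], x$tf_name, x$n_sites)
}

#' Information content of a PFM
#'
#' @param x A `PFM`.
#' @param background Background base probabilities (default uniform).
#' @return Per-column information content in bits.
#' @export
pfm_information <- function(x, background = rep(0.25, 4)) {
  f <- pfm_freqs(x)
  colSums(ifelse(f > 0, f * log2(f / background), 0))
}

#' Read motifs from minimal MEME text format
#'
#' Parses the minimal MEME motif exchange format (`MEME version`, optional
#' background line, `MOTIF` blocks with `letter-probability matrix` headers).
#' Probabilities are rescaled to counts using the recorded `nsites`.
#'
#' @param path Path to a MEME-format motif file.
#' @return List of [pfm()] objects; the file-level background (if present) is
#'   attached as `attr(x, "background")`.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), 2)])
    names(vals) <- toks[seq(1, length(toks), 2)]
    background <- unname(vals[DNA_BASES])
  }
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j]))
        j <- j + 1L
      if (j > length(lines))
        stop_regsnp("regsnp_format_error",
                    "MOTIF without letter-probability matrix at line ", i)
      hdr <- lines[j]
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
      nsites <- if (grepl("nsites=", hdr))
        as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr)) else 20
      rows <- lines[(j + 1):(j + w)]
      probs <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                        numeric(4), USE.NAMES = FALSE))
      cnts <- t(probs)
      # columns are printed at finite precision; renormalize before scaling
      cnts <- sweep(cnts, 2, colSums(cnts), "/") * nsites
      motifs[[length(motifs) + 1L]] <- pfm(cnts, name, nsites)
      i <- j + w + 1L
    } else i <- i + 1L
  }
  attr(motifs, "background") <- background
  motifs
}

#' Write motifs in minimal MEME text format
#'
#' @param motifs List of `PFM` objects.
#' @param path Output path.
#' @param background Background probabilities written to the header.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, background), collapse = " "),
               ""), con)
  for (m in motifs) {
    f <- pfm_freqs(m)
    writeLines(sprintf("MOTIF %s", m$tf_name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %.6g E= 0",
                       ncol(f), m$n_sites), con)
    for (j in seq_len(ncol(f)))
      writeLines(paste(sprintf("%.6f", f[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
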