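#' Read a FASTA file into an indexed sequence store
#'
#' Sequences are loaded with \pkg{Biostrings}, uppercased (soft-masked bases
#' are treated as their uppercase equivalents), and keyed by the first word of
#' each FASTA header. Random access uses 0-based half-open coordinates via
#' [fetch_seq()].
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return An object of class `SequenceStore`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  sequence_store(ss)
}

#' Build a sequence store from in-memory sequences
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @return An object of class `SequenceStore`.
#' @export
sequence_store <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  else
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_regsnp("regsnp_format_error", "sequences must be named by contig")
  structure(list(seqs = seqs, lengths = stats::setNames(Biostrings::width(seqs),
                                                        names(seqs))),
            class = "SequenceStore")
}

#' Fetch a subsequence from a sequence store
#'
#' @param store A `SequenceStore`.
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval on the + strand.
#' @param strand `"+"` (default) or `"-"`; `"-"` returns the reverse
#'   complement of the + strand slice.
#' @return A character string of length `end - start`.
#' @export
fetch_seq <- function(store, chrom, start, end, strand = "+") {
  if (!chrom %in% names(store$seqs))
    stop_regsnp("regsnp_key_error", "unknown contig: ", chrom)
  L <- store$lengths[[chrom]]
  if (start < 0 || end > L || start >= end)
    stop_regsnp("regsnp_range_error",
                sprintf("interval [%d,%d) outside contig %s (length %d)",
                        start, end, chrom, L))
  s <- as.character(Biostrings::subseq(store$seqs[[chrom]], start + 1L, end))
  if (strand == "-") revcomp(s) else s
}

#' @export
print.SequenceStore <- function(x, ...) {
  cat(sprintf("SequenceStore: %d contigs, %d bp total\n",
              length(x$seqs), sum(x$lengths)))
  invisible(x)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector or `SequenceStore`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "SequenceStore")) seqs <- seqs$seqs
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
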