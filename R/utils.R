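#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Map a DNA string to integer codes 1..4 (A,C,G,T); anything else (N, gaps) -> NA
encode_dna <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(x, DNA_BASES)
}

decode_dna <- function(codes) {
  paste(DNA_BASES[codes], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors as the working currency of the scanning code.
#'
#' @param seq Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_regsnp <- function(class, ...) {
  stop(structure(
    class = c(class, "regsnp_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Deterministic sub-seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103 + as.double(k) * 12347) %% 2147483629)
}
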