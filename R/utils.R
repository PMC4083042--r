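#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# uppercase + RNA->DNA normalization applied to every sequence at parse time
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

is_dna <- function(x) {
  !grepl("[^ACGT]", x)
}

# derive a module-specific RNG seed from the master seed, kept < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
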