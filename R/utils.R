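#' Normalize a nucleotide sequence
#'
#' Uppercases and converts RNA U to DNA T so that every downstream exact-match
#' and complementarity operation works on a single alphabet.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences.
#' @export
normalize_sequence <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of sequences over the IUPAC DNA alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse (not complement) of each string
str_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# empty alignment table shared by the aligners
empty_alignments <- function() {
  data.frame(sequence = character(0), abundance = integer(0),
             transcript = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

# deterministic ordering of an alignment table
sort_alignments <- function(aln) {
  aln[order(aln$transcript, aln$start, aln$end, aln$sequence), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer sequence that is empty when from > to (unlike `:`)
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)
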