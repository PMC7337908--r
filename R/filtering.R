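#' Low-complexity test on a single sequence
#'
#' A sequence is low complexity when more than 75% of its positions are one
#' nucleotide, or more than 37.5% of its overlapping dinucleotide windows are
#' one specific dinucleotide, or more than 25% of its overlapping
#' trinucleotide windows are one specific trinucleotide. Denominators are the
#' window counts L, L-1 and L-2 respectively.
#'
#' @param sequence a single normalized sequence, length >= 3.
#' @return logical.
#' @export
is_low_complexity <- function(sequence) {
  L <- nchar(sequence)
  if (L < 3L) stop("low-complexity filter undefined for sequences shorter than 3nt")
  mono <- max(table(strsplit(sequence, "", fixed = TRUE)[[1]]))
  if (mono / L > 0.75) return(TRUE)
  di <- substring(sequence, 1:(L - 1L), 2:L)
  if (max(table(di)) / (L - 1L) > 0.375) return(TRUE)
  tri <- substring(sequence, 1:(L - 2L), 3:L)
  max(table(tri)) / (L - 2L) > 0.25
}

#' Filter a collapsed read library
#'
#' Applies, in order: ambiguity (any character outside A/C/G/T), length
#' bounds, minimum abundance, low complexity (optional), and genome presence
#' (optional; exact match on either strand). Defaults follow the pipeline's
#' standard configuration: sRNAs of 19-24nt, abundance >= 1.
#'
#' @param reads data.frame with `sequence` and `abundance`.
#' @param config a [nat_config()] list (only the filter fields are used).
#' @param genome a `DNAStringSet` (or path to a genome FASTA) used for the
#'   genome-presence filter; `NULL` disables that filter.
#' @return list with `reads` (survivors) and `report` (per-filter data.frame
#'   of discarded distinct sequences and discarded abundance).
#' @export
filter_reads <- function(reads, config = nat_config(), genome = NULL) {
  report <- list()
  note <- function(name, before, after) {
    report[[length(report) + 1L]] <<- data.frame(
      filter = name,
      discarded_sequences = nrow(before) - nrow(after),
      discarded_abundance = sum(before$abundance) - sum(after$abundance),
      retained_sequences = nrow(after),
      stringsAsFactors = FALSE)
  }

  r0 <- reads
  keep <- !grepl("[^ACGT]", r0$sequence)
  r1 <- r0[keep, , drop = FALSE]
  note("ambiguity", r0, r1)

  len <- nchar(r1$sequence)
  r2 <- r1[len >= config$min_srna_length & len <= config$max_srna_length, , drop = FALSE]
  note("length", r1, r2)

  r3 <- r2[r2$abundance >= config$min_srna_abundance, , drop = FALSE]
  note("abundance", r2, r3)

  if (isTRUE(config$low_complexity_filter) && nrow(r3)) {
    lc <- vapply(r3$sequence, is_low_complexity, logical(1))
    r4 <- r3[!lc, , drop = FALSE]
  } else r4 <- r3
  note("low_complexity", r3, r4)

  if (!is.null(genome) && isTRUE(config$genome_alignment) && nrow(r4)) {
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    present <- genome_presence(r4$sequence, genome)
    r5 <- r4[present, , drop = FALSE]
  } else r5 <- r4
  note("genome_presence", r4, r5)

  if (nrow(r5) == 0L) warning("no reads survive filtering")
  rownames(r5) <- NULL
  list(reads = r5, report = do.call(rbind, report))
}

# exact presence of each sequence in the genome, either strand
genome_presence <- function(sequences, genome) {
  vapply(sequences, function(s) {
    q <- Biostrings::DNAString(s)
    sum(Biostrings::vcountPattern(q, genome)) > 0L ||
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(q), genome)) > 0L
  }, logical(1), USE.NAMES = FALSE)
}

#' Filter degradome tags
#'
#' Degradome reads pass the ambiguity filter and their own length bounds
#' (default 19-21nt); they are exempt from abundance and low-complexity
#' filtering.
#'
#' @inheritParams filter_reads
#' @return list with `reads` and `report` as for [filter_reads()].
#' @export
filter_degradome <- function(reads, config = nat_config()) {
  report <- list()
  keep <- !grepl("[^ACGT]", reads$sequence)
  r1 <- reads[keep, , drop = FALSE]
  len <- nchar(r1$sequence)
  r2 <- r1[len >= config$min_tag_length & len <= config$max_tag_length, , drop = FALSE]
  rownames(r2) <- NULL
  list(reads = r2,
       report = data.frame(
         filter = c("ambiguity", "length"),
         discarded_sequences = c(nrow(reads) - nrow(r1), nrow(r1) - nrow(r2)),
         discarded_abundance = c(sum(reads$abundance) - sum(r1$abundance),
                                 sum(r1$abundance) - sum(r2$abundance)),
         retained_sequences = c(nrow(r1), nrow(r2)),
         stringsAsFactors = FALSE))
}

#' Remove reads matching a blacklist (e.g. known miRNAs, tRNA, rRNA)
#'
#' A read is removed when its full length matches any same-length window of
#' any blacklist sequence with at most `max_mismatches` substitutions
#' (no indels), on the given strand.
#'
#' @param reads data.frame with `sequence` and `abundance`.
#' @param blacklist_sequences character vector of normalized sequences.
#' @param max_mismatches maximum substitutions tolerated (default 2).
#' @return the retained reads data.frame.
#' @export
blacklist_filter <- function(reads, blacklist_sequences, max_mismatches = 2) {
  if (length(blacklist_sequences) == 0L || nrow(reads) == 0L) return(reads)
  subject <- Biostrings::DNAStringSet(blacklist_sequences)
  hit <- vapply(reads$sequence, function(s) {
    sum(Biostrings::vcountPattern(Biostrings::DNAString(s), subject,
                                  max.mismatch = max_mismatches,
                                  with.indels = FALSE)) > 0L
  }, logical(1), USE.NAMES = FALSE)
  out <- reads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep sequences conserved across biological replicates
#'
#' @param libraries list of read data.frames (each with `sequence`,
#'   `abundance`).
#' @param min_replicates minimum number of libraries a sequence must appear in.
#' @return character vector of retained sequences.
#' @export
conserve_across_replicates <- function(libraries, min_replicates) {
  if (length(libraries) == 0L) stop("at least one library required")
  if (min_replicates > length(libraries))
    stop("min_replicates exceeds the number of libraries")
  seqs <- unlist(lapply(libraries, function(l) unique(l$sequence)))
  tab <- table(seqs)
  sort(names(tab)[tab >= min_replicates])
}
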