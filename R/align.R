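#' Build an exact-match index over a transcript set
#'
#' Supports all-occurrence exact lookup of short queries on the sense strand.
#' Occurrences never span an ambiguous base (N) in the subject.
#'
#' @param transcripts a `nat_transcripts` object or a named character vector
#'   of transcript sequences.
#' @return an object of class `exact_index`.
#' @export
build_exact_index <- function(transcripts) {
  seqs <- if (inherits(transcripts, "nat_transcripts")) transcripts$seq else transcripts
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("transcripts must have unique names")
  subject <- Biostrings::DNAStringSet(seqs)
  structure(list(subject = subject, ids = names(seqs),
                 lens = setNames(nchar(seqs), names(seqs))),
            class = "exact_index")
}

#' Find all exact occurrences of queries in an indexed transcript set
#'
#' @param index an `exact_index` from [build_exact_index()].
#' @param queries character vector of query sequences (A/C/G/T).
#' @return data.frame with columns `sequence`, `transcript`, `start`, `end`
#'   (0-based half-open), one row per occurrence, deterministically ordered.
#' @export
find_exact <- function(index, queries) {
  queries <- unique(queries)
  if (length(queries) == 0L)
    return(data.frame(sequence = character(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  rows <- vector("list", length(queries))
  for (k in seq_along(queries)) {
    q <- queries[k]
    hits <- Biostrings::vmatchPattern(Biostrings::DNAString(q), index$subject)
    cnt <- S4Vectors::elementNROWS(hits)
    which_t <- which(cnt > 0L)
    if (length(which_t) == 0L) next
    starts <- unlist(lapply(which_t, function(t) BiocGenerics::start(hits[[t]])))
    rows[[k]] <- data.frame(
      sequence = q,
      transcript = rep(index$ids[which_t], cnt[which_t]),
      start = as.integer(starts) - 1L,
      end = as.integer(starts) - 1L + nchar(q),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(sequence = character(0),
                                      transcript = character(0),
                                      start = integer(0), end = integer(0),
                                      stringsAsFactors = FALSE)
  out <- out[order(out$transcript, out$start, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align collapsed reads to transcripts (sense strand, no mismatches)
#'
#' @param index an `exact_index`.
#' @param reads data.frame with `sequence` and `abundance`.
#' @return alignment data.frame with `sequence`, `abundance`, `transcript`,
#'   `start`, `end` (0-based half-open).
#' @export
align_reads <- function(index, reads) {
  hits <- find_exact(index, reads$sequence)
  if (nrow(hits) == 0L) return(empty_alignments())
  ab <- setNames(reads$abundance, reads$sequence)
  hits$abundance <- as.integer(ab[hits$sequence])
  out <- hits[, c("sequence", "abundance", "transcript", "start", "end")]
  rownames(out) <- NULL
  out
}

#' Default scoring for the local complementarity aligner
#'
#' Emulates megablast defaults for highly similar sequences: match +2,
#' mismatch -3, gap opening 5 and gap extension 2 (a gap run of length L
#' costs 5 + 2L). The acceptance score threshold is
#' `min_overlap * match * 0.5`.
#'
#' @param match,mismatch per-column substitution scores.
#' @param gap_open,gap_ext positive gap penalties.
#' @return list of scoring parameters.
#' @export
complement_scoring <- function(match = 2L, mismatch = -3L,
                               gap_open = 5L, gap_ext = 2L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext))
}

#' Best local complementarity alignment between two transcripts
#'
#' Aligns `seqA` against the reverse complement of `seqB` with affine-gap
#' Smith-Waterman and maps the result back to each transcript's native
#' orientation. This locates the candidate overlap (annealing) region of a
#' putative NAT pair. To make the result symmetric under operand swap the
#' two sequences are ordered canonically before alignment.
#'
#' @param seqA,seqB transcript sequences (character scalars, normalized).
#' @param scoring a [complement_scoring()] list.
#' @param min_score minimum Smith-Waterman score to report an alignment;
#'   `NULL` reports any positive-scoring alignment.
#' @return `NULL`, or a list of class `overlap_alignment` with elements
#'   `intervalA`, `intervalB` (0-based half-open on each input), `columns`
#'   (alignment columns incl. gaps), `score`, `matches`, `gap_columns`,
#'   `identity`, `perfectly_complementary`, and `map_b_to_a` /
#'   `map_a_to_b` (integer position maps through paired columns, NA at gaps).
#' @export
local_complement_align <- function(seqA, seqB, scoring = complement_scoring(),
                                   min_score = NULL) {
  swapped <- seqB < seqA  # canonical operand order => swap-symmetric output
  a <- if (swapped) seqB else seqA
  b <- if (swapped) seqA else seqB
  res <- .sw_align_c(a, revcomp(b), scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_ext)
  if (res$score <= 0) return(NULL)
  if (!is.null(min_score) && res$score < min_score) return(NULL)
  ai <- res$ai; rbi <- res$bi
  ai[ai < 0L] <- NA_integer_
  rbi[rbi < 0L] <- NA_integer_
  lenB <- nchar(b)
  bi <- lenB - 1L - rbi
  cols <- length(ai)
  a_chars <- strsplit(a, "", fixed = TRUE)[[1]]
  rb_chars <- strsplit(revcomp(b), "", fixed = TRUE)[[1]]
  aligned <- !is.na(ai) & !is.na(bi)
  matched <- aligned & a_chars[ifelse(is.na(ai), 1L, ai + 1L)] ==
    rb_chars[ifelse(is.na(rbi), 1L, rbi + 1L)] &
    a_chars[ifelse(is.na(ai), 1L, ai + 1L)] != "N"
  matched[!aligned] <- FALSE
  gap_cols <- sum(is.na(ai)) + sum(is.na(bi))

  intervalA <- c(min(ai, na.rm = TRUE), max(ai, na.rm = TRUE) + 1L)
  intervalB <- c(min(bi, na.rm = TRUE), max(bi, na.rm = TRUE) + 1L)

  map_b_to_a <- rep(NA_integer_, nchar(b))
  map_b_to_a[bi[aligned] + 1L] <- ai[aligned]
  map_a_to_b <- rep(NA_integer_, nchar(a))
  map_a_to_b[ai[aligned] + 1L] <- bi[aligned]

  out <- list(
    intervalA = intervalA, intervalB = intervalB,
    columns = cols, score = res$score,
    matches = sum(matched), gap_columns = gap_cols,
    identity = sum(matched) / cols,
    perfectly_complementary = (sum(matched) == cols) && gap_cols == 0L,
    map_b_to_a = map_b_to_a, map_a_to_b = map_a_to_b)
  if (swapped) {
    out <- list(intervalA = out$intervalB, intervalB = out$intervalA,
                columns = out$columns, score = out$score,
                matches = out$matches, gap_columns = out$gap_columns,
                identity = out$identity,
                perfectly_complementary = out$perfectly_complementary,
                map_b_to_a = out$map_a_to_b, map_a_to_b = out$map_b_to_a)
  }
  class(out) <- "overlap_alignment"
  out
}

#' Verify the annealing potential of a candidate overlap as an RNA duplex
#'
#' Computes an optimal intermolecular duplex between two regions by dynamic
#' programming over Watson-Crick (+2) and G:U wobble (+1) pairs with an
#' affine penalty for unpaired stretches (opening -3, each unpaired column
#' -1); intramolecular structure is not modelled. The duplex is the
#' secondary-structure sanity check applied to trans-NAT candidates: the
#' annealed region must agree geometrically with the complementarity
#' alignment, and interior unpaired runs (bubbles) are reported for the
#' bubble-size criterion.
#'
#' @param regionA,regionB character scalars: the transcript subsequences
#'   spanning the candidate overlap (each in its native 5'->3' orientation).
#' @param wc,gu,open_pen,ext_pen scoring parameters (positive penalties).
#' @return `NULL` when no duplex can form, otherwise a list of class
#'   `duplex_result` with `intervalA`, `intervalB` (annealed spans, 0-based
#'   half-open in region coordinates), `mask` (logical per alignment column,
#'   TRUE = paired), and `interior_runs` (data.frame `length`, `position` of
#'   maximal unpaired runs strictly inside the annealed region).
#' @export
hybridize <- function(regionA, regionB, wc = 2L, gu = 1L,
                      open_pen = 3L, ext_pen = 1L) {
  if (!nzchar(regionA) || !nzchar(regionB))
    stop("hybridize requires two non-empty regions")
  rb <- str_rev(regionB)
  res <- .duplex_align_c(regionA, rb, wc, gu, open_pen, ext_pen)
  if (res$score <= 0 || length(res$ai) == 0L) return(NULL)
  ai <- res$ai; rbi <- res$bi; paired <- res$paired
  lenB <- nchar(regionB)
  bi <- ifelse(rbi < 0L, NA_integer_, lenB - 1L - rbi)
  ai[ai < 0L] <- NA_integer_
  intervalA <- c(min(ai, na.rm = TRUE), max(ai, na.rm = TRUE) + 1L)
  intervalB <- c(min(bi, na.rm = TRUE), max(bi, na.rm = TRUE) + 1L)
  runs <- rle(paired)
  pos <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
  interior <- which(!runs$values)
  # first and last columns are paired by construction, so all unpaired runs
  # are interior
  interior_runs <- data.frame(length = runs$lengths[interior],
                              position = pos[interior] - 1L)
  structure(list(intervalA = intervalA, intervalB = intervalB,
                 mask = paired, score = res$score,
                 interior_runs = interior_runs),
            class = "duplex_result")
}
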