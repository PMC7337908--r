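#' Validate a candidate pair into a NAT pair
#'
#' Runs the local complementarity alignment between the two transcripts and
#' applies the acceptance criteria: the alignment must reach the minimum
#' overlap length; the pair is classed cis when the overlap is perfectly
#' complementary or when annotation shows the transcripts originate from
#' overlapping opposite-strand loci of one chromosome; otherwise it is trans.
#' Trans pairs are rejected outright under `cis_only`. Trans pairs with both
#' transcripts at most 5000nt are verified as an intermolecular duplex: the
#' annealed region must cover at least `coverage_ratio` of the aligned
#' interval on each transcript, and every unpaired interior run must be at
#' most `largest_bubble` of the total alignment length. When either
#' transcript exceeds 5000nt the duplex step is skipped and the alignment is
#' accepted as reported.
#'
#' @param candidate list or one-row data.frame with `source` and `hit`
#'   transcript ids.
#' @param transcripts a `nat_transcripts` object.
#' @param config a [nat_config()] list.
#' @return a list of class `nat_pair`, or a `nat_rejection` with a `reason`.
#' @export
classify_pair <- function(candidate, transcripts, config = nat_config()) {
  idA <- min(candidate$source, candidate$hit)
  idB <- max(candidate$source, candidate$hit)
  seqs <- transcripts$seq
  if (!idA %in% names(seqs) || !idB %in% names(seqs))
    stop("candidate refers to unknown transcript id")
  seqA <- seqs[[idA]]; seqB <- seqs[[idB]]
  scoring <- config$scoring
  aln <- local_complement_align(seqA, seqB, scoring,
                                min_score = config$min_overlap_length *
                                  scoring$match * 0.5)
  if (is.null(aln)) return(reject("no_alignment"))
  if (aln$columns < config$min_overlap_length)
    return(reject("overlap_too_short"))

  infoA <- transcripts$info[transcripts$info$id == idA, , drop = FALSE]
  infoB <- transcripts$info[transcripts$info$id == idB, , drop = FALSE]
  genomic_cis <- FALSE
  has_genomic <- nrow(infoA) == 1L && nrow(infoB) == 1L &&
    !is.na(infoA$chromosome) && !is.na(infoB$chromosome)
  if (has_genomic) {
    genomic_cis <- infoA$chromosome == infoB$chromosome &&
      infoA$strand != infoB$strand &&
      infoA$gstart < infoB$gend && infoB$gstart < infoA$gend
  }
  nat_class <- if (aln$perfectly_complementary || genomic_cis) "cis" else "trans"

  hybridization_checked <- FALSE
  if (nat_class == "trans") {
    if (isTRUE(config$cis_only)) return(reject("trans_with_cis_only"))
    lenA <- nchar(seqA); lenB <- nchar(seqB)
    if (lenA <= 5000L && lenB <= 5000L) {
      hybridization_checked <- TRUE
      flank <- config$hybridize_flank
      ra <- c(max(0L, aln$intervalA[1] - flank),
              min(lenA, aln$intervalA[2] + flank))
      rb <- c(max(0L, aln$intervalB[1] - flank),
              min(lenB, aln$intervalB[2] + flank))
      duplex <- hybridize(substr(seqA, ra[1] + 1L, ra[2]),
                          substr(seqB, rb[1] + 1L, rb[2]))
      if (is.null(duplex)) return(reject("no_duplex"))
      annealedA <- duplex$intervalA + ra[1]
      annealedB <- duplex$intervalB + rb[1]
      covA <- interval_overlap(annealedA, aln$intervalA) /
        (aln$intervalA[2] - aln$intervalA[1])
      covB <- interval_overlap(annealedB, aln$intervalB) /
        (aln$intervalB[2] - aln$intervalB[1])
      if (covA < config$coverage_ratio || covB < config$coverage_ratio)
        return(reject("annealing_coverage"))
      if (nrow(duplex$interior_runs) &&
          any(duplex$interior_runs$length >
                config$largest_bubble * aln$columns))
        return(reject("bubble_too_large"))
    }
  }

  pair <- list(transcriptA = idA, transcriptB = idB,
               intervalA = aln$intervalA, intervalB = aln$intervalB,
               overlap_len = aln$columns,
               nat_class = nat_class,
               perfectly_complementary = aln$perfectly_complementary,
               hybridization_checked = hybridization_checked,
               alignment = aln)
  pair$orientation <- orientation(pair, transcripts)
  pair$coverage_category <- coverage_category(aln$columns,
                                              nchar(seqA), nchar(seqB))
  class(pair) <- "nat_pair"
  pair
}

reject <- function(reason) structure(list(reason = reason),
                                     class = "nat_rejection")

interval_overlap <- function(x, y) {
  max(0L, min(x[2], y[2]) - max(x[1], y[1]))
}

#' Orientation of a NAT pair
#'
#' With genomic origin available for a plus-strand transcript P and a
#' minus-strand transcript M on one chromosome: containment of one span in
#' the other is a full overlap; otherwise P starting upstream of M means the
#' 3' ends meet (tail-to-tail) and the reverse means the 5' ends meet
#' (head-to-head). Without genomic information the orientation is inferred
#' from the aligned intervals: an interval spanning at least 95% of its
#' transcript means full overlap; an overlap touching both transcripts' 3'
#' termini is tail-to-tail, both 5' termini head-to-head; anything else is
#' unknown.
#'
#' @param pair a `nat_pair` (or list with `transcriptA`, `transcriptB`,
#'   `intervalA`, `intervalB`).
#' @param transcripts a `nat_transcripts` object.
#' @return one of `"head_to_head"`, `"tail_to_tail"`, `"full_overlap"`,
#'   `"unknown"`.
#' @export
orientation <- function(pair, transcripts) {
  info <- transcripts$info
  ia <- info[info$id == pair$transcriptA, , drop = FALSE]
  ib <- info[info$id == pair$transcriptB, , drop = FALSE]
  if (nrow(ia) == 1L && nrow(ib) == 1L &&
      !is.na(ia$chromosome) && !is.na(ib$chromosome) &&
      ia$chromosome == ib$chromosome && ia$strand != ib$strand) {
    p <- if (ia$strand == "+") ia else ib
    m <- if (ia$strand == "+") ib else ia
    if ((p$gstart <= m$gstart && m$gend <= p$gend) ||
        (m$gstart <= p$gstart && p$gend <= m$gend)) return("full_overlap")
    if (p$gstart < m$gstart) return("tail_to_tail")
    return("head_to_head")
  }
  lenA <- nchar(transcripts$seq[[pair$transcriptA]])
  lenB <- nchar(transcripts$seq[[pair$transcriptB]])
  fracA <- (pair$intervalA[2] - pair$intervalA[1]) / lenA
  fracB <- (pair$intervalB[2] - pair$intervalB[1]) / lenB
  if (fracA >= 0.95 || fracB >= 0.95) return("full_overlap")
  threeA <- pair$intervalA[2] == lenA; fiveA <- pair$intervalA[1] == 0L
  threeB <- pair$intervalB[2] == lenB; fiveB <- pair$intervalB[1] == 0L
  if (threeA && threeB) return("tail_to_tail")
  if (fiveA && fiveB) return("head_to_head")
  "unknown"
}

#' Coverage category of a NAT overlap
#'
#' High-coverage (HC) when the complementary region is longer than 50% of the
#' length of either transcript; otherwise `nt100` when it is 100nt or longer;
#' otherwise low-coverage (LC). HC takes precedence, so the three categories
#' partition accepted pairs.
#'
#' @param overlap_len overlap alignment length in columns.
#' @param lenA,lenB transcript lengths.
#' @return one of `"HC"`, `"nt100"`, `"LC"`.
#' @export
coverage_category <- function(overlap_len, lenA, lenB) {
  stopifnot(lenA > 0, lenB > 0)
  if (overlap_len > 0.5 * lenA || overlap_len > 0.5 * lenB) return("HC")
  if (overlap_len >= 100L) return("nt100")
  "LC"
}
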