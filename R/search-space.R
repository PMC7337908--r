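#' Build sRNA phase blocks on each transcript
#'
#' Adjacent aligned sRNAs — abutting exactly (the next alignment starts where
#' the previous one ends) or overlapping — are chained into maximal blocks.
#' Blocks whose number of distinct member alignments reaches `min_phases` are
#' emitted with their spanning interval. A 1nt gap breaks the chain.
#'
#' @param alignments alignment data.frame (`sequence`, `transcript`, `start`,
#'   `end`), exact sense-strand hits.
#' @param min_phases minimum number of member alignments per block.
#' @return data.frame with `transcript`, `start`, `end`, `phases`.
#' @export
build_phase_blocks <- function(alignments, min_phases = 1L) {
  if (nrow(alignments) == 0L)
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), phases = integer(0),
                      stringsAsFactors = FALSE))
  aln <- unique(alignments[, c("transcript", "start", "end")])
  aln <- aln[order(aln$transcript, aln$start, aln$end), , drop = FALSE]
  out <- list()
  for (tx in unique(aln$transcript)) {
    a <- aln[aln$transcript == tx, , drop = FALSE]
    block_start <- a$start[1]; block_end <- a$end[1]; nmem <- 1L
    flush <- function(s, e, k) {
      if (k >= min_phases)
        out[[length(out) + 1L]] <<- data.frame(
          transcript = tx, start = s, end = e, phases = k,
          stringsAsFactors = FALSE)
    }
    for (i in seq2(2L, nrow(a))) {
      if (a$start[i] <= block_end) {        # overlap or exact adjacency
        block_end <- max(block_end, a$end[i])
        nmem <- nmem + 1L
      } else {
        flush(block_start, block_end, nmem)
        block_start <- a$start[i]; block_end <- a$end[i]; nmem <- 1L
      }
    }
    flush(block_start, block_end, nmem)
  }
  if (length(out) == 0L)
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), phases = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Degradome-adjacent regions
#'
#' For every sRNA alignment `[s, e)` with a degradome tag whose 5' end aligns
#' exactly at `e` (immediately after the sRNA's 3' terminus, reaching `t`) on
#' the same transcript, the combined region `[s, t)` (~40nt for 21nt reads
#' and 20nt tags) is emitted. These regions carry putative Dicer cleavage
#' evidence and seed the candidate-pair search.
#'
#' @param srna_alignments,degradome_alignments alignment data.frames on the
#'   same transcript space.
#' @return data.frame with `transcript`, `start`, `end`.
#' @export
degradome_adjacent_regions <- function(srna_alignments, degradome_alignments) {
  empty <- data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (nrow(srna_alignments) == 0L || nrow(degradome_alignments) == 0L)
    return(empty)
  m <- merge(srna_alignments[, c("transcript", "start", "end")],
             degradome_alignments[, c("transcript", "start", "end")],
             by.x = c("transcript", "end"), by.y = c("transcript", "start"),
             suffixes = c("_srna", "_tag"))
  if (nrow(m) == 0L) return(empty)
  res <- unique(data.frame(transcript = m$transcript, start = m$start,
                           end = m$end_tag, stringsAsFactors = FALSE))
  res <- res[order(res$transcript, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Generate candidate NAT pairs by reverse-complement exact matching
#'
#' Takes the extracted subsequences (phase blocks and degradome-adjacent
#' regions), reverse complements them and searches for exact occurrences in
#' all transcripts other than the source. Each hit marks a potential
#' overlapping region between two transcripts; unordered pairs are
#' deduplicated.
#'
#' @param regions data.frame with `transcript`, `start`, `end` (the extracted
#'   subsequences, 0-based half-open).
#' @param index an `exact_index` over all transcripts.
#' @param transcripts the `nat_transcripts` the regions refer to.
#' @return data.frame with `source`, `hit`, `seed_start`, `seed_end` (on the
#'   source transcript) and `hit_start`, `hit_end` (on the hit transcript),
#'   unordered-deduplicated on \{source, hit\}.
#' @export
generate_candidate_pairs <- function(regions, index, transcripts) {
  empty <- data.frame(source = character(0), hit = character(0),
                      seed_start = integer(0), seed_end = integer(0),
                      hit_start = integer(0), hit_end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) return(empty)
  regions <- unique(regions[, c("transcript", "start", "end")])
  seqs <- transcripts$seq
  out <- list()
  for (i in seq_len(nrow(regions))) {
    tx <- regions$transcript[i]
    sub <- substr(seqs[[tx]], regions$start[i] + 1L, regions$end[i])
    hits <- find_exact(index, revcomp(sub))
    hits <- hits[hits$transcript != tx, , drop = FALSE]
    if (nrow(hits) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      source = tx, hit = hits$transcript,
      seed_start = regions$start[i], seed_end = regions$end[i],
      hit_start = hits$start, hit_end = hits$end,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  # deterministic unordered dedup on {source, hit}
  res <- res[order(res$source, res$hit, res$seed_start, res$hit_start), ,
             drop = FALSE]
  key <- ifelse(res$source < res$hit,
                paste(res$source, res$hit, sep = "\r"),
                paste(res$hit, res$source, sep = "\r"))
  res <- res[!duplicated(key), , drop = FALSE]
  rownames(res) <- NULL
  res
}
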