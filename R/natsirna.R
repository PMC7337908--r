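#' Overhang configuration for star-partner search
#'
#' The duplex signature used to recognise a star partner: the partner's
#' footprint, mapped through the pair's complementarity mapping, must be
#' offset from the mature footprint by `offset` nucleotides. The default is
#' the 2nt 5' overhang; a 2nt 3' overhang (the canonical Dicer signature)
#' can be selected instead.
#'
#' @param offset offset in nucleotides (default 2).
#' @param end `"five_prime"` or `"three_prime"`.
#' @return a list with `offset` and `end`.
#' @export
overhang_config <- function(offset = 2L, end = c("five_prime", "three_prime")) {
  end <- match.arg(end)
  stopifnot(offset >= 0L)
  list(offset = as.integer(offset), end = end)
}

#' sRNA alignments inside a pair's overlap region
#'
#' @param pair a `nat_pair`.
#' @param alignments sRNA alignment data.frame.
#' @return list with elements `A` and `B`: the alignments on each transcript
#'   whose interval intersects that transcript's overlap interval by at least
#'   1nt (boundary-straddling reads are included).
#' @export
overlap_srnas <- function(pair, alignments) {
  pick <- function(tx, interval) {
    a <- alignments[alignments$transcript == tx &
                      alignments$start < interval[2] &
                      alignments$end > interval[1], , drop = FALSE]
    rownames(a) <- NULL
    a
  }
  list(A = pick(pair$transcriptA, pair$intervalA),
       B = pick(pair$transcriptB, pair$intervalB))
}

# map a footprint [s, e) on `from` coordinates into the partner transcript's
# coordinates through the pair's aligned columns; NA when either endpoint
# falls on an alignment gap
map_footprint <- function(pair, from = c("B", "A"), s, e) {
  from <- match.arg(from)
  map <- if (from == "B") pair$alignment$map_b_to_a else pair$alignment$map_a_to_b
  if (s + 1L > length(map) || e > length(map)) return(c(NA_integer_, NA_integer_))
  lo <- map[e]        # position of footprint's last base (e-1), 1-based index e
  hi <- map[s + 1L]   # position of footprint's first base
  if (is.na(lo) || is.na(hi)) return(c(NA_integer_, NA_integer_))
  c(lo, hi + 1L)
}

#' Find the star partner of a mature sRNA
#'
#' Each partner-transcript sRNA footprint is mapped through the pair's
#' complementarity mapping into the mature transcript's coordinates. A star
#' matches when the mapped footprint `[fs, fe)` satisfies `fs - s == o` and
#' `fe - e == o`, where `[s, e)` is the mature footprint and `o = +offset`
#' for a 5' overhang or `-offset` for a 3' overhang. Among multiple matches
#' the highest-abundance star wins, ties broken by the lexicographically
#' smallest sequence. Candidates whose endpoints map across alignment gaps
#' are skipped.
#'
#' @param mature_alignment one-row data.frame (or list) with `start`, `end`
#'   on the mature transcript.
#' @param pair a `nat_pair`.
#' @param partner_alignments alignments on the partner transcript (normally
#'   restricted to the overlap region).
#' @param mature_on `"A"` if the mature sRNA aligns to `transcriptA`.
#' @param config an [overhang_config()].
#' @return one-row data.frame of the star alignment, or `NULL`.
#' @export
find_star <- function(mature_alignment, pair, partner_alignments,
                      mature_on = c("A", "B"), config = overhang_config()) {
  mature_on <- match.arg(mature_on)
  if (nrow(partner_alignments) == 0L) return(NULL)
  o <- if (config$end == "five_prime") config$offset else -config$offset
  s <- mature_alignment$start; e <- mature_alignment$end
  from <- if (mature_on == "A") "B" else "A"
  hits <- integer(0)
  for (i in seq_len(nrow(partner_alignments))) {
    fp <- map_footprint(pair, from, partner_alignments$start[i],
                        partner_alignments$end[i])
    if (anyNA(fp)) next
    if (fp[1] - s == o && fp[2] - e == o) hits <- c(hits, i)
  }
  if (length(hits) == 0L) return(NULL)
  cand <- partner_alignments[hits, , drop = FALSE]
  cand <- cand[order(-cand$abundance, cand$sequence), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Degradome support for an sRNA alignment
#'
#' TRUE when a degradome tag's 5' end aligns exactly at the position
#' immediately after the sRNA's 3' terminus on the same transcript — the
#' same adjacency used to build degradome-adjacent regions.
#'
#' @param alignment one-row data.frame (or list) with `transcript` and `end`.
#' @param degradome_alignments degradome alignment data.frame (may be empty).
#' @return logical.
#' @export
degradome_support <- function(alignment, degradome_alignments) {
  if (is.null(degradome_alignments) || nrow(degradome_alignments) == 0L)
    return(FALSE)
  any(degradome_alignments$transcript == alignment$transcript &
        degradome_alignments$start == alignment$end)
}

#' Biogenesis group of a nat-siRNA call
#'
#' Group 1: star present, both mature and star supported by the degradome.
#' Group 2: star present, only the mature supported. Group 3: star present,
#' mature unsupported. Group 4: no star but mature supported. Group 5: only
#' the sRNA aligning to the overlapping region.
#'
#' @param star_present,deg_mature,deg_star logicals.
#' @return integer group 1-5.
#' @export
assign_group <- function(star_present, deg_mature, deg_star) {
  if (star_present && deg_mature && deg_star) return(1L)
  if (star_present && deg_mature) return(2L)
  if (star_present) return(3L)
  if (deg_mature) return(4L)
  5L
}

#' Call nat-siRNAs for an accepted NAT pair
#'
#' Extracts the sRNAs aligned to the pair's overlap region on each
#' transcript; the sRNAs of the transcript under investigation are the
#' mature sequences and those of the partner are the star candidates. Each
#' call is assigned its biogenesis group from the star and degradome
#' evidence.
#'
#' @param pair a `nat_pair` with a `pair_id` entry or the id given via
#'   `pair_id`.
#' @param alignments sRNA alignment data.frame.
#' @param degradome_alignments optional degradome alignment data.frame.
#' @param overhang an [overhang_config()].
#' @param pair_id identifier copied into the output.
#' @return data.frame with one row per call: `pair_id`, `sequence`,
#'   `abundance`, `origin_transcript`, `start`, `end`, `group`,
#'   `star_sequence`, `deg_support_mature`, `deg_support_star`,
#'   `multi_origin`.
#' @export
call_nat_sirnas <- function(pair, alignments, degradome_alignments = NULL,
                            overhang = overhang_config(), pair_id = "pair") {
  ov <- overlap_srnas(pair, alignments)
  multi <- multi_origin_sequences(alignments)
  one_side <- function(matures, partners, side) {
    rows <- vector("list", nrow(matures))
    for (i in seq_len(nrow(matures))) {
      m <- matures[i, , drop = FALSE]
      star <- find_star(m, pair, partners, mature_on = side, config = overhang)
      deg_m <- degradome_support(m, degradome_alignments)
      deg_s <- if (!is.null(star))
        degradome_support(star, degradome_alignments) else FALSE
      rows[[i]] <- data.frame(
        pair_id = pair_id, sequence = m$sequence, abundance = m$abundance,
        origin_transcript = m$transcript, start = m$start, end = m$end,
        group = assign_group(!is.null(star), deg_m, deg_s),
        star_sequence = if (!is.null(star)) star$sequence else NA_character_,
        deg_support_mature = deg_m, deg_support_star = deg_s,
        multi_origin = m$sequence %in% multi,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  out <- rbind(one_side(ov$A, ov$B, "A"), one_side(ov$B, ov$A, "B"))
  if (is.null(out))
    out <- data.frame(pair_id = character(0), sequence = character(0),
                      abundance = integer(0), origin_transcript = character(0),
                      start = integer(0), end = integer(0), group = integer(0),
                      star_sequence = character(0),
                      deg_support_mature = logical(0),
                      deg_support_star = logical(0),
                      multi_origin = logical(0), stringsAsFactors = FALSE)
  out <- out[order(out$origin_transcript, out$start, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sequences whose alignments support more than one distinct origin transcript
multi_origin_sequences <- function(alignments) {
  if (nrow(alignments) == 0L) return(character(0))
  tab <- unique(alignments[, c("sequence", "transcript")])
  counts <- table(tab$sequence)
  names(counts)[counts > 1L]
}

#' Drop calls whose sequence originates from multiple transcripts
#'
#' Optional post-filter; the `multi_origin` flag is always populated on the
#' calls regardless.
#'
#' @param calls calls data.frame from [call_nat_sirnas()].
#' @param enabled apply the filter (`FALSE` returns the input unchanged).
#' @return filtered calls data.frame.
#' @export
unique_origin_filter <- function(calls, enabled = TRUE) {
  if (!enabled || nrow(calls) == 0L) return(calls)
  out <- calls[!calls$multi_origin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export calls for downstream target prediction
#'
#' Writes the distinct nat-siRNA sequences as a collapsed FASTA
#' (`>seq<i>-<abundance>`), suitable as sRNA input to an external
#' degradome-based target-prediction tool. Duplicate sequences across pairs
#' are merged with summed abundance.
#'
#' @param calls calls data.frame.
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
export_for_target_prediction <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ab <- vapply(split(calls$abundance, calls$sequence), sum, numeric(1))
  reads <- data.frame(sequence = names(ab), abundance = as.integer(ab),
                      stringsAsFactors = FALSE)
  reads <- reads[order(reads$sequence), , drop = FALSE]
  write_collapsed_fasta(reads, path)
}
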