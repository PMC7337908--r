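#' Greedy 10nt clustering of sRNA alignments on a transcript
#'
#' Starting from the 5'-most unclustered alignment, every alignment whose
#' first nucleotide lies within the 10nt segment starting at the seed (seed
#' start to seed start + 9) joins the seed's cluster; the pass repeats from
#' the next unclustered alignment. Clusters whose summed redundant read
#' abundance exceeds 5 are retained.
#'
#' @param alignments alignment data.frame on one transcript (`sequence`,
#'   `abundance`, `start`).
#' @return data.frame with one row per cluster: `seed_start`, `n_alignments`,
#'   `n_unique`, `total_reads`, `retained`.
#' @export
cluster_alignments <- function(alignments) {
  empty <- data.frame(seed_start = integer(0), n_alignments = integer(0),
                      n_unique = integer(0), total_reads = integer(0),
                      retained = logical(0), stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  a <- alignments[order(alignments$start, alignments$sequence), , drop = FALSE]
  starts <- a$start
  out <- list()
  i <- 1L
  n <- nrow(a)
  while (i <= n) {
    seed <- starts[i]
    j <- i
    while (j < n && starts[j + 1L] <= seed + 9L) j <- j + 1L
    members <- a[i:j, , drop = FALSE]
    total <- sum(members$abundance)
    out[[length(out) + 1L]] <- data.frame(
      seed_start = seed, n_alignments = j - i + 1L,
      n_unique = length(unique(members$sequence)),
      total_reads = total, retained = total > 5L,
      stringsAsFactors = FALSE)
    i <- j + 1L
  }
  do.call(rbind, out)
}

#' Classify the alignment distribution pattern of a transcript
#'
#' Site-specific when the transcript has at most 10 retained clusters and at
#' least 50% of the transcript's unique reads fall inside them; otherwise
#' distributed. No profile exists for a transcript with no aligned reads.
#'
#' @param retained_clusters number of retained clusters.
#' @param unique_in_clusters distinct sequences inside retained clusters.
#' @param unique_total distinct sequences aligned anywhere on the transcript.
#' @return `"site_specific"` or `"distributed"`.
#' @export
classify_pattern <- function(retained_clusters, unique_in_clusters,
                             unique_total) {
  if (unique_total == 0L)
    stop("no profile for a transcript without aligned reads")
  if (retained_clusters <= 10L &&
      100 * unique_in_clusters / unique_total >= 50) "site_specific"
  else "distributed"
}

# full per-transcript profile: clusters, retained count, percent unique
profile_transcript <- function(alignments) {
  if (nrow(alignments) == 0L) return(NULL)
  cl <- cluster_alignments(alignments)
  a <- alignments[order(alignments$start, alignments$sequence), , drop = FALSE]
  retained <- cl[cl$retained, , drop = FALSE]
  in_clusters <- character(0)
  for (k in seq_len(nrow(retained))) {
    seed <- retained$seed_start[k]
    in_clusters <- c(in_clusters,
                     a$sequence[a$start >= seed & a$start <= seed + 9L])
  }
  unique_total <- length(unique(a$sequence))
  unique_in <- length(unique(in_clusters))
  pct <- if (unique_total) 100 * unique_in / unique_total else 0
  list(retained_clusters = nrow(retained),
       pct_unique_in_clusters = pct,
       pattern = classify_pattern(nrow(retained), unique_in, unique_total))
}

#' sRNA alignment densities of a NAT pair
#'
#' `N_o` is the number of distinct sRNA sequences intersecting the overlap
#' region on either transcript; `N_g` the number aligning anywhere on either
#' transcript; `L_o` the overlap alignment length and `L_g` the summed
#' transcript lengths. The reported densities are `N_o/L_o` and `N_g/L_g`.
#'
#' @param pair a `nat_pair`.
#' @param alignments sRNA alignment data.frame.
#' @param transcripts a `nat_transcripts` object.
#' @return list with `N_o`, `N_g`, `L_o`, `L_g`, `density_overlap`,
#'   `density_global`.
#' @export
alignment_densities <- function(pair, alignments, transcripts) {
  ov <- overlap_srnas(pair, alignments)
  N_o <- length(unique(c(ov$A$sequence, ov$B$sequence)))
  on_pair <- alignments[alignments$transcript %in%
                          c(pair$transcriptA, pair$transcriptB), , drop = FALSE]
  N_g <- length(unique(on_pair$sequence))
  L_o <- pair$overlap_len
  L_g <- nchar(transcripts$seq[[pair$transcriptA]]) +
    nchar(transcripts$seq[[pair$transcriptB]])
  list(N_o = N_o, N_g = N_g, L_o = L_o, L_g = L_g,
       density_overlap = N_o / L_o, density_global = N_g / L_g)
}

# per-pair profile rows (one per transcript with alignments) and pair pattern
profile_pair <- function(pair, alignments, pair_id) {
  rows <- list()
  patterns <- character(0)
  for (tx in c(pair$transcriptA, pair$transcriptB)) {
    a <- alignments[alignments$transcript == tx, , drop = FALSE]
    p <- profile_transcript(a)
    if (is.null(p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = pair_id, transcript = tx,
      retained_clusters = p$retained_clusters,
      pct_unique_in_clusters = round(p$pct_unique_in_clusters, 4),
      pattern = p$pattern, stringsAsFactors = FALSE)
    patterns <- c(patterns, p$pattern)
  }
  profiles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0), transcript = character(0),
               retained_clusters = integer(0),
               pct_unique_in_clusters = numeric(0), pattern = character(0),
               stringsAsFactors = FALSE)
  pair_pattern <- if ("site_specific" %in% patterns) "site_specific"
  else if (length(patterns)) "distributed" else NA_character_
  list(profiles = profiles, pair_pattern = pair_pattern)
}
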