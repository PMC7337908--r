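# Independent oracles used to cross-check the package's implementations.
# Each is written as the most literal possible rendition of the rule it
# checks, deliberately sharing no code with the implementation.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# all (overlapping) exact occurrences of q in subject, by comparing every
# window of the subject against the query
naive_exact_scan <- function(q, subjects) {
  k <- nchar(q)
  rows <- list()
  for (id in names(subjects)) {
    s <- subjects[[id]]
    L <- nchar(s)
    if (L < k) next
    hits <- which(substring(s, 1:(L - k + 1L), k:L) == q)
    for (h in hits)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = q, transcript = id, start = h - 1L, end = h - 1L + k,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(sequence = character(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# optimal local alignment score from an independent full-DP implementation
# (Biostrings), same scoring convention: gap run of length L costs
# open + L * ext
sw_oracle_score <- function(a, b, match = 2, mismatch = -3,
                            gap_open = 5, gap_ext = 2) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  as.integer(Biostrings::score(pa))
}

# literal simulation of the greedy clustering rule: repeatedly take the
# 5'-most remaining alignment as seed, pull in everything starting within
# its 10nt segment, retain clusters with summed abundance > 5
greedy_cluster_oracle <- function(starts, abundances) {
  remaining <- order(starts)
  clusters <- list()
  while (length(remaining) > 0L) {
    seed_i <- remaining[1]
    seed <- starts[seed_i]
    member <- remaining[starts[remaining] >= seed &
                          starts[remaining] <= seed + 9L]
    clusters[[length(clusters) + 1L]] <- list(
      seed = seed, total = sum(abundances[member]))
    remaining <- setdiff(remaining, member)
  }
  data.frame(seed_start = vapply(clusters, `[[`, numeric(1), "seed"),
             total_reads = vapply(clusters, `[[`, numeric(1), "total"),
             retained = vapply(clusters, function(cl) cl$total > 5,
                               logical(1)))
}

# brute-force window counting for the composition filter
low_complexity_oracle <- function(s) {
  L <- nchar(s)
  count_max <- function(k) {
    wins <- vapply(1:(L - k + 1L), function(i) substr(s, i, i + k - 1L),
                   character(1))
    max(table(wins))
  }
  count_max(1) / L > 0.75 ||
    count_max(2) / (L - 1) > 0.375 ||
    count_max(3) / (L - 2) > 0.25
}

# brute-force Hamming scan for the blacklist rule
hamming_blacklist_hit <- function(read, blacklist, max_mm = 2) {
  k <- nchar(read)
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  for (b in blacklist) {
    L <- nchar(b)
    if (L < k) next
    for (i in 1:(L - k + 1L)) {
      w <- strsplit(substr(b, i, i + k - 1L), "", fixed = TRUE)[[1]]
      if (sum(w != rc) <= max_mm) return(TRUE)
    }
  }
  FALSE
}

# brute-force interval chaining: merge alignments linked by overlap or
# exact adjacency, count members per chain
chain_blocks_oracle <- function(starts, ends, min_phases) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  groups <- list(); cur <- c(starts[1], ends[1]); n <- 1L
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur[2]) {
      cur[2] <- max(cur[2], ends[i]); n <- n + 1L
    } else {
      groups[[length(groups) + 1L]] <- c(cur, n)
      cur <- c(starts[i], ends[i]); n <- 1L
    }
  }
  groups[[length(groups) + 1L]] <- c(cur, n)
  g <- do.call(rbind, groups)
  g <- g[g[, 3] >= min_phases, , drop = FALSE]
  data.frame(start = g[, 1], end = g[, 2], phases = g[, 3])
}
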