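test_that("phase blocks chain abutting and overlapping alignments", {
  a <- aln_rows("t1", c(10L, 31L), 21L)
  b <- build_phase_blocks(a, min_phases = 2)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end, b$phases), c(10L, 52L, 2L))
  # single alignment forms a block only when one phase suffices
  single <- aln_rows("t1", 10L, 21L)
  expect_equal(nrow(build_phase_blocks(single, min_phases = 1)), 1L)
  expect_equal(build_phase_blocks(single, min_phases = 1)$end, 31L)
  expect_equal(nrow(build_phase_blocks(single, min_phases = 2)), 0L)
  # a 1nt gap breaks the chain
  gapped <- aln_rows("t1", c(10L, 32L), 21L)
  expect_equal(nrow(build_phase_blocks(gapped, min_phases = 2)), 0L)
  expect_equal(nrow(build_phase_blocks(gapped, min_phases = 1)), 2L)
})

test_that("phase blocks equal an interval-chaining oracle on random instances", {
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    starts <- sort(sample(0:300, n, replace = TRUE))
    ends <- starts + sample(19:24, n, replace = TRUE)
    aln <- data.frame(sequence = sprintf("s%03d", seq_len(n)), abundance = 1L,
                      transcript = "t", start = starts, end = ends,
                      stringsAsFactors = FALSE)
    aln <- aln[!duplicated(aln[, c("start", "end")]), ]
    min_ph <- sample(1:3, 1)
    got <- build_phase_blocks(aln, min_ph)
    want <- chain_blocks_oracle(aln$start, aln$end, min_ph)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, as.integer(want$start))
      expect_equal(got$end, as.integer(want$end))
      expect_equal(got$phases, as.integer(want$phases))
    }
  }
})

test_that("degradome-adjacent regions require strict adjacency", {
  srna <- aln_rows("t1", 100L, 21L)
  tag <- aln_rows("t1", 121L, 20L, seqs = "D1")
  r <- degradome_adjacent_regions(srna, tag)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(100L, 141L))
  expect_equal(r$end - r$start, 41L)        # the ~40nt combined region
  # 1nt gap: no region
  tag_gap <- aln_rows("t1", 122L, 20L, seqs = "D1")
  expect_equal(nrow(degradome_adjacent_regions(srna, tag_gap)), 0L)
  # different transcript: no region
  tag_other <- aln_rows("t2", 121L, 20L, seqs = "D1")
  expect_equal(nrow(degradome_adjacent_regions(srna, tag_other)), 0L)
})

test_that("degradome regions equal a brute-force cross-join", {
  set.seed(52)
  srna <- aln_rows("t1", sample(0:200, 30, TRUE), 21L,
                   seqs = sprintf("s%02d", 1:30))
  tags <- aln_rows("t1", sample(0:230, 30, TRUE), 20L,
                   seqs = sprintf("d%02d", 1:30))
  got <- degradome_adjacent_regions(srna, tags)
  want <- list()
  for (i in seq_len(nrow(srna))) for (j in seq_len(nrow(tags)))
    if (tags$start[j] == srna$end[i])
      want[[length(want) + 1L]] <- c(srna$start[i], tags$end[j])
  want <- unique(do.call(rbind, want))
  expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
  if (nrow(got))
    expect_setequal(paste(got$start, got$end),
                    paste(want[, 1], want[, 2]))
})

test_that("candidate pairs come from reverse-complement hits on other transcripts", {
  set.seed(53)
  block <- rnd_dna(60)
  tx <- c(a = paste0(rnd_dna(40), block, rnd_dna(40)),
          b = paste0(rnd_dna(20), revcomp(block), rnd_dna(20)),
          c = rnd_dna(100))
  idx <- build_exact_index(tx)
  transcripts <- natsir:::new_nat_transcripts(
    tx, info = data.frame(id = names(tx), chromosome = NA, strand = NA,
                          gstart = NA, gend = NA, source = "fasta"))
  regions <- data.frame(transcript = "a", start = 40L, end = 100L,
                        stringsAsFactors = FALSE)
  cand <- generate_candidate_pairs(regions, idx, transcripts)
  expect_equal(nrow(cand), 1L)
  expect_setequal(c(cand$source, cand$hit), c("a", "b"))
  # a block whose revcomp occurs only in its own source yields nothing
  pal_block <- "ACGTACGTAAATTTACGTACGT"
  tx2 <- c(a = paste0(rnd_dna(30), pal_block, rnd_dna(10),
                      revcomp(pal_block), rnd_dna(30)))
  transcripts2 <- natsir:::new_nat_transcripts(
    tx2, info = data.frame(id = "a", chromosome = NA, strand = NA,
                           gstart = NA, gend = NA, source = "fasta"))
  cand2 <- generate_candidate_pairs(
    data.frame(transcript = "a", start = 30L, end = 52L),
    build_exact_index(tx2), transcripts2)
  expect_equal(nrow(cand2), 0L)
})

test_that("planted pairs are all recovered and order does not matter", {
  ann <- make_synthetic_annotation(3, overlap_len_range = c(150, 150),
                                   seed = 54, n_decoys = 4)
  sim <- simulate_reads(ann, 120, seed = 55)
  reads <- sim$reads
  run_cand <- function(tx_order) {
    tx <- ann$transcripts
    tx$seq <- tx$seq[tx_order]
    idx <- build_exact_index(tx)
    aln <- align_reads(idx, reads)
    blocks <- build_phase_blocks(aln, 1)
    generate_candidate_pairs(blocks[, c("transcript", "start", "end")],
                             idx, tx)
  }
  ids <- names(ann$transcripts$seq)
  cand1 <- run_cand(ids)
  set.seed(56)
  cand2 <- run_cand(sample(ids))
  norm <- function(d) {
    k <- ifelse(d$source < d$hit, paste(d$source, d$hit),
                paste(d$hit, d$source))
    sort(unique(k))
  }
  expect_equal(norm(cand1), norm(cand2))
  expect_equal(norm(cand1), sort(paste(ann$truth$transcriptA,
                                       ann$truth$transcriptB)))
})
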