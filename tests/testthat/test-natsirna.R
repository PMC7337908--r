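# a perfect pair plus its complementarity mapping, shared by the star tests
star_fixture <- function(seed = 71) {
  tx <- make_perfect_pair(150L, flankA = 60L, flankB = 80L, seed = seed)
  pair <- classify_pair(list(source = "txA", hit = "txB"), tx, nat_config())
  list(tx = tx, pair = pair)
}

# B footprint whose mapped A footprint is [fs, fe) on a perfect overlap
b_footprint_for <- function(pair, fs, fe) {
  oaS <- pair$intervalA[1]; obE <- pair$intervalB[2]
  c(oaS + obE - fe, oaS + obE - fs)
}

test_that("overlap sRNA extraction uses any-intersection", {
  fx <- star_fixture()
  iv <- fx$pair$intervalA  # [60, 210)
  aln <- data.frame(
    sequence = c("IN", "BEFORE", "STRADDLE"), abundance = 1L,
    transcript = "txA",
    start = c(iv[1] + 10L, iv[1] - 30L, iv[1] - 10L),
    end = c(iv[1] + 31L, iv[1], iv[1] + 11L),
    stringsAsFactors = FALSE)
  ov <- overlap_srnas(fx$pair, aln)
  expect_setequal(ov$A$sequence, c("IN", "STRADDLE"))
  expect_equal(nrow(ov$B), 0L)
})

test_that("star search applies the overhang offset with its sign", {
  fx <- star_fixture()
  pair <- fx$pair
  s <- pair$intervalA[1] + 40L; e <- s + 21L
  mature <- data.frame(sequence = "M", abundance = 3L, transcript = "txA",
                       start = s, end = e, stringsAsFactors = FALSE)
  bf <- b_footprint_for(pair, s + 2L, e + 2L)   # maps to A[s+2, e+2)
  partner <- data.frame(sequence = "S", abundance = 2L, transcript = "txB",
                        start = bf[1], end = bf[2], stringsAsFactors = FALSE)
  hit <- find_star(mature, pair, partner, "A", overhang_config(2, "five_prime"))
  expect_equal(hit$sequence, "S")
  # the same partner fails under a 3' overhang, which needs A[s-2, e-2)
  expect_null(find_star(mature, pair, partner, "A",
                        overhang_config(2, "three_prime")))
  bf3 <- b_footprint_for(pair, s - 2L, e - 2L)
  partner3 <- data.frame(sequence = "S3", abundance = 1L, transcript = "txB",
                         start = bf3[1], end = bf3[2], stringsAsFactors = FALSE)
  expect_equal(find_star(mature, pair, partner3, "A",
                         overhang_config(2, "three_prime"))$sequence, "S3")
  expect_null(find_star(mature, pair, partner[0, ], "A"))
})

test_that("among multiple stars the most abundant wins, ties by sequence", {
  fx <- star_fixture()
  pair <- fx$pair
  s <- pair$intervalA[1] + 40L; e <- s + 21L
  mature <- data.frame(sequence = "M", abundance = 1L, transcript = "txA",
                       start = s, end = e, stringsAsFactors = FALSE)
  bf <- b_footprint_for(pair, s + 2L, e + 2L)
  partners <- data.frame(sequence = c("ZZ", "AA", "BB"),
                         abundance = c(5L, 5L, 9L), transcript = "txB",
                         start = bf[1], end = bf[2], stringsAsFactors = FALSE)
  expect_equal(find_star(mature, pair, partners, "A")$sequence, "BB")
  expect_equal(find_star(mature, pair, partners[1:2, ], "A")$sequence, "AA")
})

test_that("degradome support is the exact 3'-adjacency", {
  aln <- list(transcript = "txA", end = 121L)
  tags_at <- function(st) data.frame(sequence = "D", abundance = 1L,
                                     transcript = "txA", start = st,
                                     end = st + 20L, stringsAsFactors = FALSE)
  expect_true(degradome_support(aln, tags_at(121L)))
  expect_false(degradome_support(aln, tags_at(122L)))
  expect_false(degradome_support(aln, NULL))
})

test_that("group assignment is a total partition with the documented precedence", {
  expect_equal(assign_group(TRUE, TRUE, TRUE), 1L)
  expect_equal(assign_group(TRUE, TRUE, FALSE), 2L)
  expect_equal(assign_group(TRUE, FALSE, FALSE), 3L)
  expect_equal(assign_group(TRUE, FALSE, TRUE), 3L)  # star-supported only
  expect_equal(assign_group(FALSE, TRUE, FALSE), 4L)
  expect_equal(assign_group(FALSE, FALSE, FALSE), 5L)
  grid <- expand.grid(s = c(TRUE, FALSE), m = c(TRUE, FALSE),
                      t = c(TRUE, FALSE))
  groups <- mapply(assign_group, grid$s, grid$m, grid$t)
  expect_true(all(groups %in% 1:5))
})

test_that("multi-origin sequences are flagged and optionally dropped", {
  calls <- data.frame(pair_id = "p", sequence = c("AA", "BB"),
                      abundance = 1L, origin_transcript = "txA",
                      start = 0L, end = 21L, group = 5L,
                      star_sequence = NA_character_,
                      deg_support_mature = FALSE, deg_support_star = FALSE,
                      multi_origin = c(TRUE, FALSE), stringsAsFactors = FALSE)
  expect_equal(unique_origin_filter(calls, TRUE)$sequence, "BB")
  expect_equal(unique_origin_filter(calls, FALSE), calls)
})

test_that("calls partition into groups and degradome-free data yields only 3 and 5", {
  ann <- make_synthetic_annotation(4, orientation_mix = "full_overlap",
                                   overlap_len_range = c(150, 200), seed = 72)
  pd <- plant_duplex_reads(ann, group_plan = c(3L, 5L, 3L, 5L), seed = 73)
  aln <- align_reads(build_exact_index(ann$transcripts), pd$reads)
  all_calls <- list()
  for (i in 1:4) {
    pair <- classify_pair(list(source = ann$truth$transcriptA[i],
                               hit = ann$truth$transcriptB[i]),
                          ann$transcripts, nat_config())
    all_calls[[i]] <- call_nat_sirnas(pair, aln, NULL,
                                      pair_id = sprintf("p%d", i))
  }
  calls <- do.call(rbind, all_calls)
  expect_true(all(calls$group %in% c(3L, 5L)))
  expect_equal(nrow(calls), sum(table(calls$group)))
  m <- merge(calls, pd$truth, by = "sequence")
  expect_equal(nrow(m), nrow(pd$truth))
  expect_equal(m$group, m$expected_group)
})

test_that("swapping investigated transcripts preserves group structure", {
  ann <- make_synthetic_annotation(1, orientation_mix = "full_overlap",
                                   overlap_len_range = c(160, 160), seed = 74)
  pd <- plant_duplex_reads(ann, group_plan = 3L, seed = 75)
  aln <- align_reads(build_exact_index(ann$transcripts), pd$reads)
  pair <- classify_pair(list(source = "tx01A", hit = "tx01B"),
                        ann$transcripts, nat_config())
  calls <- call_nat_sirnas(pair, aln, NULL, pair_id = "p")
  # mature on A and mature on B both see the other as star: both group 3
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$origin_transcript, c("tx01A", "tx01B"))
  expect_equal(calls$group, c(3L, 3L))
  expect_equal(sort(calls$star_sequence), sort(calls$sequence))
})

test_that("export for target prediction merges duplicates and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  calls <- data.frame(sequence = c("ACGTACGTACGTACGTACGTA",
                                   "ACGTACGTACGTACGTACGTA",
                                   "TTGCAATTGCAATTGCAATTG"),
                      abundance = c(4L, 2L, 7L), stringsAsFactors = FALSE)
  export_for_target_prediction(calls, f)
  back <- read_redundant_fasta(f, collapse_header_counts = TRUE)
  expect_equal(nrow(back), 2L)
  expect_equal(back$abundance[back$sequence == "ACGTACGTACGTACGTACGTA"], 6L)
  # empty export writes an empty file
  f2 <- withr::local_tempfile(fileext = ".fa")
  export_for_target_prediction(calls[0, ], f2)
  expect_warning(e <- read_redundant_fasta(f2), "empty")
  expect_equal(nrow(e), 0L)
})
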