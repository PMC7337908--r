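test_that("generated annotations are reproducible bit-exactly from the seed", {
  a1 <- make_synthetic_annotation(3, overlap_len_range = c(120, 200),
                                  seed = 91, n_decoys = 3)
  a2 <- make_synthetic_annotation(3, overlap_len_range = c(120, 200),
                                  seed = 91, n_decoys = 3)
  expect_identical(a1$genome, a2$genome)
  expect_identical(a1$truth, a2$truth)
  a3 <- make_synthetic_annotation(3, overlap_len_range = c(120, 200),
                                  seed = 92, n_decoys = 3)
  expect_false(identical(a1$genome, a3$genome))
})

test_that("transcript extraction recovers the planted sequences byte-equal", {
  dir <- withr::local_tempdir()
  ann <- make_synthetic_annotation(4, overlap_len_range = c(120, 250),
                                   seed = 93, n_decoys = 5, out_dir = dir)
  expect_true(all(file.exists(ann$paths)))
  tx <- extract_transcripts(ann$paths[["gff3"]], ann$paths[["genome"]])
  expect_setequal(names(tx$seq), names(ann$transcripts$seq))
  expect_identical(tx$seq[names(ann$transcripts$seq)], ann$transcripts$seq)
  expect_identical(tx$info[order(tx$info$id), c("chromosome", "strand",
                                                "gstart", "gend")],
                   ann$transcripts$info[order(ann$transcripts$info$id),
                                        c("chromosome", "strand",
                                          "gstart", "gend")],
                   ignore_attr = TRUE)
})

test_that("multi-exon transcripts splice out the intron", {
  ann <- make_synthetic_annotation(3, overlap_len_range = c(150, 150),
                                   seed = 94, multi_exon_every = 3)
  ex <- ann$transcripts$exons
  two_exon <- names(which(table(ex$id) == 2))
  expect_equal(two_exon, "tx03A")
  widths <- sum(ex$end[ex$id == two_exon] - ex$start[ex$id == two_exon])
  expect_equal(nchar(ann$transcripts$seq[[two_exon]]), widths)
})

test_that("a planted trans bubble is reported by hybridization at its length", {
  ann <- make_synthetic_annotation(1, orientation_mix = "trans",
                                   overlap_len_range = c(120, 120),
                                   seed = 95, trans_mismatches = 0,
                                   trans_bubble_len = 8)
  t <- ann$truth
  regionA <- substr(ann$transcripts$seq[["tx01A"]], t$ovA_start + 1, t$ovA_end)
  regionB <- substr(ann$transcripts$seq[["tx01B"]], t$ovB_start + 1, t$ovB_end)
  d <- hybridize(regionA, regionB)
  expect_equal(nrow(d$interior_runs), 1L)
  expect_equal(d$interior_runs$length, 8L)
})

test_that("simulated reads come from where they claim to come from", {
  ann <- make_synthetic_annotation(3, overlap_len_range = c(140, 220),
                                   seed = 96, n_decoys = 4)
  sim <- simulate_reads(ann, 200, from_overlap_fraction = 0.6, seed = 97)
  expect_equal(sum(sim$reads$abundance), 200L)
  seqs <- ann$transcripts$seq
  for (i in seq_len(nrow(sim$truth))) {
    r <- sim$truth[i, ]
    expect_identical(substr(seqs[[r$transcript]], r$start + 1, r$end),
                     r$sequence)
  }
  # positives lie inside their pair's overlap, negatives outside every one
  tr <- ann$truth
  pos <- sim$truth[sim$truth$positive, ]
  for (i in seq_len(nrow(pos))) {
    t <- tr[tr$pair_idx == pos$pair_idx[i], ]
    iv <- if (pos$transcript[i] == t$transcriptA)
      c(t$ovA_start, t$ovA_end) else c(t$ovB_start, t$ovB_end)
    expect_true(pos$start[i] >= iv[1] && pos$end[i] <= iv[2])
  }
  neg <- sim$truth[!sim$truth$positive, ]
  for (i in seq_len(nrow(neg))) {
    hitA <- tr[tr$transcriptA == neg$transcript[i], ]
    hitB <- tr[tr$transcriptB == neg$transcript[i], ]
    iv <- rbind(if (nrow(hitA)) cbind(hitA$ovA_start, hitA$ovA_end),
                if (nrow(hitB)) cbind(hitB$ovB_start, hitB$ovB_end))
    if (!is.null(iv) && nrow(iv))
      expect_true(all(neg$end[i] <= iv[, 1] | neg$start[i] >= iv[, 2]))
  }
  # empty library and determinism contracts
  expect_equal(sum(simulate_reads(ann, 0, seed = 1)$reads$abundance), 0L)
  s1 <- simulate_reads(ann, 50, seed = 98)
  s2 <- simulate_reads(ann, 50, seed = 98)
  expect_identical(s1$reads, s2$reads)
})

test_that("degradome simulation plants tags at the 3'-adjacent position", {
  ann <- make_synthetic_annotation(2, orientation_mix = "full_overlap",
                                   overlap_len_range = c(150, 150), seed = 99)
  pd <- plant_duplex_reads(ann, group_plan = c(1L, 2L), seed = 100)
  deg <- simulate_degradome(ann, pd$truth[pd$truth$tag_plan, ], 1, seed = 101)
  expect_equal(nrow(deg$truth), sum(pd$truth$tag_plan))
  m <- merge(deg$truth, pd$truth[pd$truth$tag_plan, ],
             by.x = c("transcript", "start"),
             by.y = c("transcript", "end"))
  expect_equal(nrow(m), nrow(deg$truth))
  # zero support fraction produces an empty library
  none <- simulate_degradome(ann, pd$truth, 0, seed = 102)
  expect_equal(nrow(none$reads), 0L)
})

test_that("infeasible fixture parameters are refused", {
  expect_error(make_synthetic_annotation(1, overlap_len_range = c(200, 100)),
               "infeasible")
  ann <- make_synthetic_annotation(1, overlap_len_range = c(120, 120),
                                   seed = 103)
  expect_error(simulate_reads(ann, 10, read_len = 150L, seed = 1),
               "exceeds")
})
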