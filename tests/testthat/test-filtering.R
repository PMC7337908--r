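test_that("low-complexity rule matches hand-counted compositions", {
  expect_true(is_low_complexity(strrep("A", 21)))            # mono 100%
  expect_true(is_low_complexity("AATAAGAAACAAATAAAGAAA"))    # 16/21 A > 75%
  expect_false(is_low_complexity("TCGGACCAGGCTTCATTCCCC"))   # all below
  expect_error(is_low_complexity("AC"), "shorter")
})

test_that("low-complexity rule equals the window-counting oracle", {
  set.seed(11)
  for (i in 1:300) {
    # mix plain random with composition-biased sequences to hit both sides
    s <- if (i %% 3 == 0) {
      paste(sample(c("A", "C", "G", "T"), 21, TRUE,
                   prob = c(0.6, 0.2, 0.1, 0.1)), collapse = "")
    } else if (i %% 3 == 1) {
      paste(sample(c("AT", "GC", "A"), 11, TRUE), collapse = "")
    } else rnd_dna(sample(19:24, 1))
    expect_equal(is_low_complexity(s), low_complexity_oracle(s), info = s)
  }
})

test_that("read filters apply ambiguity, length, abundance and genome rules", {
  reads <- data.frame(
    sequence = c("ACGTACGTACGTACGTAC",        # 18nt: too short
                 "ACGTACGTACGTACGTACGTACGTA", # 25nt: too long
                 "ACGTNCGTACGTACGTACGTA",     # ambiguous
                 strrep("A", 21),             # low complexity
                 "ACGTACGTTGCATGCATGCAT",     # clean, in genome
                 "TTGACCGTTAGCATAACGGTC"),    # clean, absent from genome
    abundance = c(5L, 5L, 5L, 5L, 2L, 2L), stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(c(chr = paste0(
    "GGGG", "ACGTACGTTGCATGCATGCAT", "GGGG")))
  out <- filter_reads(reads, nat_config(), genome = genome)
  expect_equal(out$reads$sequence, "ACGTACGTTGCATGCATGCAT")
  rep <- out$report
  expect_equal(rep$discarded_sequences[rep$filter == "ambiguity"], 1L)
  expect_equal(rep$discarded_sequences[rep$filter == "length"], 2L)
  expect_equal(rep$discarded_sequences[rep$filter == "low_complexity"], 1L)
  expect_equal(rep$discarded_sequences[rep$filter == "genome_presence"], 1L)
  # retained + discarded = input, per stage
  expect_equal(sum(rep$discarded_sequences) + nrow(out$reads), nrow(reads))
  # genome filter off retains the unmapped read
  out2 <- filter_reads(reads, nat_config(genome_alignment = FALSE),
                       genome = genome)
  expect_true("TTGACCGTTAGCATAACGGTC" %in% out2$reads$sequence)
  # genome filter finds reverse-strand presence
  grc <- Biostrings::DNAStringSet(c(chr = as.character(
    Biostrings::reverseComplement(genome[[1]]))))
  out3 <- filter_reads(reads, nat_config(), genome = grc)
  expect_true("ACGTACGTTGCATGCATGCAT" %in% out3$reads$sequence)
})

test_that("filters are contractive and idempotent", {
  set.seed(21)
  reads <- data.frame(sequence = vapply(1:60, function(i)
    rnd_dna(sample(17:26, 1)), character(1)),
    abundance = sample(1:5, 60, TRUE), stringsAsFactors = FALSE)
  reads <- reads[!duplicated(reads$sequence), ]
  once <- filter_reads(reads, nat_config())$reads
  expect_true(all(once$sequence %in% reads$sequence))
  twice <- filter_reads(once, nat_config())$reads
  expect_equal(twice, once)
})

test_that("blacklist matching honours the mismatch bound and equals a Hamming scan", {
  bl <- c("ACGTACGTACGTACGTACGTA", "TTTTGCGCAATTGCGCAAAAA")
  exact <- data.frame(sequence = "ACGTACGTACGTACGTACGTA", abundance = 1L,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(blacklist_filter(exact, bl)), 0L)
  three_mm <- data.frame(sequence = "TCGTACGTACCTACGTACGTC", abundance = 1L,
                         stringsAsFactors = FALSE)
  expect_equal(nrow(blacklist_filter(three_mm, bl, max_mismatches = 2)), 1L)
  expect_equal(nrow(blacklist_filter(three_mm, bl, max_mismatches = 3)), 0L)

  set.seed(31)
  blacklist <- vapply(1:5, function(i) rnd_dna(30), character(1))
  reads <- data.frame(sequence = c(
    vapply(1:30, function(i) rnd_dna(21), character(1)),
    # near-copies of blacklist windows with 0-3 substitutions
    vapply(1:30, function(i) {
      w <- strsplit(substr(sample(blacklist, 1), 5, 25), "", fixed = TRUE)[[1]]
      k <- sample(0:3, 1)
      if (k > 0) {
        at <- sample(21, k)
        w[at] <- vapply(w[at], function(ch)
          sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
      }
      paste(w, collapse = "")
    }, character(1))), abundance = 1L, stringsAsFactors = FALSE)
  reads <- reads[!duplicated(reads$sequence), ]
  kept <- blacklist_filter(reads, blacklist, max_mismatches = 2)
  oracle_kept <- reads[!vapply(reads$sequence, hamming_blacklist_hit,
                               logical(1), blacklist, 2), ]
  expect_equal(sort(kept$sequence), sort(oracle_kept$sequence))
})

test_that("replicate conservation keeps sequences in enough libraries", {
  lib <- function(...) data.frame(sequence = c(...), abundance = 1L,
                                  stringsAsFactors = FALSE)
  libs <- list(lib("AAA", "CCC"), lib("AAA", "GGG"), lib("TTT"))
  expect_equal(conserve_across_replicates(libs, 2), "AAA")
  expect_setequal(conserve_across_replicates(libs, 1),
                  c("AAA", "CCC", "GGG", "TTT"))
  expect_error(conserve_across_replicates(libs, 4), "exceeds")
})
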