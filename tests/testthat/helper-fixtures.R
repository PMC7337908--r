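# small in-code fixtures shared across test files

# a minimal transcript set: B's middle is the reverse complement of A's
# middle, giving a perfect overlap. The three flank positions adjacent to
# the block on B are forced non-complementary to A's counterparts so the
# alignment terminates exactly at the planted block.
make_perfect_pair <- function(overlap_len = 150L, flankA = 60L, flankB = 80L,
                              seed = 1L) {
  set.seed(seed)
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  block <- rnd_dna(overlap_len)
  fa1 <- strsplit(rnd_dna(flankA), "", fixed = TRUE)[[1]]
  fa2 <- strsplit(rnd_dna(flankA), "", fixed = TRUE)[[1]]
  fb1 <- strsplit(rnd_dna(flankB), "", fixed = TRUE)[[1]]
  fb2 <- strsplit(rnd_dna(flankB), "", fixed = TRUE)[[1]]
  for (t in 0:2) {
    fb1[flankB - t] <- setdiff(c("A", "C", "G", "T"),
                               comp1(fa2[t + 1L]))[1]
    fb2[t + 1L] <- setdiff(c("A", "C", "G", "T"),
                           comp1(fa1[flankA - t]))[1]
  }
  a <- paste0(paste(fa1, collapse = ""), block, paste(fa2, collapse = ""))
  b <- paste0(paste(fb1, collapse = ""), natsir::revcomp(block),
              paste(fb2, collapse = ""))
  natsir:::new_nat_transcripts(
    c(txA = a, txB = b),
    info = data.frame(id = c("txA", "txB"), chromosome = NA_character_,
                      strand = NA_character_, gstart = NA_integer_,
                      gend = NA_integer_, source = "fasta",
                      stringsAsFactors = FALSE))
}

# write a tiny genome + GFF3 with two transcripts (one minus-strand,
# one two-exon) and return the paths plus expected sequences
write_mini_annotation <- function(dir) {
  set.seed(4)
  c1 <- rnd_dna(120)
  genome_path <- file.path(dir, "mini_genome.fa")
  writeLines(c(">c1", c1), genome_path)
  gff_path <- file.path(dir, "mini.gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tmRNA\t11\t40\t.\t+\t.\tID=t.plus",
    "c1\ttest\texon\t11\t20\t.\t+\t.\tParent=t.plus",
    "c1\ttest\texon\t31\t40\t.\t+\t.\tParent=t.plus",
    "c1\ttest\tmRNA\t11\t40\t.\t-\t.\tID=t.minus",
    "c1\ttest\texon\t11\t20\t.\t-\t.\tParent=t.minus",
    "c1\ttest\texon\t31\t40\t.\t-\t.\tParent=t.minus",
    "c1\ttest\tmRNA\t51\t80\t.\t+\t.\tID=t.iso2",
    "c1\ttest\texon\t51\t80\t.\t+\t.\tParent=t.iso2"),
    gff_path)
  concat <- paste0(substr(c1, 11, 20), substr(c1, 31, 40))
  list(genome = genome_path, gff3 = gff_path,
       expected = c(t.plus = concat,
                    t.minus = natsir::revcomp(concat),
                    t.iso2 = substr(c1, 51, 80)))
}

# alignment rows helper
aln_rows <- function(tx, starts, lens, seqs = NULL, abundance = 1L) {
  n <- length(starts)
  data.frame(sequence = seqs %||% sprintf("S%02d", seq_len(n)),
             abundance = rep_len(abundance, n),
             transcript = rep_len(tx, n),
             start = starts, end = starts + rep_len(lens, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
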