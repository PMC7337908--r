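#' Generate a synthetic genome and annotation with planted NAT loci
#'
#' Builds random-sequence chromosomes hosting non-overlapping NAT loci with
#' exactly known ground truth, plus decoy transcripts, and emits a genome
#' FASTA, a GFF3 annotation and a truth table. cis pairs are constructed as
#' two opposite-strand transcripts of one chromosome whose spans intersect
#' over the requested overlap length, so the spliced sequences are perfectly
#' complementary over the overlap by construction; the three genomic
#' arrangements (head-to-head, tail-to-tail, full overlap) are all
#' supported. trans pairs place the two transcripts on different
#' chromosomes, embedding a mutated reverse complement of one transcript's
#' source region into the other, with a configurable number of mismatches
#' and an optional non-complementary insert (bubble). Some cis loci carry a
#' multi-exon plus-strand transcript (the intron always lies outside the
#' overlap). Decoy transcripts and all non-overlap segments are
#' rejection-sampled so they share no 21-mer with any overlap region on
#' either strand, keeping negative reads clean.
#'
#' @param n_pairs number of NAT pairs to plant.
#' @param orientation_mix character vector recycled over pairs; each element
#'   one of `"tail_to_tail"`, `"head_to_head"`, `"full_overlap"`, `"trans"`.
#' @param overlap_len_range inclusive range the overlap lengths are drawn
#'   from.
#' @param seed integer seed; all outputs are reproducible bit-exactly from
#'   the parameters and seed.
#' @param n_decoys number of decoy single transcripts.
#' @param flank_len_range range of flank lengths around overlaps.
#' @param decoy_len_range range of decoy transcript lengths.
#' @param multi_exon_every every k-th cis pair gets a two-exon plus-strand
#'   transcript (0 disables).
#' @param trans_mismatches substitutions planted in each trans overlap.
#' @param trans_bubble_len length of the non-complementary insert planted in
#'   each trans overlap (0 disables).
#' @param gc GC content of the random background.
#' @param out_dir directory to write `genome.fa`, `annotation.gff3` and
#'   `truth.csv` into; `NULL` keeps everything in memory.
#' @return a list of class `nat_annotation`: `genome` (named character
#'   vector of chromosomes), `transcripts` (a `nat_transcripts` built
#'   directly from the construction), `truth` (data.frame with one row per
#'   pair: ids, class, orientation, overlap intervals in 0-based half-open
#'   transcript coordinates on each transcript, overlap and bubble lengths)
#'   and, when `out_dir` is given, `paths`.
#' @export
make_synthetic_annotation <- function(n_pairs,
                                      orientation_mix = c("tail_to_tail",
                                                          "head_to_head",
                                                          "full_overlap"),
                                      overlap_len_range = c(120L, 300L),
                                      seed = 1L,
                                      n_decoys = 0L,
                                      flank_len_range = c(80L, 200L),
                                      decoy_len_range = c(300L, 700L),
                                      multi_exon_every = 3L,
                                      trans_mismatches = 2L,
                                      trans_bubble_len = 0L,
                                      gc = 0.5,
                                      out_dir = NULL) {
  stopifnot(n_pairs >= 1L, overlap_len_range[1] >= 30L,
            flank_len_range[1] >= 60L)
  if (overlap_len_range[1] > overlap_len_range[2])
    stop("infeasible overlap length range")
  set.seed(seed)
  orientations <- rep_len(orientation_mix, n_pairs)
  forbidden <- new.env(parent = emptyenv())

  genome <- character(0)
  tx_seq <- character(0)
  tx_info <- list(); tx_exons <- list(); gff <- list(); truth <- list()
  pad <- 30L

  add_tx <- function(id, chrom, strand, exons_gstart, exons_gend, seq) {
    tx_seq[[id]] <<- seq
    tx_info[[length(tx_info) + 1L]] <<- data.frame(
      id = id, chromosome = chrom, strand = strand,
      gstart = min(exons_gstart), gend = max(exons_gend), source = "gff3",
      stringsAsFactors = FALSE)
    tx_exons[[length(tx_exons) + 1L]] <<- data.frame(
      id = id, start = exons_gstart, end = exons_gend,
      stringsAsFactors = FALSE)
    gff[[length(gff) + 1L]] <<- data.frame(
      chrom = chrom, start = c(min(exons_gstart), exons_gstart),
      end = c(max(exons_gend), exons_gend), strand = strand,
      type = c("mRNA", rep("exon", length(exons_gstart))),
      ID = c(id, paste0(id, ".exon", seq_along(exons_gstart))),
      Parent = c(NA_character_, rep(id, length(exons_gstart))),
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_pairs)) {
    ori <- orientations[i]
    L <- sample_range(overlap_len_range)
    fa <- sample_range(flank_len_range)
    fb <- sample_range(flank_len_range)
    idA <- sprintf("tx%02dA", i); idB <- sprintf("tx%02dB", i)

    if (ori == "trans") {
      tp <- build_trans_locus(L, fa, fb, gc, forbidden,
                              trans_mismatches, trans_bubble_len, pad)
      chromA <- sprintf("chr%02da", i); chromB <- sprintf("chr%02db", i)
      genome[[chromA]] <- tp$chromA; genome[[chromB]] <- tp$chromB
      add_tx(idA, chromA, "+", pad, pad + nchar(tp$seqA), tp$seqA)
      add_tx(idB, chromB, "+", pad, pad + nchar(tp$seqB), tp$seqB)
      truth[[i]] <- data.frame(
        pair_idx = i, transcriptA = idA, transcriptB = idB,
        class = "trans", orientation = "trans",
        ovA_start = tp$ovA[1], ovA_end = tp$ovA[2],
        ovB_start = tp$ovB[1], ovB_end = tp$ovB[2],
        overlap_len = L + trans_bubble_len,
        bubble_len = trans_bubble_len, stringsAsFactors = FALSE)
      next
    }

    multi <- multi_exon_every > 0L && i %% multi_exon_every == 0L
    il <- if (multi) 40L else 0L
    fa1 <- if (multi) fa %/% 2L else fa
    fa2 <- fa - fa1
    ov <- rand_segment(L, gc, forbidden, register = TRUE)
    chrom <- sprintf("chr%02d", i)

    if (ori == "tail_to_tail") {
      # [pad | P flank (fa1|intron|fa2) | overlap | M flank | pad]
      segs <- c(rand_segment(pad, gc, forbidden),
                rand_segment(fa1, gc, forbidden),
                if (multi) rand_segment(il, gc, forbidden) else character(0),
                rand_segment(fa2, gc, forbidden),
                ov,
                rand_segment(fb, gc, forbidden),
                rand_segment(pad, gc, forbidden))
      chrom_seq <- paste(segs, collapse = "")
      ovg <- pad + fa + il
      p_exons <- if (multi)
        list(s = c(pad, pad + fa1 + il), e = c(pad + fa1, ovg + L))
      else list(s = pad, e = ovg + L)
      m_span <- c(ovg, ovg + L + fb)
      seqP <- splice(chrom_seq, p_exons$s, p_exons$e, "+")
      seqM <- splice(chrom_seq, m_span[1], m_span[2], "-")
      ovA <- c(fa, fa + L); ovB <- c(fb, fb + L)
    } else if (ori == "head_to_head") {
      # [pad | M flank | overlap | P flank (fa1|intron|fa2) | pad]
      segs <- c(rand_segment(pad, gc, forbidden),
                rand_segment(fb, gc, forbidden),
                ov,
                rand_segment(fa1, gc, forbidden),
                if (multi) rand_segment(il, gc, forbidden) else character(0),
                rand_segment(fa2, gc, forbidden),
                rand_segment(pad, gc, forbidden))
      chrom_seq <- paste(segs, collapse = "")
      ovg <- pad + fb
      p_exons <- if (multi)
        list(s = c(ovg, ovg + L + fa1 + il), e = c(ovg + L + fa1, ovg + L + fa + il))
      else list(s = ovg, e = ovg + L + fa)
      m_span <- c(pad, ovg + L)
      seqP <- splice(chrom_seq, p_exons$s, p_exons$e, "+")
      seqM <- splice(chrom_seq, m_span[1], m_span[2], "-")
      ovA <- c(0L, L); ovB <- c(0L, L)
    } else if (ori == "full_overlap") {
      # [pad | P left flank (fa1|intron|fa2) | overlap (= M) | P right | pad]
      segs <- c(rand_segment(pad, gc, forbidden),
                rand_segment(fa1, gc, forbidden),
                if (multi) rand_segment(il, gc, forbidden) else character(0),
                rand_segment(fa2, gc, forbidden),
                ov,
                rand_segment(fb, gc, forbidden),
                rand_segment(pad, gc, forbidden))
      chrom_seq <- paste(segs, collapse = "")
      ovg <- pad + fa + il
      p_exons <- if (multi)
        list(s = c(pad, pad + fa1 + il), e = c(pad + fa1, ovg + L + fb))
      else list(s = pad, e = ovg + L + fb)
      m_span <- c(ovg, ovg + L)
      seqP <- splice(chrom_seq, p_exons$s, p_exons$e, "+")
      seqM <- splice(chrom_seq, m_span[1], m_span[2], "-")
      ovA <- c(fa, fa + L); ovB <- c(0L, L)
    } else stop("unknown orientation: ", ori)

    genome[[chrom]] <- chrom_seq
    # A = plus-strand transcript, B = minus-strand partner
    add_tx(idA, chrom, "+", p_exons$s, p_exons$e, seqP)
    add_tx(idB, chrom, "-", m_span[1], m_span[2], seqM)
    truth[[i]] <- data.frame(
      pair_idx = i, transcriptA = idA, transcriptB = idB,
      class = "cis", orientation = ori,
      ovA_start = ovA[1], ovA_end = ovA[2],
      ovB_start = ovB[1], ovB_end = ovB[2],
      overlap_len = L, bubble_len = 0L, stringsAsFactors = FALSE)
  }

  for (d in seq_len(n_decoys)) {
    dl <- sample_range(decoy_len_range)
    dseq <- rand_segment(dl, gc, forbidden)
    chrom <- sprintf("chrd%02d", d)
    id <- sprintf("decoy%02d", d)
    genome[[chrom]] <- paste0(rand_segment(pad, gc, forbidden), dseq,
                              rand_segment(pad, gc, forbidden))
    add_tx(id, chrom, "+", pad, pad + dl, dseq)
  }

  transcripts <- new_nat_transcripts(unlist(tx_seq),
                                     info = do.call(rbind, tx_info),
                                     exons = do.call(rbind, tx_exons))
  ann <- structure(list(genome = genome, transcripts = transcripts,
                        truth = do.call(rbind, truth),
                        gff = do.call(rbind, gff)),
                   class = "nat_annotation")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(genome = file.path(out_dir, "genome.fa"),
               gff3 = file.path(out_dir, "annotation.gff3"),
               truth = file.path(out_dir, "truth.csv"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                                paths[["genome"]])
    write_gff3(ann$gff, genome, paths[["gff3"]])
    write.csv(ann$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
    ann$paths <- paths
  }
  ann
}

sample_range <- function(r) if (r[1] == r[2]) as.integer(r[1]) else
  sample(r[1]:r[2], 1L)

# random DNA avoiding 21-mers already registered as overlap content
rand_segment <- function(n, gc, forbidden, register = FALSE, max_tries = 100L) {
  if (n <= 0L) return(character(0))
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  for (tries in seq_len(max_tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = probs),
               collapse = "")
    if (n < 21L || !any_kmer_hit(s, forbidden)) {
      if (register) register_kmers(s, forbidden)
      return(s)
    }
  }
  stop("could not sample a clean segment; loosen the fixture parameters")
}

kmers21 <- function(s) {
  L <- nchar(s)
  if (L < 21L) return(character(0))
  substring(s, 1:(L - 20L), 21:L)
}

register_kmers <- function(s, env) {
  for (k in c(kmers21(s), kmers21(revcomp(s)))) assign(k, TRUE, envir = env)
  invisible(NULL)
}

any_kmer_hit <- function(s, env) {
  any(vapply(c(kmers21(s), kmers21(revcomp(s))),
             exists, logical(1), envir = env, inherits = FALSE))
}

# spliced transcript sequence from genomic exon coordinates (0-based)
splice <- function(chrom_seq, starts, ends, strand) {
  parts <- substring(chrom_seq, starts + 1L, ends)
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# trans locus: transcript B embeds a mutated reverse complement of a region
# of transcript A; boundaries are sealed (3 non-complementary positions) so
# the complementarity alignment terminates exactly at the planted region
build_trans_locus <- function(L, fa, fb, gc, forbidden,
                              n_mismatches, bubble_len, pad) {
  source <- rand_segment(L, gc, forbidden, register = TRUE)
  src <- strsplit(source, "", fixed = TRUE)[[1]]
  center <- L %/% 2L
  if (bubble_len > 0L) {
    # keep an A/C-only window around the insertion point so inserted A/C
    # bases cannot pair (no Watson-Crick or G:U partner present)
    win <- seq2(max(1L, center - 5L), min(L, center + 5L))
    src[win] <- sample(c("A", "C"), length(win), TRUE)
    source <- paste(src, collapse = "")
  }
  embed <- strsplit(revcomp(paste(src, collapse = "")), "", fixed = TRUE)[[1]]
  if (n_mismatches > 0L) {
    pos <- unique(round(seq(10L, L - 10L, length.out = n_mismatches)))
    pos <- pos[abs(pos - (L - center)) > 8L]  # stay clear of the bubble site
    for (p in pos) {
      a_partner <- src[L - p + 1L]             # the base this column pairs with
      banned <- c(embed[p], comp_base(a_partner),
                  if (a_partner == "G") "T", if (a_partner == "T") "G")
      embed[p] <- sample(setdiff(c("A", "C", "G", "T"), banned), 1L)
    }
  }
  if (bubble_len > 0L) {
    at <- L - center
    insert <- sample(c("A", "C"), bubble_len, TRUE)
    embed <- append(embed, insert, after = at)
  }
  embed_seq <- paste(embed, collapse = "")
  register_kmers(embed_seq, forbidden)

  fa2 <- sample_range(c(60L, 120L))  # A's right flank
  fc <- sample_range(c(60L, 120L)); fd <- sample_range(c(60L, 120L))
  aflank1 <- rand_segment(fa, gc, forbidden)
  aflank2 <- rand_segment(fa2, gc, forbidden)
  bflank1 <- strsplit(rand_segment(fc, gc, forbidden), "", fixed = TRUE)[[1]]
  bflank2 <- strsplit(rand_segment(fd, gc, forbidden), "", fixed = TRUE)[[1]]
  # seal: B bases adjacent to the embed must not complement A's flank bases
  a2 <- strsplit(aflank2, "", fixed = TRUE)[[1]]
  a1 <- strsplit(aflank1, "", fixed = TRUE)[[1]]
  for (t in 0:2) {
    if (bflank1[fc - t] == comp_base(a2[t + 1L]))
      bflank1[fc - t] <- setdiff(c("A", "C", "G", "T"),
                                 c(comp_base(a2[t + 1L]), bflank1[fc - t]))[1]
    if (bflank2[t + 1L] == comp_base(a1[fa - t]))
      bflank2[t + 1L] <- setdiff(c("A", "C", "G", "T"),
                                 c(comp_base(a1[fa - t]), bflank2[t + 1L]))[1]
  }
  seqA <- paste0(aflank1, source, aflank2)
  seqB <- paste0(paste(bflank1, collapse = ""), embed_seq,
                 paste(bflank2, collapse = ""))
  list(chromA = paste0(rand_segment(pad, gc, forbidden), seqA,
                       rand_segment(pad, gc, forbidden)),
       chromB = paste0(rand_segment(pad, gc, forbidden), seqB,
                       rand_segment(pad, gc, forbidden)),
       seqA = seqA, seqB = seqB,
       ovA = c(fa, fa + L),
       ovB = c(fc, fc + L + bubble_len))
}

# GFF3 writer over the construction table (1-based inclusive on disk)
write_gff3 <- function(gff_df, genome, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gff_df$chrom,
    ranges = IRanges::IRanges(start = gff_df$start + 1L, end = gff_df$end),
    strand = gff_df$strand)
  S4Vectors::mcols(gr)$type <- gff_df$type
  S4Vectors::mcols(gr)$ID <- gff_df$ID
  parent <- ifelse(is.na(gff_df$Parent), "", gff_df$Parent)
  S4Vectors::mcols(gr)$Parent <- S4Vectors::unname(
    IRanges::CharacterList(lapply(parent, function(p)
      if (nzchar(p)) p else character(0))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate an sRNA library from planted NAT loci
#'
#' Emulates the benchmark design: fixed-length reads (21nt by default)
#' sampled uniformly from the overlap regions of the planted pairs, drawn
#' from either transcript of a pair at random. The remaining fraction is
#' sampled as negatives from transcript regions whose footprint is disjoint
#' from every overlap (including decoy transcripts). Low-complexity
#' positions are resampled so every simulated read survives the standard
#' input filters.
#'
#' @param ann a `nat_annotation`.
#' @param n_reads total number of redundant reads.
#' @param read_len read length.
#' @param from_overlap_fraction fraction of reads drawn from overlap regions.
#' @param seed integer seed.
#' @param out_file optional path for a redundant FASTA.
#' @return list with `reads` (collapsed data.frame `sequence`, `abundance`),
#'   `truth` (one row per redundant read: `sequence`, `transcript`, `start`,
#'   `end`, `pair_idx`, `positive`), and `path` when written.
#' @export
simulate_reads <- function(ann, n_reads, read_len = 21L,
                           from_overlap_fraction = 1, seed = 1L,
                           out_file = NULL) {
  set.seed(seed)
  truth_tab <- ann$truth
  seqs <- ann$transcripts$seq
  n_pos <- round(n_reads * from_overlap_fraction)
  n_neg <- n_reads - n_pos

  rows <- list()
  draw_read <- function(tx, lo, hi, pair_idx, positive) {
    # position sampled in [lo, hi]; low-complexity draws are rejected
    for (tries in 1:50) {
      s <- if (hi > lo) sample(lo:hi, 1L) else lo
      sq <- substr(seqs[[tx]], s + 1L, s + read_len)
      if (!is_low_complexity(sq))
        return(data.frame(sequence = sq, transcript = tx, start = s,
                          end = s + read_len, pair_idx = pair_idx,
                          positive = positive, stringsAsFactors = FALSE))
    }
    stop("could not draw a read free of low-complexity content")
  }

  if (n_pos > 0L) {
    if (any(truth_tab$ovA_end - truth_tab$ovA_start < read_len))
      stop("read length exceeds a planted overlap length")
    for (k in seq_len(n_pos)) {
      i <- sample(nrow(truth_tab), 1L)
      side <- sample(c("A", "B"), 1L)
      tx <- if (side == "A") truth_tab$transcriptA[i] else truth_tab$transcriptB[i]
      lo <- if (side == "A") truth_tab$ovA_start[i] else truth_tab$ovB_start[i]
      hi <- (if (side == "A") truth_tab$ovA_end[i] else truth_tab$ovB_end[i]) -
        read_len
      rows[[length(rows) + 1L]] <- draw_read(tx, lo, hi, truth_tab$pair_idx[i],
                                             TRUE)
    }
  }

  if (n_neg > 0L) {
    elig <- negative_windows(ann, read_len)
    if (nrow(elig) == 0L) stop("no transcript region available for negatives")
    w <- (elig$hi - elig$lo + 1L)
    for (k in seq_len(n_neg)) {
      i <- sample(nrow(elig), 1L, prob = w)
      rows[[length(rows) + 1L]] <- draw_read(elig$transcript[i], elig$lo[i],
                                             elig$hi[i], NA_integer_, FALSE)
    }
  }

  if (length(rows) == 0L) {
    truth <- data.frame(sequence = character(0), transcript = character(0),
                        start = integer(0), end = integer(0),
                        pair_idx = integer(0), positive = logical(0),
                        stringsAsFactors = FALSE)
    reads <- data.frame(sequence = character(0), abundance = integer(0),
                        stringsAsFactors = FALSE)
  } else {
    truth <- do.call(rbind, rows)
    ab <- vapply(split(seq_len(nrow(truth)), truth$sequence), length,
                 numeric(1))
    reads <- data.frame(sequence = names(ab), abundance = as.integer(ab),
                        stringsAsFactors = FALSE)
    reads <- reads[order(reads$sequence), , drop = FALSE]
  }
  rownames(reads) <- NULL
  out <- list(reads = reads, truth = truth)
  if (!is.null(out_file)) {
    write_redundant_fasta(reads, out_file)
    out$path <- out_file
  }
  out
}

# start-position windows [lo, hi] whose read footprints avoid every overlap
negative_windows <- function(ann, read_len) {
  seqs <- ann$transcripts$seq
  truth <- ann$truth
  rows <- list()
  for (tx in names(seqs)) {
    len <- nchar(seqs[[tx]])
    if (len < read_len) next
    ia <- truth[truth$transcriptA == tx, , drop = FALSE]
    ib <- truth[truth$transcriptB == tx, , drop = FALSE]
    ov <- rbind(data.frame(s = ia$ovA_start, e = ia$ovA_end),
                data.frame(s = ib$ovB_start, e = ib$ovB_end))
    if (nrow(ov) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(transcript = tx, lo = 0L,
                                              hi = len - read_len)
      next
    }
    # footprint [p, p+read_len) must be disjoint from every overlap
    ivs <- ov[order(ov$s), , drop = FALSE]
    segs <- list()
    cur <- 0L
    for (j in seq_len(nrow(ivs))) {
      if (ivs$s[j] > cur) segs[[length(segs) + 1L]] <- c(cur, ivs$s[j])
      cur <- max(cur, ivs$e[j])
    }
    if (cur < len) segs[[length(segs) + 1L]] <- c(cur, len)
    for (sg in segs) {
      hi <- sg[2] - read_len
      if (hi >= sg[1])
        rows[[length(rows) + 1L]] <- data.frame(transcript = tx, lo = sg[1],
                                                hi = hi)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(transcript = character(0), lo = integer(0),
                      hi = integer(0)))
  do.call(rbind, rows)
}

#' Plant mature/star duplexes with per-pair biogenesis-group truth
#'
#' For each pair an sRNA duplex is planted: a mature read on transcript A
#' and, for groups 1-3, its star partner on transcript B at the configured
#' overhang offset. The returned truth carries the expected group for every
#' resulting call on both transcripts (the star read, investigated from its
#' own transcript, is itself a mature with the planted read as star: a
#' group-1 duplex yields two group-1 calls, a group-2 duplex yields a
#' group-2 and a group-3 call). `tag_plan` marks the reads whose 3'-adjacent
#' degradome tag must be planted to realize the plan.
#'
#' @param ann a `nat_annotation`.
#' @param group_plan integer vector of target groups (1-5), recycled over
#'   pairs.
#' @param read_len read length.
#' @param seed integer seed.
#' @param overhang an [overhang_config()].
#' @return list with `reads` (collapsed), `truth` (per planted read:
#'   `sequence`, `transcript`, `start`, `end`, `pair_idx`, `role`,
#'   `expected_group`, `tag_plan`).
#' @export
plant_duplex_reads <- function(ann, group_plan, read_len = 21L, seed = 1L,
                               overhang = overhang_config()) {
  set.seed(seed)
  truth_tab <- ann$truth
  seqs <- ann$transcripts$seq
  plan <- rep_len(as.integer(group_plan), nrow(truth_tab))
  o <- if (overhang$end == "five_prime") overhang$offset else -overhang$offset
  rows <- list()
  for (i in seq_len(nrow(truth_tab))) {
    g <- plan[i]
    txA <- truth_tab$transcriptA[i]; txB <- truth_tab$transcriptB[i]
    oaS <- truth_tab$ovA_start[i]; oaE <- truth_tab$ovA_end[i]
    obS <- truth_tab$ovB_start[i]; obE <- truth_tab$ovB_end[i]
    lenA <- nchar(seqs[[txA]]); lenB <- nchar(seqs[[txB]])
    need_star <- g <= 3L
    need_tag_m <- g %in% c(1L, 2L, 4L)
    need_tag_s <- g == 1L
    placed <- FALSE
    for (tries in 1:200) {
      lo <- oaS + max(0L, -o); hi <- oaE - read_len - max(0L, o)
      if (hi < lo) break
      s <- if (hi > lo) sample(lo:hi, 1L) else lo
      e <- s + read_len
      bs <- oaS + obE - (e + o); be <- oaS + obE - (s + o)
      if (need_star && (bs < 0L || be > lenB)) next
      if (need_tag_m && e + 20L > lenA) next
      if (need_tag_s && need_star && be + 20L > lenB) next
      mature <- substr(seqs[[txA]], s + 1L, e)
      if (is_low_complexity(mature)) next
      star <- if (need_star) substr(seqs[[txB]], bs + 1L, be) else NULL
      if (need_star && is_low_complexity(star)) next
      exp_mature <- g
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = mature, transcript = txA, start = s, end = e,
        pair_idx = truth_tab$pair_idx[i], role = "mature",
        expected_group = exp_mature, tag_plan = need_tag_m,
        stringsAsFactors = FALSE)
      if (need_star) {
        exp_star <- if (g == 1L) 1L else 3L
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = star, transcript = txB, start = bs, end = be,
          pair_idx = truth_tab$pair_idx[i], role = "star",
          expected_group = exp_star, tag_plan = need_tag_s,
          stringsAsFactors = FALSE)
      }
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place a duplex for pair ", i,
                      " under the requested plan")
  }
  truth <- do.call(rbind, rows)
  ab <- vapply(split(seq_len(nrow(truth)), truth$sequence), length, numeric(1))
  reads <- data.frame(sequence = names(ab), abundance = as.integer(ab),
                      stringsAsFactors = FALSE)
  reads <- reads[order(reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads, truth = truth)
}

#' Simulate a degradome library supporting planted reads
#'
#' For the chosen fraction of the given reads, a tag (20nt by default) whose
#' 5' end sits immediately after the read's 3' terminus is extracted from
#' the same transcript, realizing the adjacency the pipeline uses as
#' degradome support. Reads whose tag would run past the transcript end are
#' skipped.
#'
#' @param ann a `nat_annotation`.
#' @param read_truth data.frame with `transcript`, `end` (e.g. the `truth` of
#'   [simulate_reads()] or [plant_duplex_reads()], possibly subset).
#' @param support_fraction fraction of reads to support.
#' @param tag_len tag length (within the standard 19-21nt bounds).
#' @param seed integer seed.
#' @param out_file optional path for a redundant FASTA.
#' @return list with `reads` (collapsed tags), `truth` (tag placements), and
#'   `path` when written.
#' @export
simulate_degradome <- function(ann, read_truth, support_fraction = 1,
                               tag_len = 20L, seed = 1L, out_file = NULL) {
  set.seed(seed)
  seqs <- ann$transcripts$seq
  n <- nrow(read_truth)
  pick <- if (support_fraction >= 1) seq_len(n) else
    sort(sample(n, round(n * support_fraction)))
  rows <- list()
  for (i in pick) {
    tx <- read_truth$transcript[i]; at <- read_truth$end[i]
    if (at + tag_len > nchar(seqs[[tx]])) next
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = substr(seqs[[tx]], at + 1L, at + tag_len),
      transcript = tx, start = at, end = at + tag_len,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), transcript = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  if (nrow(truth)) {
    ab <- vapply(split(seq_len(nrow(truth)), truth$sequence), length,
                 numeric(1))
    reads <- data.frame(sequence = names(ab), abundance = as.integer(ab),
                        stringsAsFactors = FALSE)
    reads <- reads[order(reads$sequence), , drop = FALSE]
  } else reads <- data.frame(sequence = character(0), abundance = integer(0),
                             stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  out <- list(reads = reads, truth = truth)
  if (!is.null(out_file)) {
    write_redundant_fasta(reads, out_file)
    out$path <- out_file
  }
  out
}
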