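#' Read a redundant FASTA library of small RNA or degradome reads
#'
#' Reads an adapter-trimmed library in redundant FASTA format and collapses
#' identical sequences into distinct records with abundances. Sequences are
#' normalized (uppercase, U to T). With `collapse_header_counts = TRUE`,
#' records whose header ends in `-<int>` or `(<int>)` contribute that count
#' instead of 1, so already-collapsed libraries round-trip.
#'
#' @param path path to a FASTA file.
#' @param collapse_header_counts logical; parse abundances out of headers.
#' @return data.frame with columns `sequence` and `abundance`, one row per
#'   distinct sequence, ordered by sequence.
#' @export
read_redundant_fasta <- function(path, collapse_header_counts = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  check_fasta_syntax(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA library: ", path)
    return(data.frame(sequence = character(0), abundance = integer(0),
                      stringsAsFactors = FALSE))
  }
  seqs <- normalize_sequence(as.character(set))
  counts <- rep(1L, length(seqs))
  if (collapse_header_counts) {
    hdr <- names(set)
    m <- regmatches(hdr, regexec("[-(]([0-9]+)\\)?$", hdr))
    parsed <- vapply(m, function(g) if (length(g) == 2L) as.integer(g[2]) else NA_integer_,
                     integer(1))
    counts[!is.na(parsed)] <- parsed[!is.na(parsed)]
  }
  ab <- vapply(split(counts, seqs), sum, numeric(1))
  out <- data.frame(sequence = names(ab), abundance = as.integer(ab),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$sequence), , drop = FALSE]
}

# cheap structural validation so malformed files fail with a line number
check_fasta_syntax <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(invisible(TRUE))
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("malformed FASTA record at line ", nonblank[1], " of ", path,
         ": expected '>' header")
  headers <- which(startsWith(lines, ">"))
  nxt <- c(headers[-1], length(lines) + 1L)
  for (k in seq_along(headers)) {
    between <- lines[seq2(headers[k] + 1L, nxt[k] - 1L)]
    if (!any(nzchar(trimws(between))))
      stop("malformed FASTA record at line ", headers[k], " of ", path,
           ": header with no sequence")
  }
  invisible(TRUE)
}

#' Build a transcript set from a transcriptome FASTA
#'
#' @param path FASTA of spliced transcript sequences, 5' to 3'.
#' @return a `nat_transcripts` object (see [extract_transcripts()]).
#' @export
transcripts_from_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate transcript ids in ", path)
  seqs <- setNames(normalize_sequence(as.character(set)), ids)
  new_nat_transcripts(seqs,
                      info = data.frame(id = ids, chromosome = NA_character_,
                                        strand = NA_character_,
                                        gstart = NA_integer_, gend = NA_integer_,
                                        source = "fasta",
                                        stringsAsFactors = FALSE),
                      exons = NULL)
}

new_nat_transcripts <- function(seqs, info, exons = NULL) {
  stopifnot(all(nchar(seqs) >= 1L))
  structure(list(seq = seqs, info = info, exons = exons),
            class = "nat_transcripts")
}

#' @export
print.nat_transcripts <- function(x, ...) {
  cat("nat_transcripts: ", length(x$seq), " transcripts (",
      sum(!is.na(x$info$chromosome)), " with genomic origin)\n", sep = "")
  invisible(x)
}

#' @export
length.nat_transcripts <- function(x) length(x$seq)

#' Extract spliced transcripts from a GFF3 annotation and genome
#'
#' One transcript is produced per transcript-level feature (`mRNA`,
#' `transcript`, or any feature with `exon` children), keeping every splice
#' variant. Exons are concatenated in transcription order and minus-strand
#' transcripts are reverse complemented, so sequences are always 5' to 3'.
#' The genomic span is recorded for cis/trans classification and orientation.
#'
#' Internally all coordinates are 0-based half-open; the GFF3 file is parsed
#' as 1-based inclusive per its specification.
#'
#' @param gff3_path path to a GFF3 annotation.
#' @param genome_path path to the corresponding genome FASTA.
#' @return a `nat_transcripts` object: `seq` is a named character vector of
#'   transcript sequences; `info` is a data.frame (id, chromosome, strand,
#'   gstart, gend, source); `exons` a data.frame of per-transcript genomic
#'   exon intervals (id, start, end) in 0-based half-open coordinates.
#' @export
extract_transcripts <- function(gff3_path, genome_path) {
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  if (!file.exists(genome_path)) stop("genome FASTA not found: ", genome_path)
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- rtracklayer::import(gff3_path, format = "gff3")

  type <- as.character(gff$type)
  ids <- as.character(gff$ID)
  parents <- gff$Parent  # CharacterList
  parent1 <- vapply(as.list(parents), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  is_exon <- type == "exon"
  exon_parents <- unique(parent1[is_exon & !is.na(parent1)])
  is_tx <- (type %in% c("mRNA", "transcript") & !is.na(ids)) |
    (!is.na(ids) & ids %in% exon_parents)
  tx_idx <- which(is_tx)
  if (length(tx_idx) == 0L) stop("no transcript-level features in ", gff3_path)

  out_ids <- character(0); out_seqs <- character(0)
  info <- list(); exon_rows <- list()
  for (i in tx_idx) {
    tid <- ids[i]
    chrom <- as.character(GenomicRanges::seqnames(gff))[i]
    strand <- as.character(GenomicRanges::strand(gff))[i]
    if (!strand %in% c("+", "-"))
      stop("transcript ", tid, " has no usable strand")
    if (!chrom %in% names(genome))
      stop("chromosome ", chrom, " of transcript ", tid, " absent from genome")
    ex <- which(is_exon & parent1 == tid)
    if (length(ex) == 0L) {
      warning("transcript ", tid, " has no exon children; using feature span")
      ex <- i
    }
    es <- GenomicRanges::start(gff)[ex]; ee <- GenomicRanges::end(gff)[ex]
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    clen <- Biostrings::nchar(genome[[chrom]])
    if (any(es < 1L) || any(ee > clen))
      stop("exon coordinates of ", tid, " out of bounds on ", chrom)
    parts <- vapply(seq_along(es), function(k)
      as.character(Biostrings::subseq(genome[[chrom]], es[k], ee[k])),
      character(1))
    seq <- paste(parts, collapse = "")
    if (strand == "-") seq <- revcomp(seq)
    out_ids <- c(out_ids, tid)
    out_seqs <- c(out_seqs, normalize_sequence(seq))
    info[[length(info) + 1L]] <- data.frame(
      id = tid, chromosome = chrom, strand = strand,
      gstart = min(es) - 1L, gend = max(ee), source = "gff3",
      stringsAsFactors = FALSE)
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      id = tid, start = es - 1L, end = ee, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out_ids)) stop("duplicate transcript ids in ", gff3_path)
  new_nat_transcripts(setNames(out_seqs, out_ids),
                      info = do.call(rbind, info),
                      exons = do.call(rbind, exon_rows))
}

# map a genomic position to transcript coordinates (0-based), NA if intronic
genomic_to_transcript_pos <- function(gpos, exons, strand) {
  o <- order(exons$start)
  es <- exons$start[o]; ee <- exons$end[o]
  widths <- ee - es
  offs <- cumsum(c(0L, widths))[seq_along(widths)]
  k <- which(gpos >= es & gpos < ee)
  if (length(k) == 0L) return(NA_integer_)
  tpos_plus <- offs[k] + (gpos - es[k])
  if (strand == "+") tpos_plus else sum(widths) - 1L - tpos_plus
}

#' Write pipeline results to CSV files
#'
#' Produces `nat_pairs.csv`, `nat_sirnas.csv` and `profiles.csv` in
#' `out_dir`. Coordinates are written 1-based inclusive (internal
#' representation is 0-based half-open).
#'
#' @param results a result bundle as returned by [run_pipeline()], or any list
#'   with `pairs`, `calls` and `profiles` data.frames in internal coordinates.
#' @param out_dir output directory, created if missing.
#' @return invisibly, a named character vector of the three file paths.
#' @export
write_results_csv <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  pairs <- results$pairs
  calls <- results$calls
  profiles <- results$profiles

  p <- pairs
  for (col in c("overlap_startA", "overlap_startB"))
    if (nrow(p)) p[[col]] <- p[[col]] + 1L
  pair_cols <- c("pair_id", "transcriptA", "transcriptB", "class",
                 "orientation", "category", "overlap_startA", "overlap_endA",
                 "overlap_startB", "overlap_endB", "overlap_len",
                 "hybridization_checked", "density_overlap", "density_global",
                 "pattern")
  p <- p[, pair_cols, drop = FALSE]

  s <- calls
  if (nrow(s)) s$start <- s$start + 1L
  call_cols <- c("pair_id", "sequence", "abundance", "origin_transcript",
                 "start", "end", "group", "star_sequence",
                 "deg_support_mature", "deg_support_star", "multi_origin")
  s <- s[, call_cols, drop = FALSE]

  prof_cols <- c("pair_id", "transcript", "retained_clusters",
                 "pct_unique_in_clusters", "pattern")
  pr <- profiles[, prof_cols, drop = FALSE]

  paths <- c(nat_pairs = file.path(out_dir, "nat_pairs.csv"),
             nat_sirnas = file.path(out_dir, "nat_sirnas.csv"),
             profiles = file.path(out_dir, "profiles.csv"))
  write.csv(p, paths[["nat_pairs"]], row.names = FALSE, quote = FALSE)
  write.csv(s, paths[["nat_sirnas"]], row.names = FALSE, quote = FALSE)
  write.csv(pr, paths[["profiles"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write reads as a collapsed FASTA (`>seq<i>-<abundance>`)
#'
#' @param reads data.frame with `sequence` and `abundance`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_collapsed_fasta <- function(reads, path) {
  lines <- character(0)
  if (nrow(reads)) {
    lines <- as.vector(rbind(
      sprintf(">seq%d-%d", seq_len(nrow(reads)), reads$abundance),
      reads$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write reads as a redundant FASTA (one record per copy)
#'
#' @param reads data.frame with `sequence` and `abundance`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_redundant_fasta <- function(reads, path) {
  seqs <- rep(reads$sequence, reads$abundance)
  lines <- character(0)
  if (length(seqs)) {
    lines <- as.vector(rbind(sprintf(">read%d", seq_along(seqs)), seqs))
  }
  writeLines(lines, path)
  invisible(path)
}
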