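#' Pipeline configuration
#'
#' Collects the tunable parameters with their standard defaults: minimum
#' overlap (annealed region) length 100nt; minimum sRNA phases 1; sRNA
#' length bounds 19-24nt; minimum sRNA abundance 1; degradome tag length
#' bounds 19-21nt; cis-only search enabled; 80% coverage ratio between the
#' complementarity alignment and the annealed duplex; largest tolerated
#' bubble 10% of the alignment; low-complexity and genome-presence filters
#' enabled.
#'
#' @param min_overlap_length minimum length of the annealed region between
#'   NATs (alignment columns).
#' @param min_srna_phases minimum number of adjacent sRNA alignment phases.
#' @param min_srna_length,max_srna_length input sRNA length bounds.
#' @param min_srna_abundance minimum input sRNA abundance.
#' @param min_tag_length,max_tag_length degradome read length bounds.
#' @param cis_only only report NATs that are perfectly complementary or from
#'   the same genomic location.
#' @param coverage_ratio required overlap between the complementarity
#'   alignment and the annealed duplex, per transcript.
#' @param largest_bubble largest unpaired region in a trans-NAT duplex, as a
#'   fraction of the total alignment length.
#' @param low_complexity_filter discard input sequences by composition.
#' @param genome_alignment when a genome is provided, discard sRNAs that do
#'   not align to it.
#' @param overhang an [overhang_config()] for star-partner search.
#' @param unique_origin drop calls whose sequence maps to several transcripts.
#' @param min_replicate_presence keep only sequences present in at least this
#'   many input libraries (1 = union).
#' @param scoring a [complement_scoring()] list.
#' @param hybridize_flank flank (nt) added around the complementarity
#'   alignment before duplex verification.
#' @param seed integer seed recorded in the run manifest.
#' @return a list of class `nat_config`.
#' @export
nat_config <- function(min_overlap_length = 100L,
                       min_srna_phases = 1L,
                       min_srna_length = 19L,
                       max_srna_length = 24L,
                       min_srna_abundance = 1L,
                       min_tag_length = 19L,
                       max_tag_length = 21L,
                       cis_only = TRUE,
                       coverage_ratio = 0.80,
                       largest_bubble = 0.10,
                       low_complexity_filter = TRUE,
                       genome_alignment = TRUE,
                       overhang = overhang_config(),
                       unique_origin = FALSE,
                       min_replicate_presence = 1L,
                       scoring = complement_scoring(),
                       hybridize_flank = 20L,
                       seed = 1L) {
  structure(list(
    min_overlap_length = as.integer(min_overlap_length),
    min_srna_phases = as.integer(min_srna_phases),
    min_srna_length = as.integer(min_srna_length),
    max_srna_length = as.integer(max_srna_length),
    min_srna_abundance = as.integer(min_srna_abundance),
    min_tag_length = as.integer(min_tag_length),
    max_tag_length = as.integer(max_tag_length),
    cis_only = isTRUE(cis_only),
    coverage_ratio = coverage_ratio,
    largest_bubble = largest_bubble,
    low_complexity_filter = isTRUE(low_complexity_filter),
    genome_alignment = isTRUE(genome_alignment),
    overhang = overhang,
    unique_origin = isTRUE(unique_origin),
    min_replicate_presence = as.integer(min_replicate_presence),
    scoring = scoring,
    hybridize_flank = as.integer(hybridize_flank),
    seed = as.integer(seed)), class = "nat_config")
}

#' Run the nat-siRNA prediction pipeline
#'
#' Executes filtering, exact mapping, search-space reduction, NAT pair
#' classification, nat-siRNA calling and profiling, and optionally writes
#' the three CSV result files. The run is deterministic given the inputs and
#' configuration and invariant to the order of records in the input files.
#'
#' @param reference_fasta transcriptome FASTA (mutually exclusive with
#'   `gff3`/`genome_fasta`).
#' @param gff3 GFF3 annotation; requires `genome_fasta`.
#' @param genome_fasta genome FASTA (required with `gff3`; optional with
#'   `reference_fasta`, where it only powers the genome-presence filter).
#' @param srna_files character vector of redundant sRNA FASTA paths.
#' @param degradome_file optional redundant degradome FASTA.
#' @param blacklist_file optional FASTA of sequences to exclude (miRNA, tRNA,
#'   rRNA), matched with up to 2 mismatches.
#' @param config a [nat_config()].
#' @param out_dir optional output directory for CSV results and the run
#'   manifest.
#' @return a list of class `nat_results`: `pairs`, `calls`, `profiles`
#'   data.frames (internal 0-based half-open coordinates), `pair_objects`,
#'   `filter_report`, `stage_counts`, `config`.
#' @export
run_pipeline <- function(reference_fasta = NULL, gff3 = NULL,
                         genome_fasta = NULL, srna_files,
                         degradome_file = NULL, blacklist_file = NULL,
                         config = nat_config(), out_dir = NULL) {
  if (is.null(reference_fasta) && is.null(gff3))
    stop("a reference transcriptome (FASTA or GFF3 + genome) is required")
  if (!is.null(gff3) && is.null(genome_fasta))
    stop("when a GFF3 annotation is the reference, a corresponding genome must also be provided")
  if (length(srna_files) < 1L) stop("at least one sRNA library is required")

  stage <- list()
  log_stage <- function(name, value) {
    stage[[name]] <<- value
    message(sprintf("[natsir] %s: %s", name, value))
  }

  transcripts <- if (!is.null(gff3)) extract_transcripts(gff3, genome_fasta)
  else transcripts_from_fasta(reference_fasta)
  log_stage("transcripts", length(transcripts))

  libs <- lapply(srna_files, read_redundant_fasta)
  if (config$min_replicate_presence > 1L) {
    keep <- conserve_across_replicates(libs, config$min_replicate_presence)
    libs <- lapply(libs, function(l) l[l$sequence %in% keep, , drop = FALSE])
  }
  merged <- do.call(rbind, libs)
  ab <- vapply(split(merged$abundance, merged$sequence), sum, numeric(1))
  reads <- data.frame(sequence = names(ab), abundance = as.integer(ab),
                      stringsAsFactors = FALSE)
  reads <- reads[order(reads$sequence), , drop = FALSE]
  log_stage("input_sequences", nrow(reads))

  genome <- if (!is.null(genome_fasta))
    Biostrings::readDNAStringSet(genome_fasta) else NULL
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
  filt <- filter_reads(reads, config, genome = genome)
  reads <- filt$reads
  if (!is.null(blacklist_file)) {
    bl <- read_redundant_fasta(blacklist_file)
    reads <- blacklist_filter(reads, bl$sequence)
  }
  log_stage("filtered_sequences", nrow(reads))

  index <- build_exact_index(transcripts)
  alignments <- align_reads(index, reads)
  alignments <- sort_alignments(alignments)
  log_stage("srna_alignments", nrow(alignments))

  deg_alignments <- NULL
  if (!is.null(degradome_file)) {
    deg <- read_redundant_fasta(degradome_file)
    deg <- filter_degradome(deg, config)$reads
    deg_alignments <- sort_alignments(align_reads(index, deg))
    log_stage("degradome_alignments", nrow(deg_alignments))
  }

  blocks <- build_phase_blocks(alignments, config$min_srna_phases)
  regions <- blocks[, c("transcript", "start", "end")]
  if (!is.null(deg_alignments)) {
    regions <- unique(rbind(regions,
                            degradome_adjacent_regions(alignments,
                                                       deg_alignments)))
  }
  candidates <- generate_candidate_pairs(regions, index, transcripts)
  log_stage("candidate_pairs", nrow(candidates))

  pair_objects <- list()
  pair_rows <- list(); call_rows <- list(); profile_rows <- list()
  for (i in seq_len(nrow(candidates))) {
    pair <- classify_pair(candidates[i, , drop = FALSE], transcripts, config)
    if (inherits(pair, "nat_rejection")) next
    pid <- sprintf("pair_%d", length(pair_objects) + 1L)
    pair$pair_id <- pid
    pair_objects[[pid]] <- pair

    calls <- call_nat_sirnas(pair, alignments, deg_alignments,
                             overhang = config$overhang, pair_id = pid)
    calls <- unique_origin_filter(calls, config$unique_origin)
    call_rows[[pid]] <- calls

    dens <- alignment_densities(pair, alignments, transcripts)
    prof <- profile_pair(pair, alignments, pid)
    profile_rows[[pid]] <- prof$profiles

    pair_rows[[pid]] <- data.frame(
      pair_id = pid,
      transcriptA = pair$transcriptA, transcriptB = pair$transcriptB,
      class = pair$nat_class, orientation = pair$orientation,
      category = pair$coverage_category,
      overlap_startA = pair$intervalA[1], overlap_endA = pair$intervalA[2],
      overlap_startB = pair$intervalB[1], overlap_endB = pair$intervalB[2],
      overlap_len = pair$overlap_len,
      hybridization_checked = pair$hybridization_checked,
      density_overlap = round(dens$density_overlap, 6),
      density_global = round(dens$density_global, 6),
      pattern = prof$pair_pattern,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(pair_id = character(0), transcriptA = character(0),
               transcriptB = character(0), class = character(0),
               orientation = character(0), category = character(0),
               overlap_startA = integer(0), overlap_endA = integer(0),
               overlap_startB = integer(0), overlap_endB = integer(0),
               overlap_len = integer(0), hybridization_checked = logical(0),
               density_overlap = numeric(0), density_global = numeric(0),
               pattern = character(0), stringsAsFactors = FALSE)
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(pair_id = character(0), sequence = character(0),
               abundance = integer(0), origin_transcript = character(0),
               start = integer(0), end = integer(0), group = integer(0),
               star_sequence = character(0), deg_support_mature = logical(0),
               deg_support_star = logical(0), multi_origin = logical(0),
               stringsAsFactors = FALSE)
  profiles <- if (length(profile_rows)) do.call(rbind, profile_rows) else
    data.frame(pair_id = character(0), transcript = character(0),
               retained_clusters = integer(0),
               pct_unique_in_clusters = numeric(0), pattern = character(0),
               stringsAsFactors = FALSE)
  rownames(pairs) <- rownames(calls) <- rownames(profiles) <- NULL
  log_stage("accepted_pairs", nrow(pairs))
  log_stage("nat_sirna_calls", nrow(calls))
  if (nrow(pairs) == 0L) warning("no NAT pairs passed the acceptance criteria")

  results <- structure(list(pairs = pairs, calls = calls, profiles = profiles,
                            pair_objects = pair_objects,
                            filter_report = filt$report,
                            stage_counts = stage, config = config),
                       class = "nat_results")
  if (!is.null(out_dir)) {
    write_results_csv(results, out_dir)
    write_run_manifest(results, file.path(out_dir, "run_manifest.txt"))
  }
  results
}

#' @export
print.nat_results <- function(x, ...) {
  cat("nat_results: ", nrow(x$pairs), " NAT pairs, ",
      nrow(x$calls), " nat-siRNA calls\n", sep = "")
  invisible(x)
}

# plain-text manifest of configuration and stage counts, for reproducibility
write_run_manifest <- function(results, path) {
  cfg <- results$config
  scalars <- vapply(cfg, function(v)
    if (is.list(v)) paste(unlist(v), collapse = "/") else paste(v, collapse = ","),
    character(1))
  lines <- c("# natsir run manifest",
             paste0("config.", names(scalars), " = ", scalars),
             paste0("stage.", names(results$stage_counts), " = ",
                    unlist(results$stage_counts)))
  writeLines(lines, path)
  invisible(path)
}
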