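---
title: "Predicting NAT-derived siRNAs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NAT-derived siRNAs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natsir)
```

## The biological model

Natural antisense transcripts (NATs) pair with other transcripts over a
complementary region. When both transcripts of a pair are expressed in the
same cell, the double-stranded overlap can be processed by Dicer-like
enzymes into nat-siRNAs, which act as post-transcriptional regulators.
Two observable signatures anchor the computational model:

* **cis pairs** come from overlapping opposite-strand loci, so their
  overlap is *perfectly* complementary; **trans pairs** come from separate
  loci and pair imperfectly, which is why they additionally face a
  secondary-structure plausibility check.
* Dicer processing leaves footprints: an sRNA/sRNA* duplex offset by a
  fixed 2nt overhang, and degradome (PARE) tags whose 5′ ends mark
  processing boundaries immediately 3′ of an sRNA.

The pipeline is sRNA-conditioned: rather than an all-vs-all transcriptome
scan, only transcript regions that actually accumulate sRNA alignments (or
sRNA + adjacent degradome tag evidence) seed the pair search. This is both
the biological prior — duplexes that produce no sRNAs are invisible to
sRNA sequencing anyway — and the reason the search scales.

## Pipeline stages and their assumptions

1. **Filtering.** Reads with non-ACGT characters are unalignable and
   dropped. Length bounds (19–24nt sRNA, 19–21nt tags) bracket Dicer
   products and PARE tag sizes. The low-complexity rule discards reads in
   which one mono-, di- or tri-nucleotide composition exceeds 75%, 37.5%
   or 25% of windows; we count *overlapping* windows with denominators
   L, L−1 and L−2 — the strictest consistent reading of those
   percentages. Degradome tags face only the ambiguity and length
   filters; abundance and complexity rules are specified for sRNAs only.
2. **Exact sense-strand alignment.** Biogenesis requires the sRNA to be a
   substring of its precursor transcript, so mapping is exact and
   sense-only. Multi-mapping reads contribute alignments to every
   location; a per-call `multi_origin` flag (and an optional filter)
   handles the ambiguity downstream rather than discarding evidence early.
3. **Search-space reduction.** "Adjacent" sRNA phases mean the next
   alignment starts exactly where the previous one ends (half-open
   coordinates) or overlaps it; any 1nt gap breaks a chain. Degradome
   regions require a tag 5′ end exactly at an sRNA's 3′-adjacent
   position. Extracted subsequences are reverse complemented and matched
   exactly against all *other* transcripts; isoforms of the same gene are
   excluded only when they are the identical transcript id, since
   opposite-strand isoform overlaps are legitimate cis pairs.
4. **Pair validation.** The overlap is the best local alignment of
   transcript A against the reverse complement of transcript B
   (affine-gap Smith–Waterman). The minimum overlap applies to alignment
   *columns* (gaps included) — the annealed region's physical extent.
   Trans candidates are verified as an intermolecular duplex; if either
   transcript exceeds 5000nt the duplex step is skipped and the alignment
   accepted as reported, bubble and coverage criteria included — the
   skip is a deliberate trade of stringency for tractability on long
   transcripts.
5. **Calling and grouping.** Mature sRNAs are defined per investigated
   transcript; partner-transcript sRNAs are the star candidates. The
   star test maps the partner footprint through the pair's aligned
   columns, so it works for gapped trans overlaps too; candidates whose
   endpoints land on alignment gaps are skipped rather than guessed.
   Overlap membership is any-intersection (≥ 1nt), so boundary-straddling
   reads are reported rather than silently lost.
6. **Profiling.** Greedy 5′-to-3′ clustering with a 10nt seed window
   (seed start to seed start + 9); "more than 5 reads" is summed
   redundant abundance, while the 50% rule counts *distinct* sequences —
   the two rules deliberately use different currencies. The cluster-count
   bound (≤ 10) is evaluated over retained clusters. A pair is labelled
   site-specific when either transcript is.

## Parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `min_overlap_length` | 100 | alignment columns | minimum annealed region considered able to produce siRNAs |
| `min_srna_phases` | 1 | alignments | minimum adjacent-alignment evidence to seed a search |
| `min_srna_length` / `max_srna_length` | 19 / 24 | nt | Dicer product size range |
| `min_srna_abundance` | 1 | reads | keep singletons by default; raise to suppress noise |
| `min_tag_length` / `max_tag_length` | 19 / 21 | nt | PARE tag size range |
| `cis_only` | TRUE | — | trans search is optional and slower; cis pairs carry the strongest prior |
| `coverage_ratio` | 0.80 | fraction | duplex must reproduce ≥ 80% of the aligned interval on each transcript |
| `largest_bubble` | 0.10 | fraction of columns | largest tolerated unpaired run in a trans duplex |
| `low_complexity_filter` | TRUE | — | composition filter on input sRNAs |
| `genome_alignment` | TRUE | — | discard sRNAs absent from the genome when one is provided |
| `overhang` | 2nt, 5′ | nt | star-partner offset; a 3′ setting is available since the canonical Dicer signature is a 2nt 3′ overhang |
| `unique_origin` | FALSE | — | optionally drop calls whose sequence maps to several transcripts |
| `hybridize_flank` | 20 | nt | sequence added around the aligned interval before duplex verification, so the duplex may anneal slightly beyond the alignment |

The coverage-ratio denominator is the aligned interval length on each
transcript and the criterion must hold on both — the conservative reading
where the rule names no denominator. The high-coverage category reads
"either transcript" as an OR, which makes HC precedence over the 100nt
category necessary; the three categories then partition accepted pairs.

## Numerical choices

* **Complementarity scoring** emulates megablast defaults (match +2,
  mismatch −3, gap open 5, gap extend 2; a gap run of length L costs
  5 + 2L), appropriate for the near-identical matches complementary
  overlaps produce. The report threshold is `min_overlap × match × 0.5`.
  DP ties prefer the diagonal over gap states and the smallest end cell,
  making the single reported alignment deterministic. Operands are
  ordered canonically before alignment, so results are symmetric under
  swapping the two transcripts.
* **Duplex verification** scores Watson–Crick pairs +2, G:U wobble +1,
  and charges unpaired stretches an affine penalty (opening 3, each
  column 1); no intramolecular structure is modelled. The duplex is used
  as a geometric yes/no check (annealed extent, bubble sizes), not as a
  free-energy estimate, which is why a pairing-count model suffices; an
  adapter to a thermodynamic engine could sit behind the same contract.
  The duplex must start and end on a paired column, so every unpaired run
  reported is interior.
* **Coordinates** are 0-based half-open internally (unambiguous
  arithmetic), 1-based inclusive in GFF3 and CSV files (convention).
* **Degenerate inputs**: empty libraries yield empty, header-only
  outputs with a warning rather than errors; unpairable duplex regions
  return no result; the low-complexity rule is undefined (errors) below
  3nt; a transcript with no aligned reads has no distribution profile.

## What the synthetic generator emulates — and what it does not

`make_synthetic_annotation()` plants cis loci as genuinely overlapping
opposite-strand genomic spans, so perfect overlap complementarity, the
three orientations and multi-exon splicing arise exactly as in real
annotations, and the overlap always terminates at a transcript end on
each side (a property of span intersections that makes planted overlap
coordinates exact). Trans loci embed a mutated reverse complement of one
transcript's region into another chromosome, with exact mismatch and
bubble placement; bubble surroundings are restricted to an A/C alphabet
so the insert cannot pair, keeping the planted run length exact. Decoys
and non-overlap segments are rejection-sampled against all overlap
21-mers (both strands), so simulated negative reads cannot collide with
overlap content. `simulate_reads()` mirrors the benchmark design:
fixed-length 21nt reads drawn uniformly from overlap regions of either
transcript of a pair, with negatives drawn from footprints disjoint from
every overlap.

What this does *not* emulate: sequencing errors, expression-level
heterogeneity, repeat families and paralogous multi-mapping, RNA
modifications, or annotation errors. Passing the planted-truth suites
therefore demonstrates the correctness of the algorithms under clean
signals — recall of perfect cis signals, exact criterion behavior,
correct group bookkeeping — not robustness to noisy real libraries,
where filter settings and replicate conservation carry more weight.

## Validation design and problem sizes

The test suite validates each engine against an independent oracle: the
exact-match index against a naive all-window substring scan (500 queries
over 20 transcripts), the complementarity aligner's scores against an
independent full-DP implementation (Biostrings) on 100 random pairs up to
300nt, and the greedy clustering against a literal simulation of the
clustering rule on 1000 random instances. End-to-end runs use 20 planted
pairs with 120–300nt overlaps among 30 decoys and 2000 reads (half
negatives) — sizes chosen so the full benchmark emulation completes in
well under two minutes on one CPU while exercising every orientation,
category and group. The acceptance script re-runs this design from
scratch at a caller-supplied seed.

## Known limitations

* One overlap region is reported per transcript pair (the best local
  alignment); disjoint secondary overlaps are not enumerated.
* The duplex model has no nearest-neighbor thermodynamics; borderline
  trans bubbles near the 10% bound may be judged differently than a
  free-energy model would judge them.
* Exact-match mapping means a single sequencing error hides a read; the
  upstream replicate-conservation filter is the intended mitigation.
* The >5000nt skip accepts long-transcript trans alignments without any
  structural check.
* Downstream target prediction is out of scope; `export_for_target_prediction()`
  writes the collapsed FASTA interface for external degradome-based
  target-prediction tools.
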