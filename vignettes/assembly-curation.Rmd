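---
title: "Map-guided assembly curation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map-guided assembly curation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmforge)
```

asmforge curates a draft genome assembly into chromosome-scale sequence and
evaluates the result. This vignette explains the procedures, the tunable
parameters and their defaults, the design choices made where the problem
left the design open, and what the synthetic validation does and does not
demonstrate.

## The scaffolding model

A genetic (recombination) map provides, for each linkage group, an ordered
set of SNP markers with centimorgan positions. Markers aligned to the draft
assembly carry three pieces of evidence per scaffold: which linkage group
(chromosome) the scaffold belongs to, where it sits along that chromosome,
and which way it points.

Marker alignments are filtered hard before any inference: mapping identity
at least `min_identity` (default 0.98), full-length marker coverage, and a
unique genomic placement. The thresholds are deliberately strict — a
misplaced marker is worse than a discarded one, because every downstream
decision trusts the surviving hits.

**Chimera detection.** A scaffold is flagged as chimeric when markers from
two or more linkage groups align to it. The flag requires at least
`min_conflict_markers` (default 2) hits in every non-dominant group: a
single stray marker is indistinguishable from mismapping noise, so it never
breaks a scaffold. This reading of the break rule is one of two defensible
interpretations ("at least two conflicting markers" versus "markers from at
least two groups, any count"); the threshold is configurable so either
behaviour is available, and the default favours robustness over recall.

**Breakpoint placement.** No marker evidence pinpoints the true junction,
only brackets it: the breakpoint goes at the midpoint between the last hit
of one same-group run and the first hit of the next. When an assembly gap
lies between those two hits the break snaps into the gap closest to that
midpoint, because a gap is a position where the assembly itself already
declares uncertainty — splitting there destroys no contig sequence.

**Orientation and order.** The Pearson correlation is computed between the
rank of hit positions along the scaffold and the rank of marker order on
the map — ranks, not centimorgan distances, because marker *order* is the
quantity the map asserts most reliably; local cM distances are noisy at
scaffold scale. `r > 0` orients the scaffold `+`, `r < 0` orients it `-`;
fewer than two markers, a zero correlation or a constant rank vector leave
the orientation `unknown`, and such scaffolds are emitted in their input
orientation with the flag preserved in the assignment table. The ordering
key along a chromosome is the *median* marker cM position — robust to a
single mismapped marker, unlike the mean or either extreme. Ties break by
descending segment length, then name, so output is deterministic.
Chromosomes are assembled with 100 bp map-evidence gaps between
consecutive segments, the usual convention for joins supported by linkage
rather than sequence.

## The gap-filling rule

A gap is closed when a contig from an independent patch assembly aligns on
both sides of it with **more than** `min_flank` bases per flank (default
5000, strict inequality) ending **at most** `max_distance` bases from the
gap edge (default 10, inclusive). Both boundary semantics are exact and
tested at the boundary (a 5000 bp flank or an 11 bp distance never fills).
Flank length is measured as aligned bases in the flanking block rather
than its span on the target, since spans inflate across target insertions.
One qualifying patch assembly suffices; when both qualify, the evidence
with the longer minimum flank wins, with lexicographic tie-breaks so reruns
are identical. A single alignment block crossing the whole gap is treated
as two flanks at zero distance — the strongest possible evidence.

The splice point is the exact end of the flanking alignment block: up to
`max_distance` target bases between block end and gap edge are replaced by
patch sequence, on the grounds that bases an independent assembly could not
align across are the least trustworthy in the region.

**Collapses.** A negative gap asserts that the assembly has *too little*
sequence at a point. Splicing on one assembly's say-so would let any
mis-assembled patch contig inject sequence, so collapses are only
*confirmed*, never spliced, and confirmation needs two patch assemblies to
agree on the implied insertion's position (within `collapse_pos_tol`,
default 20 bp) and size (within `max(20 bp, 10%)`). The tolerances are
explicit configuration: "agreement" has no canonical numeric definition,
so the package states one rather than hiding it.

## The QC suite

* **Contiguity.** `Nx` is the length of the sequence at which the
  cumulative sorted-descending total first reaches `x%` of the assembly;
  `NGx` uses a fixed genome size (default 2.8 Gb) instead, making values
  comparable across assemblies of different total length. An assembly that
  never reaches `x%` of the genome size reports `NGx` as absent rather
  than 0 — a short assembly is not an assembly of zero-length contigs.
* **QV.** Consensus quality is `-10 log10(error_bases / assessed_bases)`.
  Error bases are counted from a small-variant table as
  `max(nchar(ref), nchar(alt))` per PASS record, heterozygous and
  homozygous-alternate alike by default; both conventions are configurable
  because published pipelines differ in their FreeBayes filtering. Zero
  error bases yields a detection-limited lower bound, reported as
  `">= cap"`.
* **Chromosome ends.** An acrocentric chromosome should show centromeric
  repeats in its first `end_window` bases (default 500 kb) and telomeric
  repeats in its last; a metacentric one, telomeres at both ends. The
  verdict is a pure function of the four end-window booleans plus the
  karyotype — deliberately so, since an "internal centromere" criterion
  would make the verdict depend on repeat content the end windows never
  see, and the 32-case verdict table could no longer be enumerated and
  tested exhaustively. The classic misassembly signature, centromeric
  arrays at both ends, gets its own verdict. Motif detection is a thin
  helper (three or more consecutive motif copies, both strands); motif
  sequences are configuration, not code.
* **Repeat regions.** Intervals merge only when overlapping by at least
  1 bp — abutting intervals stay separate — and merged regions are
  classed by position (chromosome start within 500 kb, unplaced scaffold,
  or chromosome body) with mean length and a `mean ± 2·SE` confidence
  interval per class.
* **Gap–gene proximity.** A gene counts for the intron statistic when any
  gap intersects a derived intron, and for the flank statistic when any
  gap lies within `flank_bp` (default 10 kb) of the gene *including its
  body* — a gap inside an intron is certainly within 10 kb, so the intron
  set is a subset of the flank set by construction.
* **Transcript classes.** Statuses are assigned in strict priority:
  `not_aligning`, then `split` (best placement spans two or more target
  sequences), then `low_cds_coverage` (best placement covers under 95% of
  the CDS), else `ok`. The best placement maximises summed matches, with
  ties broken toward fewer target sequences and longer coverage.

## The synthetic truth set

`simulate_truth_set()` builds everything the pipeline consumes, with every
planted fact recorded: uniform-ACGT chromosomes carrying a 30 kb
centromeric satellite array at the start and a 3 kb telomeric `TTAGGG`
array at the end; multi-exon genes away from the arrays; a draft whose
scaffolds replace true sequence with equal-length N gaps and include
inter-chromosome misjoins, whole-scaffold inversions and silent collapses;
a genetic map whose marker hits are computed by exact coordinate
bookkeeping; two patch assemblies whose alignment geometry is engineered
per gap (qualifying spans from A, B or both; a flank of exactly 5000 bp;
an edge distance of exactly 11 bp; no span; agreeing and disagreeing
collapse evidence); and a variant table whose error-base total is exact by
construction.

Alignments are computed from coordinates, never by running an aligner: the
rules under test are alignment-geometry thresholds, and bookkeeping makes
the boundary cases exact where a real aligner would blur them. The default
scale — 3 chromosomes of 2 Mb, 60 genes, 40 markers per chromosome, 4
scaffolds per chromosome with 3 misjoins, 2 inversions and 2 collapses,
and 10,000 planted error bases in 20 Mb assessed — keeps a full
simulate–scaffold–gapfill–qc cycle under a minute on one CPU while leaving
roughly ten markers on each side of every planted junction.

What passing these tests shows is that the *rules are implemented
exactly*: every planted misjoin with two markers per side is found with no
false breaks, order and orientation are recovered perfectly, exactly the
qualifying gaps close, and the planted QV is recovered. What it does not
show is performance on real data, where markers mismap, alignments have
gapped, partial and repeat-confounded blocks, repeat arrays are neither
pure nor uniquely placed, and coverage is uneven. The simulator
deliberately omits sequencing error models, realistic repeat landscapes
and read-level data; conclusions about real-genome accuracy require real
genomes.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open throughout; AGP and VCF are
converted at the file boundary (both are 1-based on disk). This removes
the class of off-by-one errors that mixing conventions invites. Negative
gaps cannot be expressed in AGP v2.0 and travel in a sidecar TSV. N runs
shorter than `min_gap_run` (default 10) are not counted as structural
gaps, so isolated ambiguous bases left by polishing do not inflate gap
counts. Unknown FASTA characters become `N` with a warning rather than an
error, since real assemblies contain IUPAC ambiguity codes. Division by
zero in comparison arithmetic reports "undefined" (`NA`) rather than
failing, and a single-member repeat category reports its mean with an
undefined confidence interval.

## A worked example

```{r example}
ts <- simulate_truth_set(seed = 7, n_chromosomes = 2, chrom_length = 6e5,
                         n_genes = 10, n_scaffolds_per_chrom = 3,
                         n_misjoins = 1, n_inversions = 1, n_collapses = 1,
                         markers_per_chrom = 16, assessed_bases = 1e6,
                         error_rate = 5e-4)
res <- map_guided_scaffold(ts$draft$layouts, ts$map$hits, ts$map$markers)
length(res$breaks)          # chimeric scaffolds broken
res$assignments[, c("scaffold", "linkage_group", "orientation",
                    "pearson_r", "n_markers")]

gf <- gap_fill(ts$draft$layouts, ts$draft$scaffolds,
               list(A = ts$patches$A, B = ts$patches$B),
               negative_gaps = ts$draft$negative_gaps)
gf$summary[c("gaps_before", "n_filled", "gaps_after")]

estimate_qv(count_error_bases(ts$variants$variants),
            ts$variants$assessed_bases)$qv_label
```

## Known limitations

Scaffolds whose markers all fall on one side of a misjoin cannot be
broken; the break rule needs two markers per conflicting group. Orientation
of single-marker scaffolds is unknowable from the map and is passed
through unchanged. Gap filling trusts the provided alignments; it does not
verify flank sequence identity itself. The transcript classifier expects
compound placements to be delimited upstream (a `placement` column); it
does not chain blocks into placements. Collapse confirmation reports but
does not apply insertions.
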