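---
title: "Surveying a genome from BAC-end sequences: methods and design notes"
author: "bessurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying a genome from BAC-end sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

Before a genome is assembled, a lot can be learned about it from a BAC
(bacterial artificial chromosome) library and a sample of Sanger reads taken
from the two ends of each clone insert (BAC-end sequences, BESs).  A few
megabases of such reads — effectively a sparse random sample of the genome —
support estimates of GC content, repeat-element composition, microsatellite
(SSR) density and motif spectrum, protein-coding fraction and total gene
content, while the paired geometry of the two ends (known approximate
separation, inward orientation) enables microsynteny scans against related
reference genomes and the classical Clarke–Carbon characterization of the
library itself.

`bessurvey` implements that whole survey as composable, deterministic
stages:

1. **QC** — quality end-trimming, vector screening, length filtering,
   organelle removal (`qc_reads()`);
2. **repeat census** — hierarchical aggregation of masking annotations plus
   a light seed-and-extend masker for a custom repeat library
   (`build_census()`, `mask_with_library()`);
3. **SSR mining** — perfect and compound SSR detection, motif
   canonicalization, length classes, density (`find_perfect_ssrs()`,
   `merge_compound()`, `ssr_summary()`);
4. **coding census and extrapolation** — per-read interval-union match
   lengths from homology hit tables, scaled to a genome-size range
   (`coding_summary()`, `extrapolate_genome()`);
5. **microsynteny** — best-hit pairing of clone ends and the
   SE / PE (non-colocalized / collinear / rearranged / gapped)
   classification (`classify_clone_pairs()`);
6. **library statistics** — insert-size bins, fold coverage and the
   Clarke–Carbon single-copy probability (`single_copy_probability()`).

A synthetic-data generator (`simulate_genome()`, `simulate_bes()`) produces
a toy genome, clone library and read set with complete truth tables so
every stage is testable without any external download.

## Conventions and key parameters

All coordinates, in memory and on disk, are 1-based inclusive (the
BLAST/GFF3 convention); interval arithmetic is delegated to `IRanges`.
Minus-strand alignments are encoded by `s_start > s_end`.  Any base outside
`A/C/G/T` is stored as `N`.  Reported percentages round half-up to two
decimals, matching how survey tables are conventionally printed (R's
`round()` is round-half-even, which would disagree on exact halves).

Stage thresholds and their defaults:

| parameter | default | meaning |
|---|---|---|
| `qmin` | 20 | minimum Phred score for terminal bases; interior low-quality bases are retained |
| `min_read_len` | 100 bp | inclusive length floor after trimming |
| `org_evalue` | 1e-15 | E-value at or below which a read with an organelle hit is removed |
| `est_evalue`, `protein_evalue` | 1e-10, 1e-06 | hit-table filters applied before coding aggregation |
| SSR `min_len` | 20 bp (mono), 15 bp (di–hexa) | whole-unit span floor per unit length |
| `ssr_max_gap` | 100 bp | maximum gap between members of a compound SSR |
| synteny filter | identity ≥ 70 %, length ≥ 50 bp, E ≤ 1e-06 | all boundaries inclusive |
| `span_min`, `span_max` | 15–350 kb | collinear span bounds (the observed clone insert range) |
| masker | ≥ 50 bp at ≥ 80 % identity | seed-and-extend acceptance for repeat-library matches |

## SSR semantics

A perfect SSR is a maximal tandem run of a primitive 1–6 bp unit whose
whole-unit span reaches the per-unit-length floor.  Several decisions fix
the edge cases:

* **Whole units only.**  "At least 15 bp" for di- to hexanucleotides is
  interpreted as `unit_len × n_units ≥ 15` with integral `n_units`, so a
  dinucleotide needs 8 units (16 bp), a trinucleotide 5, a tetranucleotide
  4, and penta-/hexanucleotides 3.  Fractional trailing units are clipped,
  and the locus is anchored at the left end of the maximal run.
* **Smallest primitive unit wins.**  A poly-A run also matches unit `AA`;
  only `(A)n` is reported.  Where qualifying runs of different unit lengths
  overlap, candidates are taken in order of start, then unit length, and
  overlapping later candidates are dropped — a deterministic left-to-right
  rule.
* **`N` breaks runs**; no SSR spans an ambiguous base.
* **Compound SSRs** merge *transitively*: maximal chains of perfect loci
  with successive gaps ≤ 100 bp become one compound locus, however long the
  chain.
* **Canonical motifs.**  The canonical unit is the lexicographically
  smallest string over all rotations of the motif and of its reverse
  complement; the class label is `X/Y` with `Y` the canonical rotation of
  the reverse complement of `X` (`AG/CT`, `AAT/ATT`, `AT/AT`).  This makes
  the motif spectrum invariant under strand flips and phase shifts, which a
  property test verifies directly.
* **Length classes** (perfect loci only): Class I at span ≥ 20 bp, Class II
  at 10–19 bp.  Under the default 20 bp mononucleotide floor, mono loci are
  always Class I; surveys that report Class II mononucleotides used a lower
  floor for that scan, which is why the floor is configuration, not a
  constant.

The detector itself is a shift-comparison: for period *k*, positions where
`x[i] == x[i+k]` are run-length encoded, each maximal `TRUE` run of length
*L* giving a maximal period-*k* region of span *L + k*.  The test suite
holds it equal to an independent brute-force oracle that extends every
(start, unit length) candidate by literal substring comparison — 1,000
random 2 kb sequences in the acceptance suite.

## The stand-in matcher

Vector screening and novel-library masking use the package's own gap-free
seed-and-extend matcher: exact 12-mer seeds, ungapped extension scored
match +1 / mismatch −2 under an x-drop of 20, with candidate endpoints
restricted to prefixes that keep the extended segment at the required
identity (otherwise a chance low-identity continuation past the true end of
a vector tail can drag the whole segment below threshold and lose the
match).  Terminal matches (within 10 bp of a read end) are trimmed;
internal matches are masked to `N`.

This matcher is intentionally *not* a CROSS_MATCH or RepeatMasker
replacement: it has no gapped alignment, no score matrices, no repeat
divergence model.  It is adequate for substitution-diverged copies — which
is exactly what the simulator plants — and every downstream step equally
accepts externally produced masking tables (`mask_annotations()`,
`read_annotations()`), which is the intended route for real data.

## Census semantics

Element counts are plain annotation counts (two overlapping annotations of
one family are two elements), while masked bp use interval union — within a
class for the class rows, and across *all* classes for the grand-total row.
The total can therefore be smaller than the column sum when classes overlap
on the same bases; the example census shipped in
`inst/extdata/sweetpotato_bes_census.tsv` shows precisely this signature
(per-class lengths summing above the printed total), which is why the
package adopts cross-class union for the total row.  Known-library and
novel-library masking percentages are additive by construction, because
novel masking runs on the already `N`-masked output of known masking.  The
combined repeat fraction adds the two already-rounded percentages, the
convention such tables use.

## Coding extrapolation

"Cumulative match length" is defined as the per-read union of query-side
alignment intervals, summed over reads — the only definition bounded by the
read length, hence immune to double-counting overlapping hits.  The coding
fraction (matched bp / total bp) scales linearly to a genome-size range,
and gene counts are `floor(coding length / mean gene length)` at each
bound.  Published surveys are not always internally consistent here (the
printed coding-length bounds need not back-compute from the printed
percentage); the package always recomputes from its inputs and leaves such
discrepancies visible rather than forcing any printed value.

## Microsynteny classification

One best hit per end (maximum bitscore, ties broken by E-value, identity,
subject id, subject start — fully deterministic), then per clone:

| both ends hit? | same subject? | orientation | span in 15–350 kb? | category |
|---|---|---|---|---|
| no | — | — | — | SE |
| yes | no | — | — | PE non-colocalized |
| yes | yes | wrong | — | PE rearranged |
| yes | yes | inward | yes | PE collinear |
| yes | yes | inward | no | PE gapped |

"Correct orientation" is defined as opposite strands facing inward — the
configuration produced by sequencing the two ends of one insert — with the
plus-strand hit upstream; the span is `max(subject coords) − min(subject
coords) + 1` over both hits regardless of strand encoding.  The rule table
is verified exhaustively over the 12-cell grid and by a 10,000-pair random
property test, and classification is symmetric under swapping the ends.
Whether best-hit selection happens before or after pairing is survey-
dependent; both modes exist (`classify_clone_pairs(best = FALSE)`).

## Library statistics

The Clarke–Carbon probability that a random single-copy locus is present in
a library of `N` clones with insert `I` from a genome `G` is
`P = 1 − (1 − I/G)^N`, computed via `log1p` for tiny `I/G`; the inverse
(`clarke_carbon_clones()`) gives the clone count needed for a target `P`.
The closed form is checked against Monte-Carlo clone sampling on a 10 Mb
toy genome (10,000 replicates) in the regime libraries are actually built
for (`P ≈ 0.99`), where the Monte-Carlo standard error (~0.001) is well
inside the ±0.005 comparison band; at mid-range `P` the band would be only
a couple of standard errors wide and the check would fail on noise alone.
The mean insert excludes no-insert clones, and fold coverage takes an
*effective* mean insert as a parameter, because printed fold ranges in
surveys of this kind do not always back-compute to the printed mean insert
(the worked example reproduces its printed 7.93–10.82× range at an
effective 99 kb, not the printed 101 kb mean).

## The synthetic-data generator

`sim_config()` defaults describe the conditions the package is validated
under: a 5 Mb AT-rich genome (GC 0.38) carrying 12 % known-family and 18 %
novel-family repeats (4 families each, 800/700 bp elements at 3 %/5 %
substitution divergence), one planted SSR per 2 kb drawn from an AT-biased
motif pool, a ~5 % genic fraction, two 20 kb organelle genomes, and a
1,200-clone library with truncated-lognormal inserts in 15–305 kb (mean
about 100 kb) read from both ends at Sanger-like lengths (mean 658 bp,
range 100–945 bp), 0.7 % organellar contamination, vector tails on half the
reads, and a configurable unpaired fraction.

Design points that matter for interpreting test results:

* **Placement.**  Features are shuffled and placed with at least 110 bp of
  background between them, so planted SSRs can never merge into compounds
  and feature boundaries are controlled.  Background and all component
  sequences are *scrubbed*: any chance run that would qualify as an SSR is
  broken by a single substitution, and planted SSR flanks are fixed so each
  planted run is maximal.  The planted truth table is therefore the
  complete SSR truth, which is what makes exact recall/precision a
  meaningful assertion.
* **Truth-derived hit tables.**  Organelle, reference-genome and
  gene-fragment hit tables are emitted directly from truth with E = 1e-180,
  so alignment-tool behaviour is never a test dependency.  The forward read
  aligns at the insert's left edge on the plus strand and the reverse read
  at the right edge on the minus strand, so a correctly classified pair
  recovers the true insert size as its span.
* **Coordinate bookkeeping.**  QC records the bases removed from each
  read's 5' end (`offset5`), and `expected_read_features()` projects the
  genome-level truth through that offset onto the processed reads —
  including the phase-rotated motif and whole-unit clipping of an SSR cut
  by a read edge.  Recovery is judged against this *read-level* truth: how
  faithfully a 1.5 Mb read sample reflects a 5 Mb genome is a property of
  sampling, not of the pipeline under test (the genome-level planted
  fractions are reported alongside, with a looser band).
* **Quality model.**  The end-to-end recovery runs use the clean quality
  model (all Q40) so that planted truth maps exactly onto post-QC reads;
  the two-state good/bad Markov model that produces trimmable ends is
  exercised by its own tests of the trimming stage.
* **Determinism.**  One master seed derives one stream per stage (genome,
  library, quality, contamination); identical configurations give
  byte-identical outputs.

What the generator does **not** emulate: chromatogram-level noise, indel
divergence of repeat copies, nested/fragmented repeat structures,
polyploid haplotypes, chimeric clones, and real database search behaviour.
Passing the recovery suite therefore demonstrates that the pipeline's
bookkeeping, thresholds and classification rules are exact under controlled
conditions — not that the stand-in matcher rivals production maskers on
real repeats.

## Problem sizes used in validation

The unit suites run on a 400 kb / 60-clone simulation; the end-to-end
acceptance check runs the full default conditions above (5 Mb, 1,200
clones, ~2,300 reads); detector–oracle equivalence uses 1,000 random 2 kb
sequences; pair classification uses the exhaustive grid plus 10,000 random
pairs; interval-union checks use 1,000 random hit sets; the Monte-Carlo
Clarke–Carbon comparison uses 10,000 replicates.  These sizes were chosen
so each stochastic assertion sits several standard errors inside its band.

## Known limitations and visible discrepancies

* The matcher is gap-free; indel-diverged repeat copies would be recovered
  only piecewise.  Real masking tables are the supported alternative.
* Survey tables of this kind contain small internal inconsistencies
  (printed means, densities and fold ranges that do not exactly
  back-compute from their own inputs).  The package's policy is to
  recompute and report, never to force a printed value: the worked example
  yields a 658.05 bp mean read length, one SSR per 1.97 kb, a 10.01 %
  NR-confirmed coding fraction, and a 7.93–10.82× fold range only at a
  99 kb effective insert — each documented where it appears.
* Dataset-level numbers that depend on real reads or external databases
  (GC content of a particular genome, absolute read and SSR counts,
  top-hit species spectra) are out of reach of a self-contained package
  and are covered instead by format-fidelity and property tests.
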