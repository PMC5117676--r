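# bessurvey

Genome surveys from BAC-end sequences (BESs), in R.

Before a genome is assembled, a BAC library plus a few thousand Sanger
reads taken from the two ends of its clone inserts already answer a lot:
how AT-rich the genome is, how much of it is repetitive and of which
transposon classes, how dense and which kinds of microsatellites (SSRs) it
carries, what fraction is protein-coding and roughly how many genes that
implies, and — because the two ends of a clone sit a known distance apart
in inward orientation — where the genome is microsyntenic with sequenced
relatives.  `bessurvey` implements that survey end to end for people
characterizing a new library or re-analysing deposited BES sets: read QC
(quality/vector trimming, organelle screening), a hierarchical
repeat-element census, an SSR miner with motif canonicalization, coding
and gene-content extrapolation, Clarke–Carbon library statistics, and
paired-end microsynteny classification.  A synthetic-data generator with
full truth tables makes every stage testable offline.

## The statistics at the core

* **Clarke–Carbon library coverage.**  The probability that a random
  single-copy locus is in a library of *N* clones of insert *I* from a
  genome *G* is *P* = 1 − (1 − *I*/*G*)^*N* (computed stably via `log1p`);
  fold coverage is *N·I*/*G*.
* **SSR mining.**  Perfect SSRs are maximal whole-unit tandem runs of a
  primitive 1–6 bp motif (≥ 20 bp for mononucleotides, ≥ 15 bp otherwise);
  runs ≤ 100 bp apart merge transitively into compound SSRs; motifs are
  canonicalized over rotation and reverse complement into classes such as
  `AG/CT` and `AAT/ATT`; perfect loci split into Class I (≥ 20 bp) and
  Class II (10–19 bp).
* **Repeat census.**  Element counts plus interval-union masked bp per
  taxonomy node (Class I retrotransposons: Ty1-Copia, Ty3-Gypsy, LINE,
  SINE; Class II DNA transposons; satellites; simple repeats; …), with a
  cross-class union for the grand total.
* **Cumulative match length.**  For coding and reference coverage, the
  per-read union of alignment intervals summed over reads — overlapping
  hits are never double-counted.
* **Microsynteny.**  Best hit per clone end, then SE / PE
  non-colocalized / collinear / rearranged / gapped, where collinear means
  same subject, opposite strands facing inward, span within 15–350 kb.

See `vignettes/bes-survey-methods.Rmd` for the full model description and
design decisions.

## Worked example

The package ships a repeat census from a sweetpotato BES survey
(11,542 reads, 7,595,261 bp) as example data.  Recomputing the survey's
derived quantities:

```r
library(bessurvey)
total_bp <- 7595261

cen <- read.table(system.file("extdata", "sweetpotato_bes_census.tsv",
                              package = "bessurvey"),
                  sep = "\t", header = TRUE, check.names = FALSE)

census_share(cen, "Class I retrotransposon", "Total repetitive DNA")
#> [1] 69.92        # % of repetitive bp that is Class I

census_share(cen, "Class I retrotransposon|LTR retrotransposons",
             "Class I retrotransposon")
#> [1] 86.52        # % of retrotransposon bp that is LTR

coding_fraction(924646, total_bp)   # known-repeat masked fraction
#> [1] 12.17
total_repeat_fraction(12.17, 18.31) # plus novel-library masking
#> [1] 30.48

coding_fraction(773346, total_bp)   # tomato-protein coding fraction
#> [1] 10.18
extrapolate_genes(c(217.78e6, 296.97e6), 1379)  # genes at 2.2-3.0 Gb
#> [1] 157926 215351

genome_coverage(240384, 99e3, c(2.2e9, 3.0e9))  # fold coverage
#> [1] 10.82  7.93
single_copy_probability(240384, 101e3, 3e9)
#> [1] 0.9997

rate(173, 288)                      # polymorphic SSR primer pairs
#> [1] 60.07
```

SSR mining on a read:

```r
loci <- find_perfect_ssrs(c(F0001 = paste0("GCAGT", strrep("AT", 9),
                                           "CCGTA", strrep("AAG", 6), "TG")))
loci[, c("start", "end", "motif", "motif_class", "n_units", "length_class")]
#>   start end motif motif_class n_units length_class
#> 1     5  22    TA       AT/AT       9           II
#> 2    29  46   AAG     AAG/CTT       6           II
merge_compound(loci)$members        # 6 bp apart => one compound locus
#> [1] "(TA)9@5-22,(AAG)6@29-46"
```

The first locus starts at position 5, not 6: the detector anchors at the
left end of the maximal run (`...T|ATATAT...` extends the `TA` phase one
base left), and both loci are Class II because their spans are under
20 bp.

A full synthetic survey (simulate, then run the pipeline on its files):

```r
sb <- simulate_bes(simulate_genome(sim_config(seed = 1)))
write_sim_fixtures(sb, "fixtures")
# then: Rscript inst/scripts/bes-survey.R run --config run.yaml
```

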