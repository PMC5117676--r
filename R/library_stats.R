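## Library-level characterization: insert sizes, genome coverage, the
## Clarke-Carbon single-copy probability, and screening/marker rates.

#' Insert-size distribution of a clone sample
#'
#' Bins clone insert sizes into the conventional survey bins: `> 90 kb`,
#' `40-90 kb`, `< 40 kb` (but with an insert) and `no insert` (size 0).
#'
#' @param sizes numeric vector of insert sizes in bp, with `0` for empty
#'   clones; negative sizes are an error.
#' @return list with `pct` (named bin percentages, 2 dp, summing to 100 up to
#'   rounding), `n` per bin, and `mean_insert` over clones with an insert.
#' @export
insert_size_distribution <- function(sizes) {
  if (!length(sizes)) stop_contract("sizes must be non-empty")
  if (any(sizes < 0)) stop_contract("negative insert size")
  bins <- c(">90 kb" = sum(sizes > 90e3),
            "40-90 kb" = sum(sizes >= 40e3 & sizes <= 90e3),
            "<40 kb" = sum(sizes > 0 & sizes < 40e3),
            "no insert" = sum(sizes == 0))
  with_insert <- sizes[sizes > 0]
  list(pct = pct2(bins, length(sizes)),
       n = bins,
       mean_insert = mean(with_insert))
}

#' Genome coverage of a clone library
#'
#' @param n_clones number of clones `N`.
#' @param mean_insert mean insert size in bp.  The "effective" insert is a
#'   parameter on purpose: published fold ranges do not always back-compute
#'   to the printed mean insert.
#' @param genome_size genome size in bp, or a two-element range.
#' @return fold coverage `N * insert / G` for each genome-size value, 2 dp
#'   (a larger genome gives a smaller fold).
#' @export
genome_coverage <- function(n_clones, mean_insert, genome_size) {
  stopifnot(n_clones > 0, mean_insert > 0, all(genome_size > 0))
  round_half_up(n_clones * mean_insert / genome_size, 2)
}

#' Clarke-Carbon single-copy probability
#'
#' Probability `P = 1 - (1 - I/G)^N` that a random single-copy locus is
#' represented in a library of `N` clones with insert size `I` from a genome
#' of size `G`, computed in the numerically stable `log1p` form.
#'
#' @param n_clones number of clones `N` (0 gives probability 0).
#' @param insert insert size in bp; must satisfy `0 < insert < G`.
#' @param genome_size genome size `G` in bp.
#' @return the probability.
#' @export
single_copy_probability <- function(n_clones, insert, genome_size) {
  stopifnot(n_clones >= 0)
  if (insert <= 0 || insert >= genome_size) {
    stop_contract("insert must satisfy 0 < insert < genome_size")
  }
  -expm1(n_clones * log1p(-insert / genome_size))
}

#' Clarke-Carbon inverse: clones needed for a target probability
#'
#' `N = ln(1 - P) / ln(1 - f)` with `f = insert/G`.
#'
#' @param p target probability in (0, 1).
#' @param insert,genome_size as in [single_copy_probability()].
#' @return the (real-valued) number of clones.
#' @export
clarke_carbon_clones <- function(p, insert, genome_size) {
  stopifnot(p > 0, p < 1)
  log1p(-p) / log1p(-insert / genome_size)
}

#' Simple screening / marker rate
#'
#' @param positives number of positive outcomes.
#' @param screened number screened; must be positive and `>= positives`.
#' @return `100 * positives / screened`, 2 dp half-up.
#' @export
rate <- function(positives, screened) {
  if (screened <= 0) stop_contract("screened must be positive")
  if (positives < 0 || positives > screened) {
    stop_contract("positives must lie in [0, screened]")
  }
  pct2(positives, screened)
}
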