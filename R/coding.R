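## Coding-region census from EST/CDS/protein hit tables and genome-wide
## gene-content extrapolation.
##
## "Cumulative match length" is the per-read union of query-side alignment
## intervals, summed over reads -- overlapping hits are never double-counted,
## which is the only definition bounded by read length.

#' Union of query-side match intervals
#'
#' @param hits a hit table (any mix of queries).
#' @param per_query if `TRUE`, return a per-query data frame; otherwise the
#'   summed union bp over all queries.
#' @return integer bp, or a data frame `query_id`/`union_bp`.
#' @export
union_match_length <- function(hits, per_query = FALSE) {
  if (nrow(hits) == 0L) {
    if (per_query) {
      return(data.frame(query_id = character(), union_bp = integer(),
                        stringsAsFactors = FALSE))
    }
    return(0L)
  }
  per <- vapply(split(hits, hits$query_id), function(q) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(q$q_start, q$q_end))))
  }, integer(1))
  if (per_query) {
    data.frame(query_id = names(per), union_bp = unname(per),
               stringsAsFactors = FALSE)
  } else {
    sum(per)
  }
}

#' Coding fraction of a read set
#'
#' @param matched_bp cumulative (unioned) match length in bp.
#' @param total_bp total read bp; must be positive and `>= matched_bp`.
#' @return `100 * matched_bp / total_bp`, 2 dp half-up.
#' @export
coding_fraction <- function(matched_bp, total_bp) {
  if (total_bp <= 0) stop_contract("total_bp must be positive")
  if (matched_bp > total_bp) stop_contract("matched_bp exceeds total_bp")
  pct2(matched_bp, total_bp)
}

#' Summarize coding-region hits
#'
#' Applies the E-value cutoff, then aggregates the per-read union of match
#' intervals.
#'
#' @param hits hit table against an EST/CDS/protein set.
#' @param total_bp total bp of the read set.
#' @param e_cutoff E-value filter applied before aggregation (`1e-10` is the
#'   usual nucleotide cutoff, `1e-06` the protein one).
#' @return list of class `coding_summary`: `n_reads_with_hits`,
#'   `cumulative_match_bp`, `pct_of_total`, `e_cutoff`.
#' @export
coding_summary <- function(hits, total_bp, e_cutoff = 1e-10) {
  hits <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
  bp <- union_match_length(hits)
  out <- list(n_reads_with_hits = length(unique(hits$query_id)),
              cumulative_match_bp = bp,
              pct_of_total = coding_fraction(bp, total_bp),
              e_cutoff = e_cutoff)
  class(out) <- "coding_summary"
  out
}

#' @export
print.coding_summary <- function(x, ...) {
  cat(sprintf("coding summary: %d reads with hits (E <= %g), %s bp matched (%.2f%%)\n",
              x$n_reads_with_hits, x$e_cutoff,
              format(x$cumulative_match_bp, big.mark = ","), x$pct_of_total))
  invisible(x)
}

#' Gene-count extrapolation from a coding-length range
#'
#' @param coding_length_range two-element numeric, total coding bp at the
#'   lower and upper genome-size bound.
#' @param mean_gene_len mean coding-region length in bp (positive).
#' @return integer two-element vector, `floor(coding_length / mean_gene_len)`
#'   at each bound.
#' @export
extrapolate_genes <- function(coding_length_range, mean_gene_len) {
  if (mean_gene_len <= 0) stop_contract("mean_gene_len must be positive")
  as.integer(floor(coding_length_range / mean_gene_len))
}

#' Genome-wide coding extrapolation
#'
#' Scales the observed coding fraction to a genome-size range and converts to
#' an expected gene-count range for a given mean coding-region length.
#'
#' @param coding_pct observed coding percentage of the read set (0-100).
#' @param genome_size_range two-element numeric, genome size bounds in bp.
#' @param mean_gene_len mean coding-region length in bp.
#' @return list of class `genome_extrapolation` with `coding_fraction`,
#'   `genome_size_range`, `coding_length_range` and `gene_count_range`.
#' @export
extrapolate_genome <- function(coding_pct, genome_size_range, mean_gene_len) {
  stopifnot(length(genome_size_range) == 2L,
            genome_size_range[1] <= genome_size_range[2])
  clr <- coding_pct / 100 * genome_size_range
  out <- list(coding_fraction = coding_pct / 100,
              genome_size_range = genome_size_range,
              coding_length_range = clr,
              mean_gene_len = mean_gene_len,
              gene_count_range = extrapolate_genes(clr, mean_gene_len))
  class(out) <- "genome_extrapolation"
  out
}

#' @export
print.genome_extrapolation <- function(x, ...) {
  cat(sprintf(paste0("genome extrapolation: coding %.2f%% of %s-%s Mb genome",
                     " -> %.2f-%.2f Mb coding, %s-%s genes (mean gene %d bp)\n"),
              100 * x$coding_fraction,
              format(x$genome_size_range[1] / 1e6),
              format(x$genome_size_range[2] / 1e6),
              x$coding_length_range[1] / 1e6, x$coding_length_range[2] / 1e6,
              format(x$gene_count_range[1], big.mark = ","),
              format(x$gene_count_range[2], big.mark = ","),
              as.integer(x$mean_gene_len)))
  invisible(x)
}
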