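## Read QC: quality end-trimming, vector screening, length filtering,
## organelle removal, dataset summary.  The canonical stage order is
## quality trim -> vector screen -> length filter -> organelle filter.

#' Trim read ends by Phred quality
#'
#' Iteratively removes leading and trailing bases with quality below `qmin`;
#' interior low-quality bases are retained.  A read whose bases all fall
#' below `qmin` becomes empty (and will be dropped by the length filter).
#' The number of bases removed from the 5' end is accumulated in the
#' `offset5` column so that read-local coordinates can be mapped back to the
#' raw read.
#'
#' @param records a [bes_set()]; every read must carry qualities.
#' @param qmin minimum Phred score for terminal bases (default 20).
#' @return the trimmed `bes_set` (possibly with empty sequences).
#' @export
trim_by_quality <- function(records, qmin = 20L) {
  if (any(vapply(records$quality, is.null, logical(1)))) {
    stop_contract("trim_by_quality requires per-base qualities")
  }
  for (i in seq_len(nrow(records))) {
    q <- records$quality[[i]]
    good <- which(q >= qmin)
    if (!length(good)) {
      records$bases[i] <- ""
      records$quality[[i]] <- integer()
      records$offset5[i] <- records$offset5[i] + length(q)
    } else {
      a <- good[1]
      b <- good[length(good)]
      records$bases[i] <- substr(records$bases[i], a, b)
      records$quality[[i]] <- q[a:b]
      records$offset5[i] <- records$offset5[i] + a - 1L
    }
  }
  records
}

#' Screen reads for cloning-vector sequence
#'
#' Matches the vector against each read on both strands with the package's
#' gap-free seed-and-extend matcher.  Matches touching a read end (within
#' `end_margin` bp) are trimmed off; internal matches are masked to `N`.  A
#' read that is pure vector becomes empty.
#'
#' @param records a [bes_set()].
#' @param vector_seq the vector sequence (single string).
#' @param min_match minimum match length in bp (default 20).
#' @param min_ident minimum percent identity (default 95).
#' @param end_margin a match starting/ending within this many bp of a read
#'   end counts as terminal (default 10).
#' @return the screened `bes_set`.
#' @export
screen_vector <- function(records, vector_seq, min_match = 20L,
                          min_ident = 95, end_margin = 10L) {
  if (is.null(vector_seq) || !nzchar(vector_seq)) {
    stop_contract("vector_seq must be non-empty")
  }
  idx <- build_seed_index(c(vector = normalize_bases(vector_seq)),
                          seed_width = min(12L, min_match))
  for (i in seq_len(nrow(records))) {
    s <- records$bases[i]
    if (!nzchar(s)) next
    m <- find_matches(s, idx, min_match = min_match, min_ident = min_ident)
    if (!nrow(m)) next
    L <- nchar(s)
    left <- m$q_start <= end_margin
    right <- m$q_end >= L - end_margin + 1L
    keep_from <- if (any(left)) max(m$q_end[left]) + 1L else 1L
    keep_to <- if (any(right)) min(m$q_start[right]) - 1L else L
    internal <- !left & !right
    if (any(internal)) {
      s <- mask_string(s, m$q_start[internal], m$q_end[internal])
    }
    if (keep_from > keep_to) {
      records$bases[i] <- ""
      if (!is.null(records$quality[[i]])) records$quality[[i]] <- integer()
      records$offset5[i] <- records$offset5[i] + L
    } else {
      records$bases[i] <- substr(s, keep_from, keep_to)
      if (!is.null(records$quality[[i]])) {
        records$quality[[i]] <- records$quality[[i]][keep_from:keep_to]
      }
      records$offset5[i] <- records$offset5[i] + keep_from - 1L
    }
  }
  records
}

#' Drop reads shorter than a minimum length
#'
#' @param records a [bes_set()].
#' @param min_len minimum retained read length in bp (default 100); the
#'   boundary is inclusive (a 100 bp read is kept).
#' @return list with elements `kept` and `removed`, both `bes_set`s.
#' @export
filter_length <- function(records, min_len = 100L) {
  keep <- nchar(records$bases) >= min_len
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Partition reads into nuclear and organellar
#'
#' A read is organellar iff it has at least one hit with
#' `evalue <= e_cutoff` against an organelle subject.  The partition is
#' exhaustive and disjoint; hits referencing unknown reads are ignored with a
#' warning.
#'
#' @param records a [bes_set()].
#' @param hits hit table against organelle genomes (see [read_hits()]).
#' @param e_cutoff E-value cutoff (default `1e-15`).
#' @param organelle_subjects optional character vector restricting which
#'   subjects count as organellar; by default every subject in `hits` does
#'   (the table is assumed to be a search against organelle genomes only).
#' @return list with elements `nuclear` and `organellar`.
#' @export
filter_organellar <- function(records, hits, e_cutoff = 1e-15,
                              organelle_subjects = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(nuclear = records, organellar = records[0, , drop = FALSE]))
  }
  unknown <- !(hits$query_id %in% records$read_id)
  if (any(unknown)) {
    warning(sum(unknown), " hit(s) reference unknown reads and are ignored")
    hits <- hits[!unknown, , drop = FALSE]
  }
  if (!is.null(organelle_subjects)) {
    hits <- hits[hits$subject_id %in% organelle_subjects, , drop = FALSE]
  }
  org_ids <- unique(hits$query_id[hits$evalue <= e_cutoff])
  is_org <- records$read_id %in% org_ids
  list(nuclear = records[!is_org, , drop = FALSE],
       organellar = records[is_org, , drop = FALSE])
}

#' Dataset-level summary statistics
#'
#' @param records a non-empty [bes_set()].
#' @param n_organellar_removed count of reads removed as organellar upstream
#'   (carried into the summary table).
#' @return list of class `bes_dataset_stats`: read counts, paired/unpaired
#'   counts (a read is paired iff both ends of its clone are present), total
#'   and min/max/mean length (mean to 2 dp), and GC percent computed over
#'   `A+C+G+T` only (`N` excluded, 2 dp).
#' @export
summarize_dataset <- function(records, n_organellar_removed = 0L) {
  if (nrow(records) == 0L) stop_contract("empty read set")
  lens <- nchar(records$bases)
  ends_per_clone <- table(records$clone_id)
  paired_clones <- names(ends_per_clone)[ends_per_clone == 2L]
  n_paired <- sum(records$clone_id %in% paired_clones)
  base_counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(records$bases))[, c("A", "C", "G", "T"),
                                             drop = FALSE])
  gc <- pct2(base_counts[["G"]] + base_counts[["C"]], sum(base_counts))
  out <- list(n_reads = nrow(records),
              n_paired = n_paired,
              n_unpaired = nrow(records) - n_paired,
              total_bp = sum(lens),
              min_len = min(lens),
              max_len = max(lens),
              mean_len = round_half_up(sum(lens) / nrow(records), 2),
              gc_percent = gc,
              n_organellar_removed = n_organellar_removed)
  class(out) <- "bes_dataset_stats"
  out
}

#' @export
print.bes_dataset_stats <- function(x, ...) {
  cat(sprintf(paste0("BES dataset: %d reads (%d paired / %d unpaired), ",
                     "%s bp total\n  length %d-%d bp (mean %.2f), ",
                     "GC %.2f%%, organellar removed: %d\n"),
              x$n_reads, x$n_paired, x$n_unpaired,
              format(x$total_bp, big.mark = ","), x$min_len, x$max_len,
              x$mean_len, x$gc_percent, x$n_organellar_removed))
  invisible(x)
}

#' Run the full read-QC stage
#'
#' Fixed stage order: quality trim (skipped when no qualities are present)
#' -> vector screen (skipped without a vector) -> length filter -> organelle
#' filter.  Re-running the stage on its own output is idempotent.
#'
#' @param records a [bes_set()].
#' @param vector_seq optional vector sequence.
#' @param organelle_hits optional hit table against organelle genomes.
#' @param qmin,min_len,e_cutoff stage thresholds.
#' @return list with `records` (clean reads), `stats`
#'   (a [summarize_dataset()] result), `removed_short`, `organellar`, and a
#'   `counts` vector of per-stage read counts.
#' @export
qc_reads <- function(records, vector_seq = NULL, organelle_hits = NULL,
                     qmin = 20L, min_len = 100L, e_cutoff = 1e-15) {
  counts <- c(input = nrow(records))
  has_qual <- !any(vapply(records$quality, is.null, logical(1)))
  if (has_qual) records <- trim_by_quality(records, qmin = qmin)
  if (!is.null(vector_seq)) records <- screen_vector(records, vector_seq)
  lf <- filter_length(records, min_len = min_len)
  counts["after_length_filter"] <- nrow(lf$kept)
  if (!is.null(organelle_hits)) {
    ## hits against reads already dropped upstream are expected, not unknown
    organelle_hits <- organelle_hits[
      organelle_hits$query_id %in% lf$kept$read_id, , drop = FALSE]
  }
  of <- filter_organellar(lf$kept, organelle_hits, e_cutoff = e_cutoff)
  counts["organellar"] <- nrow(of$organellar)
  counts["clean"] <- nrow(of$nuclear)
  stats <- summarize_dataset(of$nuclear,
                             n_organellar_removed = nrow(of$organellar))
  list(records = of$nuclear, stats = stats, removed_short = lf$removed,
       organellar = of$organellar, counts = counts)
}
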