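## Paired-end microsynteny classification against a reference genome.
##
## A clone with a retained hit for only one end is a single-end (SE) match.
## With both ends hitting: different subjects -> PE non-colocalized; same
## subject -> span = max(subject coords) - min(subject coords) + 1, and the
## pair is collinear when the two hits are on opposite strands facing inward
## (the configuration sequencing both ends of one insert produces) with the
## span inside the insert-size bounds; wrong orientation -> rearranged;
## correct orientation with span outside the bounds -> gapped.

#' Filter reference hits on identity, length and E-value
#'
#' All three boundaries are inclusive.
#'
#' @param hits a hit table.
#' @param min_ident minimum percent identity (default 70).
#' @param min_len minimum alignment length in bp (default 50).
#' @param e_cutoff maximum E-value (default `1e-06`).
#' @return the retained hits.
#' @export
filter_hits <- function(hits, min_ident = 70, min_len = 50L,
                        e_cutoff = 1e-06) {
  keep <- hits$pct_identity >= min_ident & hits$aln_length >= min_len &
    hits$evalue <= e_cutoff
  hits[keep, , drop = FALSE]
}

#' Best hit of one query
#'
#' Maximum bitscore; ties broken by smaller E-value, then larger percent
#' identity, then lexicographically smaller subject id, then smaller
#' `s_start`, which makes the choice fully deterministic.
#'
#' @param hits hit table for a single query (at least one row).
#' @return the selected one-row hit table.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0L) stop_contract("best_hit needs at least one hit")
  ord <- order(-hits$bitscore, hits$evalue, -hits$pct_identity,
               hits$subject_id, pmin(hits$s_start, hits$s_end))
  hits[ord[1], , drop = FALSE]
}

#' Best hit per query over a whole table
#' @param hits a hit table.
#' @return hit table with one row per distinct query.
#' @export
best_hits_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  out <- do.call(rbind, lapply(split(hits, hits$query_id), best_hit))
  rownames(out) <- NULL
  out
}

subject_lo <- function(h) min(h$s_start, h$s_end)
subject_hi <- function(h) max(h$s_start, h$s_end)

#' Classify one clone's pair of end hits
#'
#' @param fwd_hit,rev_hit one-row hit tables for the two ends (either may be
#'   `NULL`/empty, but not both).
#' @param span_min,span_max subject-span bounds in bp for the collinear
#'   category (defaults 15 and 350 kb, the observed clone insert range).
#' @return list of class `synteny_pair` with `category` (one of `SE`,
#'   `PE_non_colocalized`, `PE_collinear`, `PE_rearranged`, `PE_gapped`),
#'   `subject` and `span` (bp, colocalized pairs only).
#' @export
classify_pair <- function(fwd_hit = NULL, rev_hit = NULL,
                          span_min = 15e3, span_max = 350e3) {
  has <- function(h) !is.null(h) && nrow(h) > 0L
  if (!has(fwd_hit) && !has(rev_hit)) {
    stop_contract("classify_pair needs at least one hit")
  }
  if (xor(has(fwd_hit), has(rev_hit))) {
    h <- if (has(fwd_hit)) fwd_hit else rev_hit
    out <- list(category = "SE", subject = h$subject_id, span = NA_real_)
  } else if (fwd_hit$subject_id != rev_hit$subject_id) {
    out <- list(category = "PE_non_colocalized", subject = NA_character_,
                span = NA_real_)
  } else {
    span <- max(subject_hi(fwd_hit), subject_hi(rev_hit)) -
      min(subject_lo(fwd_hit), subject_lo(rev_hit)) + 1
    opposite <- fwd_hit$strand != rev_hit$strand
    inward <- FALSE
    if (opposite) {
      plus <- if (fwd_hit$strand == "+") fwd_hit else rev_hit
      minus <- if (fwd_hit$strand == "+") rev_hit else fwd_hit
      inward <- subject_lo(plus) <= subject_lo(minus) &&
        subject_hi(plus) <= subject_hi(minus)
    }
    cat <- if (!opposite || !inward) {
      "PE_rearranged"
    } else if (span >= span_min && span <= span_max) {
      "PE_collinear"
    } else {
      "PE_gapped"
    }
    out <- list(category = cat, subject = fwd_hit$subject_id, span = span)
  }
  class(out) <- "synteny_pair"
  out
}

#' Pair clone ends and classify every clone
#'
#' Selects one best hit per end (unless `best = FALSE`, in which case the
#' table must already hold one hit per end), groups hits by clone via the
#' read-id convention, and classifies each clone with [classify_pair()].
#'
#' @param hits filtered hit table whose query ids follow the `F`/`R` clone
#'   convention.
#' @param span_min,span_max passed to [classify_pair()].
#' @param best apply [best_hits_per_query()] first (default `TRUE`).
#' @param id_pattern regex parsing query ids into direction and clone id.
#' @return data frame with one row per clone: `clone_id`, `category`,
#'   `subject`, `span`.
#' @export
classify_clone_pairs <- function(hits, span_min = 15e3, span_max = 350e3,
                                 best = TRUE, id_pattern = "^([FR])(.+)$") {
  if (best) hits <- best_hits_per_query(hits)
  m <- regmatches(hits$query_id, regexec(id_pattern, hits$query_id))
  ok <- lengths(m) == 3L
  if (!all(ok)) {
    warning(sum(!ok), " hit(s) with unparseable query id dropped")
    hits <- hits[ok, , drop = FALSE]
    m <- m[ok]
  }
  dir <- vapply(m, `[`, "", 2L)
  clone <- vapply(m, `[`, "", 3L)
  rows <- lapply(split(seq_len(nrow(hits)), clone), function(ix) {
    fwd <- hits[ix[dir[ix] == "F"], , drop = FALSE]
    rev <- hits[ix[dir[ix] == "R"], , drop = FALSE]
    cp <- classify_pair(if (nrow(fwd)) fwd[1, , drop = FALSE] else NULL,
                        if (nrow(rev)) rev[1, , drop = FALSE] else NULL,
                        span_min = span_min, span_max = span_max)
    data.frame(clone_id = clone[ix][1], category = cp$category,
               subject = cp$subject, span = cp$span,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize pair classifications
#' @param pairs result of [classify_clone_pairs()].
#' @return named integer vector of category counts (all five categories).
#' @export
synteny_summary <- function(pairs) {
  lv <- c("SE", "PE_non_colocalized", "PE_collinear", "PE_rearranged",
          "PE_gapped")
  table(factor(pairs$category, levels = lv))
}

#' Reference-match coverage
#'
#' @param hits filtered hit table.
#' @param by `"query"` (union of query-side intervals per read, the
#'   cumulative match length) or `"subject"` (union of subject-side intervals
#'   per reference sequence).
#' @return list with `n_queries_matched`, `n_subjects_matched`, `union_bp`.
#' @export
reference_coverage <- function(hits, by = c("query", "subject")) {
  by <- match.arg(by)
  if (by == "query") {
    ubp <- union_match_length(hits)
  } else if (nrow(hits) == 0L) {
    ubp <- 0L
  } else {
    ubp <- sum(vapply(split(hits, hits$subject_id), function(s) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(pmin(s$s_start, s$s_end),
                         pmax(s$s_start, s$s_end)))))
    }, integer(1)))
  }
  list(n_queries_matched = length(unique(hits$query_id)),
       n_subjects_matched = length(unique(hits$subject_id)),
       union_bp = ubp)
}
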