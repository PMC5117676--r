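## Microsatellite (SSR) mining.
##
## Detection thresholds follow the common survey convention: a mononucleotide
## run must reach 20 bp, di- through hexanucleotide repeats must reach 15 bp
## of whole units (so >=8 di, >=5 tri, >=4 tetra, >=3 penta, >=3 hexa units).
## Runs are maximal, whole-unit, left-anchored; the smallest primitive unit
## wins where a region qualifies at several unit lengths; N breaks runs.

default_ssr_min_len <- function() c(`1` = 20L, `2` = 15L, `3` = 15L,
                                    `4` = 15L, `5` = 15L, `6` = 15L)

ssr_locus_columns <- c("seq_id", "start", "end", "motif", "canonical_motif",
                       "motif_class", "unit_len", "n_units", "kind",
                       "length_class", "members")

empty_ssr_loci <- function() {
  df <- data.frame(seq_id = character(), start = integer(), end = integer(),
                   motif = character(), canonical_motif = character(),
                   motif_class = character(), unit_len = integer(),
                   n_units = integer(), kind = character(),
                   length_class = character(), members = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("ssr_loci", "data.frame")
  df
}

as_ssr_loci <- function(df) {
  if (nrow(df) == 0L) return(empty_ssr_loci())
  df <- as.data.frame(df)[ssr_locus_columns]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$unit_len <- as.integer(df$unit_len)
  df$n_units <- as.integer(df$n_units)
  for (cc in c("seq_id", "motif", "canonical_motif", "motif_class", "kind",
               "length_class", "members")) {
    df[[cc]] <- as.character(df[[cc]])
  }
  rownames(df) <- NULL
  class(df) <- c("ssr_loci", "data.frame")
  df
}

#' Canonical motif under rotation and strand equivalence
#'
#' The canonical unit of a motif is the lexicographically smallest string
#' among all rotations of the motif and all rotations of its reverse
#' complement, so that e.g. `TC`, `CT`, `GA` and `AG` all canonicalize to
#' `AG`.  The motif class label is rendered `"X/Y"` where `X` is the canonical
#' unit and `Y` the canonical unit of its reverse complement (`"AG/CT"`,
#' `"AAT/ATT"`, `"AT/AT"`).
#'
#' @param motif character vector of primitive motifs of length 1-6.
#' @return for [standardize_motif()], the canonical unit(s); for
#'   [motif_class()], the `"X/Y"` class label(s).
#' @export
standardize_motif <- function(motif) {
  vapply(motif, function(m) {
    if (nchar(m) < 1L || nchar(m) > 6L) {
      stop_contract("motif length must be 1-6: ", m)
    }
    if (!is_primitive_motif(m)) {
      stop_contract("motif is not primitive: ", m)
    }
    min(c(rotations(m), rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname standardize_motif
#' @export
motif_class <- function(motif) {
  x <- standardize_motif(motif)
  y <- vapply(x, function(cm) min(rotations(revcomp(cm))), character(1),
              USE.NAMES = FALSE)
  paste(x, y, sep = "/")
}

## maximal tandem runs of period k in a character vector; returns candidate
## loci as a list of (start, end, unit, k, n_units)
tandem_candidates <- function(x, min_len) {
  L <- length(x)
  valid <- x %in% c("A", "C", "G", "T")
  out <- vector("list", 64L)
  n_out <- 0L
  for (k in 1:6) {
    if (L < 2L * k) next
    idx <- seq_len(L - k)
    eq <- (x[idx] == x[idx + k]) & valid[idx] & valid[idx + k]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- r$lengths[j] + k          # length of the maximal period-k region
      n <- span %/% k
      if (k * n < min_len[[k]] || n < 2L) next
      i <- starts[j]
      unit <- paste(x[i:(i + k - 1L)], collapse = "")
      if (!is_primitive_motif(unit)) next
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- c(start = i, end = i + k * n - 1L, k = k, n = n)
      names(out)[n_out] <- unit
    }
  }
  out[seq_len(n_out)]
}

## resolve overlapping candidates: sort by (start, unit_len) and keep greedily
resolve_candidates <- function(cand) {
  if (!length(cand)) return(cand)
  starts <- vapply(cand, `[[`, 0L, "start")
  ks <- vapply(cand, `[[`, 0L, "k")
  ord <- order(starts, ks)
  cand <- cand[ord]
  keep <- logical(length(cand))
  last_end <- 0L
  for (i in seq_along(cand)) {
    if (cand[[i]][["start"]] > last_end) {
      keep[i] <- TRUE
      last_end <- cand[[i]][["end"]]
    }
  }
  cand[keep]
}

#' Detect perfect SSRs in a sequence or read set
#'
#' Finds maximal, non-overlapping tandem runs of a primitive 1-6 bp unit whose
#' whole-unit length reaches the per-unit-length minimum (`min_len`), left to
#' right.  Partial trailing units are excluded, the smallest primitive unit
#' wins on ambiguous runs (a poly-A run is reported as `(A)n`, never `(AA)n`),
#' and `N` breaks runs.
#'
#' @param x a [bes_set()] or a character vector of sequences (optionally
#'   named; names become `seq_id`).
#' @param min_len named integer vector mapping unit length (`"1"`..`"6"`) to
#'   the minimum total SSR length in bp; default `c(20,15,15,15,15,15)`.
#' @return an `ssr_loci` data frame of perfect loci with canonical motifs and
#'   length classes (`I` for spans >= 20 bp, else `II`).
#' @export
find_perfect_ssrs <- function(x, min_len = default_ssr_min_len()) {
  if (inherits(x, "bes_set")) {
    seqs <- stats::setNames(x$bases, x$read_id)
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  min_len <- as.integer(min_len)
  if (length(min_len) != 6L) stop_contract("min_len must map unit lengths 1-6")
  res <- lapply(seq_along(seqs), function(si) {
    xx <- strsplit(seqs[[si]], "", fixed = TRUE)[[1]]
    cand <- resolve_candidates(tandem_candidates(xx, min_len))
    if (!length(cand)) return(NULL)
    data.frame(seq_id = names(seqs)[si],
               start = vapply(cand, `[[`, 0L, "start"),
               end = vapply(cand, `[[`, 0L, "end"),
               motif = names(cand),
               unit_len = vapply(cand, `[[`, 0L, "k"),
               n_units = vapply(cand, `[[`, 0L, "n"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  if (is.null(df)) return(empty_ssr_loci())
  df$canonical_motif <- standardize_motif(df$motif)
  df$motif_class <- motif_class(df$motif)
  df$kind <- "perfect"
  df$length_class <- ifelse(df$end - df$start + 1L >= 20L, "I", "II")
  df$members <- NA_character_
  as_ssr_loci(df)
}

#' Merge nearby perfect SSRs into compound loci
#'
#' Maximal chains of perfect SSRs on one sequence whose successive gaps are
#' `<= max_gap` bp become a single compound locus spanning the first start to
#' the last end; singletons stay perfect.  Merging is transitive: a chain
#' A-B-C with both gaps within `max_gap` is one compound locus with three
#' members.
#'
#' @param loci an `ssr_loci` table of perfect loci (sorted, non-overlapping,
#'   as produced by [find_perfect_ssrs()]).
#' @param max_gap maximum gap in bp between members of a compound SSR.
#' @return an `ssr_loci` table mixing perfect and compound rows.
#' @export
merge_compound <- function(loci, max_gap = 100L) {
  if (nrow(loci) == 0L) return(loci)
  out <- lapply(split(seq_len(nrow(loci)), loci$seq_id), function(ix) {
    sub <- loci[ix[order(loci$start[ix])], ]
    gaps <- sub$start[-1] - sub$end[-nrow(sub)] - 1L
    chain <- cumsum(c(0L, as.integer(gaps > max_gap)))
    do.call(rbind, lapply(split(seq_len(nrow(sub)), chain), function(ci) {
      grp <- sub[ci, ]
      if (nrow(grp) == 1L) return(grp)
      members <- paste(sprintf("(%s)%d@%d-%d", grp$motif, grp$n_units,
                               grp$start, grp$end), collapse = ",")
      data.frame(seq_id = grp$seq_id[1],
                 start = grp$start[1], end = grp$end[nrow(grp)],
                 motif = NA_character_, canonical_motif = NA_character_,
                 motif_class = NA_character_,
                 unit_len = NA_integer_, n_units = NA_integer_,
                 kind = "compound", length_class = NA_character_,
                 members = members, stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, out)
  df <- df[order(df$seq_id, df$start), ]
  as_ssr_loci(df)
}

#' Length class of perfect SSRs
#'
#' Class I: total span >= 20 bp; Class II: 10-19 bp.  Length classes apply to
#' perfect SSRs only; passing a compound locus is an error.
#'
#' @param loci an `ssr_loci` table.
#' @return character vector of `"I"`/`"II"`.
#' @export
classify_length <- function(loci) {
  if (any(loci$kind != "perfect")) {
    stop_contract("length classes apply to perfect SSRs only")
  }
  ifelse(loci$end - loci$start + 1L >= 20L, "I", "II")
}

count_members <- function(members) {
  lengths(strsplit(members, ",", fixed = TRUE))
}

#' Summarize an SSR scan
#'
#' @param loci an `ssr_loci` table (after [merge_compound()]; a table of only
#'   perfect loci is also accepted).
#' @param total_bp total bp scanned, used for the density.
#' @return list with counts by unit length (and % of all loci), counts by
#'   canonical motif class, the perfect/compound and Class I/II splits, and
#'   the density expressed as one SSR per `total_bp / n_loci / 1000` kb
#'   (2 dp).  With zero loci the density is `NA`.
#' @export
ssr_summary <- function(loci, total_bp) {
  if (total_bp <= 0) stop_contract("total_bp must be positive")
  n <- nrow(loci)
  perfect <- loci[loci$kind == "perfect", ]
  by_unit <- table(factor(perfect$unit_len, levels = 1:6))
  names(by_unit) <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  by_class <- sort(table(perfect$motif_class), decreasing = TRUE)
  list(
    n_ssrs = n,
    n_perfect = nrow(perfect),
    n_compound = n - nrow(perfect),
    by_unit_len = as.integer(by_unit),
    by_unit_len_pct = if (nrow(perfect)) pct2(as.integer(by_unit), nrow(perfect))
                      else rep(NA_real_, 6L),
    unit_len_labels = names(by_unit),
    by_motif_class = by_class,
    n_class_I = sum(perfect$length_class == "I"),
    n_class_II = sum(perfect$length_class == "II"),
    density_kb = if (n > 0L) round_half_up(total_bp / n / 1000, 2) else NA_real_
  )
}
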