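## Repeat-element census and library masking.
##
## Census semantics: element counts are plain annotation counts (not merged);
## masked bp use interval union, within each class per read for class rows
## and across ALL classes per read for the grand-total row (so the total can
## be smaller than the column sum when classes overlap on the same bases).

#' Aggregate repeat annotations into a hierarchical census
#'
#' One census row per taxonomy node plus the derived rows
#' `"Total interspersed repeats"` (Class I + Class II + Unclassified) and
#' `"Total repetitive DNA"` (everything, cross-class union).  For each node:
#' `n_elements` = number of annotations in its subtree, `masked_bp` = summed
#' per-read interval union over the subtree, `pct_of_total` =
#' `100 * masked_bp / total_bp` (2 dp, half-up).
#'
#' @param annotations a [repeat_annotations()] table.
#' @param taxonomy a repeat taxonomy (default [default_repeat_taxonomy()]).
#' @param total_bp total bp of the read set surveyed.
#' @return data frame of class `repeat_census` with columns `class_path`,
#'   `n_elements`, `masked_bp`, `pct_of_total`.
#' @export
build_census <- function(annotations, taxonomy = default_repeat_taxonomy(),
                         total_bp) {
  if (missing(total_bp) || total_bp <= 0) {
    stop_contract("total_bp must be positive")
  }
  unknown <- !(annotations$class_path %in% taxonomy)
  if (any(unknown)) {
    warning(sum(unknown), " annotation(s) with unknown class_path counted ",
            "as 'Unclassified'")
    annotations$class_path[unknown] <- "Unclassified"
  }
  union_bp <- function(sub) {
    if (nrow(sub) == 0L) return(0L)
    sum(vapply(split(sub, sub$query_id), function(q) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(q$q_start, q$q_end))))
    }, integer(1)))
  }
  node_row <- function(path, sub) {
    data.frame(class_path = path, n_elements = nrow(sub),
               masked_bp = union_bp(sub),
               pct_of_total = pct2(union_bp(sub), total_bp),
               stringsAsFactors = FALSE)
  }
  in_subtree <- function(path) {
    annotations$class_path == path |
      startsWith(annotations$class_path, paste0(path, "|"))
  }
  rows <- lapply(taxonomy, function(p) {
    node_row(p, annotations[in_subtree(p), , drop = FALSE])
  })
  interspersed_roots <- c("Class I retrotransposon", "Class II DNA transposons",
                          "Unclassified")
  inter_sel <- Reduce(`|`, lapply(intersect(interspersed_roots, taxonomy),
                                  in_subtree),
                      rep(FALSE, nrow(annotations)))
  rows <- c(rows,
            list(node_row("Total interspersed repeats",
                          annotations[inter_sel, , drop = FALSE]),
                 node_row("Total repetitive DNA", annotations)))
  out <- do.call(rbind, rows)
  class(out) <- c("repeat_census", "data.frame")
  out
}

#' Share of one census row within another
#'
#' E.g. the Class I fraction of total repetitive DNA, or the LTR fraction of
#' all retrotransposons, recomputed from the stored census bp.
#'
#' @param census a [build_census()] result (or any data frame with
#'   `class_path` and `masked_bp`).
#' @param numerator,denominator class paths present in the census.
#' @return percentage (2 dp, half-up).
#' @export
census_share <- function(census, numerator, denominator) {
  bp <- function(p) {
    i <- match(p, census$class_path)
    if (is.na(i)) stop_contract("class path not in census: ", p)
    census$masked_bp[i]
  }
  pct2(bp(numerator), bp(denominator))
}

#' Mask reads with a repeat library
#'
#' Runs the package's seed-and-extend matcher (see [find_matches()]) for each
#' library family against each read on both strands; matched read intervals
#' become annotations (default `source = "novel"`) and the matched bases are
#' replaced by `N` in the returned reads.  Masking already-masked sequence is
#' a no-op, so known and novel masked bp stay disjoint when novel masking is
#' run on known-masked reads.
#'
#' @param records a [bes_set()].
#' @param library named character vector of family sequences.
#' @param min_match minimum match length in bp (default 50).
#' @param min_ident minimum percent identity (default 80).
#' @param class_paths optional named character vector mapping family name to
#'   a taxonomy class path; unmapped families become `"Unclassified"`.
#' @param source annotation source label (default `"novel"`).
#' @param taxonomy taxonomy for validation.
#' @return list with `annotations` (a [repeat_annotations()] table) and
#'   `records` (the masked `bes_set`).
#' @export
mask_with_library <- function(records, library, min_match = 50L,
                              min_ident = 80, class_paths = NULL,
                              source = "novel",
                              taxonomy = default_repeat_taxonomy()) {
  if (!length(library)) stop_contract("library must be non-empty")
  idx <- build_seed_index(library)
  anns <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    s <- records$bases[i]
    if (!nzchar(s)) next
    m <- find_matches(s, idx, min_match = min_match, min_ident = min_ident)
    if (!nrow(m)) next
    cp <- if (is.null(class_paths)) rep("Unclassified", nrow(m)) else {
      cpv <- unname(class_paths[m$family])
      cpv[is.na(cpv)] <- "Unclassified"
      cpv
    }
    anns[[i]] <- data.frame(query_id = records$read_id[i],
                            q_start = m$q_start, q_end = m$q_end,
                            class_path = cp, family = m$family,
                            stringsAsFactors = FALSE)
    records$bases[i] <- mask_string(s, m$q_start, m$q_end)
  }
  anns <- do.call(rbind, anns)
  annotations <- if (is.null(anns)) empty_repeat_annotations() else {
    repeat_annotations(anns$query_id, anns$q_start, anns$q_end,
                       anns$class_path, anns$family, source,
                       taxonomy = taxonomy)
  }
  list(annotations = annotations, records = records)
}

#' Apply precomputed repeat annotations as a mask
#'
#' Replaces every annotated interval with `N` (used when masking tables come
#' from an external masker rather than [mask_with_library()]).
#'
#' @param records a [bes_set()].
#' @param annotations a [repeat_annotations()] table in read coordinates.
#' @return the masked `bes_set`.
#' @export
mask_annotations <- function(records, annotations) {
  if (nrow(annotations) == 0L) return(records)
  by_read <- split(annotations, annotations$query_id)
  for (id in names(by_read)) {
    i <- match(id, records$read_id)
    if (is.na(i)) next
    a <- by_read[[id]]
    records$bases[i] <- mask_string(records$bases[i], a$q_start, a$q_end)
  }
  records
}

#' Combine known and novel repeat percentages
#'
#' The survey convention adds the two already-rounded component percentages
#' (known-library masking plus novel-library masking, computed on disjoint
#' bases because novel masking runs on known-masked sequence).
#'
#' @param known_pct,novel_pct percentages on the 0-100 scale.
#' @return their sum.
#' @export
total_repeat_fraction <- function(known_pct, novel_pct) {
  stopifnot(known_pct >= 0, novel_pct >= 0)
  s <- known_pct + novel_pct
  if (s > 100) stop_contract("combined repeat fraction exceeds 100%")
  s
}
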