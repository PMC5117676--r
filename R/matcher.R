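## Lightweight seed-and-extend sequence matcher.
##
## This is the package's own gap-free local matcher used for vector screening
## and repeat-library masking of Sanger-style end reads.  It is deliberately
## simple: exact seed words shared between read and library are extended in
## both directions without gaps under an x-drop rule (match +1, mismatch -2,
## x-drop 20).  It is NOT a CROSS_MATCH or RepeatMasker replacement for real
## data -- externally produced masking/hit tables can be supplied to every
## downstream step instead -- but it is deterministic and sufficient for
## substitution-diverged copies, which is what the simulator plants.

MATCH_SCORE <- 1L
MISMATCH_SCORE <- -2L
XDROP <- 20L

## best gap-free extension of two character vectors a (from ai) and b (from
## bi), moving right by +1 steps; returns c(len, matches) of the best prefix.
## Candidate endpoints are restricted to prefixes whose own identity stays at
## min_ident, so a chance low-identity continuation past the true end of a
## match cannot drag the accepted segment below threshold.
extend_right <- function(a, ai, b, bi, min_ident = 0) {
  n <- min(length(a) - ai + 1L, length(b) - bi + 1L)
  if (n <= 0L) return(c(0L, 0L))
  av <- a[ai:(ai + n - 1L)]
  bv <- b[bi:(bi + n - 1L)]
  eq <- av == bv & av != "N"
  sc <- cumsum(ifelse(eq, MATCH_SCORE, MISMATCH_SCORE))
  run_best <- cummax(sc)
  drop_at <- which(run_best - sc > XDROP)
  lim <- if (length(drop_at)) drop_at[1] - 1L else n
  if (lim == 0L) return(c(0L, 0L))
  t <- seq_len(lim)
  cm <- cumsum(eq)[t]
  ok <- t[100 * cm / t >= min_ident]
  if (!length(ok)) return(c(0L, 0L))
  best <- ok[which.max(sc[ok])]
  c(best, cm[match(best, t)])
}

#' Build a seed index for a sequence library
#'
#' @param library named character vector of library sequences (e.g. repeat
#'   families or a cloning vector).
#' @param seed_width exact-match word size used for seeding.
#' @return an index object consumed by [find_matches()].
#' @export
build_seed_index <- function(library, seed_width = 12L) {
  stopifnot(length(library) > 0L, all(nzchar(library)))
  library <- normalize_bases(library)
  entries <- list()
  chars <- list()
  for (fam in names(library)) {
    for (st in c("+", "-")) {
      s <- if (st == "+") library[[fam]] else revcomp(library[[fam]])
      L <- nchar(s)
      key <- paste0(fam, st)
      chars[[key]] <- strsplit(s, "", fixed = TRUE)[[1]]
      if (L < seed_width) next
      pos <- seq_len(L - seed_width + 1L)
      entries[[key]] <- data.frame(
        kmer = substring(s, pos, pos + seed_width - 1L),
        fam = fam, strand = st, pos = pos, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, entries)
  tab <- tab[!grepl("N", tab$kmer, fixed = TRUE), ]
  list(seed_width = seed_width,
       kmer_map = split(seq_len(nrow(tab)), tab$kmer),
       tab = tab, chars = chars)
}

#' Find gap-free local matches of a library in one read
#'
#' Seeds are exact `seed_width`-mers shared between the read and either
#' strand of a library sequence; each seed is extended without gaps under the
#' x-drop rule and kept if it reaches `min_match` bp at `min_ident` percent
#' identity.  Overlapping accepted matches on the read are merged per family.
#'
#' @param read a single sequence string.
#' @param index a [build_seed_index()] object.
#' @param min_match minimum match length in bp.
#' @param min_ident minimum percent identity.
#' @return data frame with columns `q_start`, `q_end`, `family`, `strand`,
#'   `pct_identity`, `length` (possibly empty).
#' @export
find_matches <- function(read, index, min_match = 50L, min_ident = 80) {
  w <- index$seed_width
  L <- nchar(read)
  empty <- data.frame(q_start = integer(), q_end = integer(),
                      family = character(), strand = character(),
                      pct_identity = numeric(), length = integer(),
                      stringsAsFactors = FALSE)
  if (L < w) return(empty)
  rx <- strsplit(read, "", fixed = TRUE)[[1]]
  pos <- seq_len(L - w + 1L)
  rk <- substring(read, pos, pos + w - 1L)
  hit_rows <- index$kmer_map[rk]
  seeded <- which(!vapply(hit_rows, is.null, logical(1)))
  if (!length(seeded)) return(empty)
  res <- list()
  ## per (family, strand): covered read intervals already explained, so each
  ## repeat copy costs one extension, not one per seed word
  covered <- list()
  for (i in seeded) {
    for (row in hit_rows[[i]]) {
      fam <- index$tab$fam[row]
      st <- index$tab$strand[row]
      key <- paste0(fam, st)
      cov <- covered[[key]]
      if (!is.null(cov) &&
          any(i >= cov$q_start & (i + w - 1L) <= cov$q_end)) next
      fx <- index$chars[[key]]
      j <- index$tab$pos[row]
      rgt <- extend_right(rx, i + w, fx, j + w, min_ident)
      lft <- extend_right(rev(rx), L - i + 2L, rev(fx), length(fx) - j + 2L,
                          min_ident)
      q_start <- i - lft[1]
      q_end <- i + w - 1L + rgt[1]
      len <- q_end - q_start + 1L
      nmatch <- w + lft[2] + rgt[2]
      ident <- 100 * nmatch / len
      if (len >= min_match && ident >= min_ident) {
        seg <- data.frame(q_start = q_start, q_end = q_end,
                          family = fam, strand = st,
                          pct_identity = round(ident, 2), length = len,
                          stringsAsFactors = FALSE)
        res[[length(res) + 1L]] <- seg
        covered[[key]] <- rbind(cov, seg[c("q_start", "q_end")])
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  ## merge overlapping accepted matches per family
  merged <- lapply(split(out, out$family), function(sub) {
    ir <- IRanges::reduce(IRanges::IRanges(sub$q_start, sub$q_end))
    data.frame(q_start = IRanges::start(ir), q_end = IRanges::end(ir),
               family = sub$family[1],
               strand = sub$strand[which.max(sub$length)],
               pct_identity = round(stats::weighted.mean(sub$pct_identity,
                                                         sub$length), 2),
               length = IRanges::width(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$q_start, out$q_end), ]
  rownames(out) <- NULL
  out
}

## replace intervals of a string with N
mask_string <- function(s, starts, ends) {
  if (!length(starts)) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_along(starts)) x[starts[i]:ends[i]] <- "N"
  paste(x, collapse = "")
}
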