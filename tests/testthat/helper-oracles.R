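# Independent oracles used by the property and acceptance tests.  They share
# no code with the package internals they check.

# Brute-force SSR oracle: tests every (start, unit length) candidate by
# direct whole-unit substring comparison, then applies the documented
# selection rule (smallest primitive unit wins; loci non-overlapping, left
# to right).
brute_force_ssrs <- function(seq, min_len = c(20L, 15L, 15L, 15L, 15L, 15L)) {
  L <- nchar(seq)
  is_prim <- function(u) {
    k <- nchar(u)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L && strrep(substr(u, 1L, d), k %/% d) == u) return(FALSE)
    }
    TRUE
  }
  cand <- list()
  for (k in 1:6) {
    if (L < 2L * k) next
    s <- seq_len(L - k + 1L)
    unit <- substring(seq, s, s + k - 1L)
    uu <- unique(unit)
    prim_ok <- stats::setNames(
      vapply(uu, is_prim, logical(1)) & !grepl("N", uu, fixed = TRUE), uu)
    alive <- which(prim_ok[unit])
    n <- rep(1L, length(s))
    j <- 1L
    while (length(alive)) {
      e <- s[alive] + (j + 1L) * k - 1L
      ok <- e <= L &
        substring(seq, s[alive] + j * k, e) == unit[alive]
      n[alive[ok]] <- j + 1L
      alive <- alive[ok]
      j <- j + 1L
    }
    q <- which(k * n >= min_len[k] & n >= 2L)
    for (i in q) {
      cand[[length(cand) + 1L]] <- data.frame(
        start = s[i], end = s[i] + k * n[i] - 1L, motif = unit[i],
        unit_len = k, n_units = n[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit_len = integer(), n_units = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, cand)
  df <- df[order(df$start, df$unit_len), ]
  keep <- logical(nrow(df))
  last_end <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- df$end[i]
    }
  }
  df <- df[keep, ]
  rownames(df) <- NULL
  df
}

# per-base interval union oracle
per_base_union <- function(starts, ends, L = max(ends)) {
  covered <- logical(L)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  sum(covered)
}

# Monte-Carlo Clarke-Carbon: sample clone start positions on a linear toy
# genome and ask how often a fixed single-copy locus is captured.
mc_single_copy <- function(n_clones, insert, genome_size, reps) {
  locus <- genome_size / 2
  hits <- vapply(seq_len(reps), function(r) {
    starts <- runif(n_clones, 1, genome_size - insert + 1)
    any(starts <= locus & starts + insert - 1 >= locus)
  }, logical(1))
  mean(hits)
}

random_dna <- function(n, gc = 0.38) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_hit_table <- function(n, n_queries = 3, qlen = 1000) {
  qs <- sample(paste0("q", seq_len(n_queries)), n, replace = TRUE)
  a <- sample.int(qlen - 10L, n, replace = TRUE)
  b <- pmin(qlen, a + sample.int(200L, n, replace = TRUE))
  as_hits(data.frame(query_id = qs, subject_id = "s1",
                     pct_identity = round(runif(n, 60, 100), 1),
                     aln_length = b - a + 1L, mismatches = 0L, gap_opens = 0L,
                     q_start = a, q_end = b, s_start = a, s_end = b,
                     evalue = 10^-runif(n, 1, 50), bitscore = runif(n, 40, 400),
                     stringsAsFactors = FALSE))
}

# one-row reference hit for pair-classification tests
ref_hit <- function(query_id, subject_id, s_lo, s_hi, strand,
                    len = s_hi - s_lo + 1L) {
  as_hits(data.frame(query_id = query_id, subject_id = subject_id,
                     pct_identity = 95, aln_length = len, mismatches = 0L,
                     gap_opens = 0L, q_start = 1L, q_end = len,
                     s_start = if (strand == "+") s_lo else s_hi,
                     s_end = if (strand == "+") s_hi else s_lo,
                     evalue = 1e-50, bitscore = 2 * len,
                     stringsAsFactors = FALSE))
}
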