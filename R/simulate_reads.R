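## BAC clone library and end-read simulation on a toy genome, with per-read
## truth expectations and truth-derived hit tables.

truncated_lognormal <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rlnorm(2L * n, meanlog, sdlog)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  round(out[seq_len(n)])
}

truncated_normal <- function(n, mean, sd, lo, hi) {
  out <- round(stats::rnorm(n, mean, sd))
  pmin(pmax(out, lo), hi)
}

## two-state good/bad quality chain along a read
markov_quality <- function(len, cfg) {
  bad <- logical(len)
  state <- stats::runif(1) < cfg$p_bad_start
  for (i in seq_len(len)) {
    bad[i] <- state
    p <- if (state) 1 - cfg$p_bad_to_good else cfg$p_good_to_bad
    state <- stats::runif(1) < p
  }
  ifelse(bad, cfg$q_bad, cfg$q_good)
}

## map a genome interval [s2, e2] into read-local coordinates for a read
## covering genome [a, b]; fwd reads keep orientation, rev reads (which store
## the reverse complement) flip it
to_local <- function(s2, e2, a, b, direction) {
  if (direction == "forward") c(s2 - a + 1L, e2 - a + 1L)
  else c(b - e2 + 1L, b - s2 + 1L)
}

#' Simulate BAC end reads from a toy genome
#'
#' Per clone an insert is sampled from the truncated lognormal model and
#' placed uniformly; the forward read copies the insert's left end on the
#' plus strand and the reverse read the right end on the minus strand (inward
#' orientation).  A configured fraction of clones yield only the forward
#' read; reads are replaced by organelle fragments at the contamination rate;
#' vector tails are prepended at the vector rate; qualities follow the
#' configured model.  Truth tables record every read's genomic extent, the
#' per-read SSR and repeat-interval expectations (accounting for read-edge
#' clipping of planted loci), and truth-derived hit tables (organelle,
#' reference genome, gene fragments; E-value `1e-180`) so downstream filters
#' can be exercised without an aligner.
#'
#' @param sim a [simulate_genome()] result.
#' @param min_len SSR thresholds used to decide which (possibly clipped)
#'   planted loci remain detectable within a read.
#' @return list of class `bes_sim`: `records` (a [bes_set()]), `truth`
#'   (`reads`, `clones`, `expected_ssrs`, `expected_repeats`, and `hits`),
#'   plus the genome truth, components and config.
#' @export
simulate_bes <- function(sim, min_len = default_ssr_min_len()) {
  stopifnot(inherits(sim, "bes_sim_genome"))
  cfg <- sim$config
  set.seed(sim$stage_seeds[2])
  G <- cfg$genome_size
  n <- cfg$n_clones
  clone_id <- sprintf("%04d", seq_len(n))
  insert <- truncated_lognormal(n, cfg$insert_meanlog, cfg$insert_sdlog,
                                cfg$insert_min, cfg$insert_max)
  insert <- pmin(insert, G - 1L)
  a0 <- floor(stats::runif(n, 1, G - insert + 1))
  clones <- data.frame(clone_id = clone_id, insert_start = as.integer(a0),
                       insert_end = as.integer(a0 + insert - 1),
                       insert_size = as.integer(insert),
                       both_ends = stats::runif(n) >= cfg$unpaired_fraction,
                       stringsAsFactors = FALSE)

  reads <- data.frame(read_id = character(), clone_id = character(),
                      direction = character(), g_start = integer(),
                      g_end = integer(), stringsAsFactors = FALSE)
  for (dir in c("forward", "reverse")) {
    sel <- if (dir == "forward") rep(TRUE, n) else clones$both_ends
    rl <- truncated_normal(sum(sel), cfg$read_len_mean, cfg$read_len_sd,
                           cfg$read_len_min, cfg$read_len_max)
    cl <- clones[sel, ]
    gs <- if (dir == "forward") cl$insert_start else cl$insert_end - rl + 1L
    ge <- if (dir == "forward") cl$insert_start + rl - 1L else cl$insert_end
    reads <- rbind(reads, data.frame(
      read_id = paste0(ifelse(dir == "forward", "F", "R"), cl$clone_id),
      clone_id = cl$clone_id, direction = dir,
      g_start = as.integer(gs), g_end = as.integer(ge),
      stringsAsFactors = FALSE))
  }
  reads <- reads[order(reads$clone_id, reads$direction), ]
  rownames(reads) <- NULL

  ## contamination stream
  set.seed(sim$stage_seeds[4])
  reads$organellar <- stats::runif(nrow(reads)) < cfg$contamination
  org_source <- sample(names(sim$components$organelles), nrow(reads),
                       replace = TRUE)
  reads$vector_len <- ifelse(stats::runif(nrow(reads)) < cfg$vector_rate,
                             cfg$vector_prefix_len, 0L)

  ## assemble bases (insert part only, pre-vector)
  bases <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    if (reads$organellar[i]) {
      os <- sim$components$organelles[[org_source[i]]]
      rl <- reads$g_end[i] - reads$g_start[i] + 1L
      p <- sample.int(nchar(os) - rl + 1L, 1L)
      bases[i] <- substr(os, p, p + rl - 1L)
      reads$g_start[i] <- NA_integer_
      reads$g_end[i] <- NA_integer_
    } else {
      s <- substr(sim$genome, reads$g_start[i], reads$g_end[i])
      bases[i] <- if (reads$direction[i] == "forward") s else revcomp(s)
    }
  }

  ## truth-derived hit tables
  mk_hits <- function(query_id, subject_id, q_start, q_end, s_start, s_end) {
    len <- abs(q_end - q_start) + 1L
    as_hits(data.frame(query_id = query_id, subject_id = subject_id,
                       pct_identity = 100, aln_length = len,
                       mismatches = 0L, gap_opens = 0L,
                       q_start = q_start, q_end = q_end,
                       s_start = s_start, s_end = s_end,
                       evalue = 1e-180, bitscore = 2 * len,
                       stringsAsFactors = FALSE))
  }
  rl_all <- nchar(bases)
  org <- which(reads$organellar)
  hits_org <- if (length(org)) {
    mk_hits(reads$read_id[org], org_source[org],
            rep(1L, length(org)), rl_all[org],
            rep(1L, length(org)), rl_all[org])
  } else NULL
  nuc <- which(!reads$organellar)
  hits_ref <- if (length(nuc)) {
    fwd <- reads$direction[nuc] == "forward"
    mk_hits(reads$read_id[nuc], "toygenome",
            rep(1L, length(nuc)), rl_all[nuc],
            ifelse(fwd, reads$g_start[nuc], reads$g_end[nuc]),
            ifelse(fwd, reads$g_end[nuc], reads$g_start[nuc]))
  } else NULL
  gene_rows <- list()
  tg <- sim$truth$genes
  for (i in nuc) {
    a <- reads$g_start[i]; b <- reads$g_end[i]
    ov <- which(tg$start <= b & tg$end >= a)
    for (j in ov) {
      s2 <- max(tg$start[j], a); e2 <- min(tg$end[j], b)
      if (e2 - s2 + 1L < 30L) next
      loc <- to_local(s2, e2, a, b, reads$direction[i])
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        read_id = reads$read_id[i], gene_id = tg$gene_id[j],
        q_start = loc[1], q_end = loc[2],
        s_start = s2 - tg$start[j] + 1L, s_end = e2 - tg$start[j] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  hits_gene <- if (length(gene_rows)) {
    gr <- do.call(rbind, gene_rows)
    mk_hits(gr$read_id, gr$gene_id, gr$q_start, gr$q_end,
            gr$s_start, gr$s_end)
  } else NULL
  hits <- list(organelle = hits_org %||% empty_hits(),
               reference = hits_ref %||% empty_hits(),
               genes = hits_gene %||% empty_hits())

  ## qualities, then vector tails
  set.seed(sim$stage_seeds[3])
  quality <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    quality[[i]] <- if (cfg$quality_model == "clean") {
      rep(cfg$q_good, nchar(bases[i]))
    } else {
      markov_quality(nchar(bases[i]), cfg)
    }
  }
  vtail <- substr(sim$components$vector_seq, 1L, cfg$vector_prefix_len)
  for (i in which(reads$vector_len > 0L)) {
    bases[i] <- paste0(vtail, bases[i])
    quality[[i]] <- c(rep(cfg$q_good, nchar(vtail)), quality[[i]])
  }

  records <- bes_set(reads$read_id, bases, quality = quality)
  clones$any_organellar <- clones$clone_id %in%
    reads$clone_id[reads$organellar]
  out <- list(records = records,
              truth = list(reads = reads, clones = clones, hits = hits),
              genome = sim$genome,
              genome_truth = sim$truth,
              components = sim$components,
              min_len = min_len,
              config = cfg)
  class(out) <- "bes_sim"
  out$truth$expected_ssrs <- expected_read_features(out)$ssrs
  out$truth$expected_repeats <- expected_read_features(out)$repeats
  out
}

#' Map planted truth onto (possibly QC-processed) reads
#'
#' Projects the genome-level truth tables into read-local coordinates,
#' accounting for read-edge clipping of planted loci and for any bases the
#' QC stage removed from the 5' end (vector tails, quality trims) via the
#' `offset5` bookkeeping column.  A clipped SSR is expected only while its
#' whole-unit remainder still satisfies the detection threshold, and its
#' expected motif is the phase rotation the detector's left anchoring
#' produces.
#'
#' @param simbes a [simulate_bes()] result.
#' @param records optionally, the processed [bes_set()] whose coordinates the
#'   expectations should use (e.g. the QC output); by default the raw
#'   insert-only reads.
#' @return list of data frames `ssrs` (read_id, start, end, motif, unit_len,
#'   n_units) and `repeats` (read_id, start, end, family, class_path,
#'   source), in read-local coordinates.
#' @export
expected_read_features <- function(simbes, records = NULL) {
  reads <- simbes$truth$reads
  tss <- simbes$genome_truth$ssrs
  trp <- simbes$genome_truth$repeats
  min_len <- simbes$min_len
  genome <- simbes$genome
  exp_ssrs <- list()
  exp_reps <- list()
  for (i in which(!reads$organellar)) {
    if (!is.null(records)) {
      ir <- match(reads$read_id[i], records$read_id)
      if (is.na(ir)) next
      off <- max(0L, records$offset5[ir] - reads$vector_len[i])
      L2 <- nchar(records$bases[ir])
    } else {
      off <- 0L
      L2 <- reads$g_end[i] - reads$g_start[i] + 1L
    }
    if (L2 == 0L) next
    if (reads$direction[i] == "forward") {
      a <- reads$g_start[i] + off
      b <- a + L2 - 1L
    } else {
      b <- reads$g_end[i] - off
      a <- b - L2 + 1L
    }
    dirn <- reads$direction[i]
    for (j in which(tss$start <= b & tss$end >= a)) {
      s2 <- max(tss$start[j], a); e2 <- min(tss$end[j], b)
      k <- tss$unit_len[j]
      nu <- (e2 - s2 + 1L) %/% k
      if (k * nu < min_len[[k]] || nu < 2L) next
      loc <- to_local(s2, e2, a, b, dirn)
      motif <- if (dirn == "forward") substr(genome, s2, s2 + k - 1L) else
        revcomp(substr(genome, e2 - k + 1L, e2))
      exp_ssrs[[length(exp_ssrs) + 1L]] <- data.frame(
        read_id = reads$read_id[i], start = loc[1],
        end = loc[1] + k * nu - 1L, motif = motif,
        unit_len = k, n_units = nu, stringsAsFactors = FALSE)
    }
    for (j in which(trp$start <= b & trp$end >= a)) {
      s2 <- max(trp$start[j], a); e2 <- min(trp$end[j], b)
      loc <- to_local(s2, e2, a, b, dirn)
      exp_reps[[length(exp_reps) + 1L]] <- data.frame(
        read_id = reads$read_id[i], start = loc[1], end = loc[2],
        family = trp$family[j], class_path = trp$class_path[j],
        source = trp$source[j], stringsAsFactors = FALSE)
    }
  }
  ssrs <- if (length(exp_ssrs)) do.call(rbind, exp_ssrs) else
    data.frame(read_id = character(), start = integer(), end = integer(),
               motif = character(), unit_len = integer(),
               n_units = integer(), stringsAsFactors = FALSE)
  reps <- if (length(exp_reps)) do.call(rbind, exp_reps) else
    data.frame(read_id = character(), start = integer(), end = integer(),
               family = character(), class_path = character(),
               source = character(), stringsAsFactors = FALSE)
  list(ssrs = ssrs, repeats = reps)
}

#' Read-level repeat annotations from simulation truth
#'
#' Converts the per-read planted repeat intervals into a
#' [repeat_annotations()] table (the shape an external masker's output parser
#' would produce), optionally restricted to one source.
#'
#' @param simbes a [simulate_bes()] result.
#' @param source `"known"`, `"novel"`, or `"both"`.
#' @param records optionally, processed reads to project onto (see
#'   [expected_read_features()]).
#' @return a [repeat_annotations()] table in read coordinates.
#' @export
truth_repeat_annotations <- function(simbes, source = c("known", "novel",
                                                        "both"),
                                     records = NULL) {
  source <- match.arg(source)
  er <- if (is.null(records)) simbes$truth$expected_repeats else
    expected_read_features(simbes, records)$repeats
  if (source != "both") er <- er[er$source == source, , drop = FALSE]
  if (nrow(er) == 0L) return(empty_repeat_annotations())
  repeat_annotations(er$read_id, er$start, er$end, er$class_path,
                     er$family, er$source)
}

#' Write the simulated dataset as plain-text fixture files
#'
#' Emits `genome.fa`, `reads.fastq`, `vector.fa`, the component libraries,
#' truth tables (GFF3/TSV) and truth-derived hit tables (`.m8`) under `dir`.
#'
#' @param simbes a [simulate_bes()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_fixtures <- function(simbes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  dir.create(file.path(dir, "hits"), showWarnings = FALSE)
  gss <- Biostrings::DNAStringSet(c(toygenome = simbes$genome))
  Biostrings::writeXStringSet(gss, file.path(dir, "genome.fa"))
  write_sequences(simbes$records, file.path(dir, "reads.fastq"),
                  format = "fastq")
  vec <- Biostrings::DNAStringSet(c(vector = simbes$components$vector_seq))
  Biostrings::writeXStringSet(vec, file.path(dir, "vector.fa"))
  lib <- Biostrings::DNAStringSet(simbes$components$novel_library)
  Biostrings::writeXStringSet(lib, file.path(dir, "novel_library.fa"))
  write_hits(simbes$truth$hits$organelle, file.path(dir, "hits/organelle.m8"))
  write_hits(simbes$truth$hits$reference, file.path(dir, "hits/reference.m8"))
  write_hits(simbes$truth$hits$genes, file.path(dir, "hits/genes.m8"))
  write_annotations(truth_repeat_annotations(simbes, "known"),
                    file.path(dir, "truth/known_repeats.gff3"),
                    format = "gff3")
  utils::write.table(simbes$truth$clones,
                     file.path(dir, "truth/clones.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(simbes$truth$expected_ssrs,
                     file.path(dir, "truth/expected_ssrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
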