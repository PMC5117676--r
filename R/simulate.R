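## Synthetic-data generator: a toy AT-rich genome with planted repeat
## families, SSR loci and gene fragments; a BAC clone library sampled from
## it; and Sanger-style end reads with vector tails, quality profiles and
## low-level organellar contamination.  Every planted feature is bookkept in
## truth tables (including per-read expectations), so each pipeline stage can
## be validated exactly, with no downloads.
##
## One integer seed drives one derived stream per stage (genome, library,
## quality, contamination), so the stages are independently reproducible.

#' Simulation configuration
#'
#' Defaults describe the survey conditions the package is validated under: a
#' 5 Mb AT-rich (GC 0.38) toy genome carrying 12% known-family and 18%
#' novel-family repeats, one SSR per 2 kb, a ~5% genic fraction; a clone
#' library with inserts lognormal within 15-305 kb (mean about 100 kb) read
#' from both ends with Sanger-like lengths (mean 658 bp, range 100-945) and
#' 0.7% organellar contamination.
#'
#' @param seed integer master seed.
#' @param genome_size genome length in bp.
#' @param gc_content background GC proportion.
#' @param known_repeat_fraction,novel_repeat_fraction target genome fractions
#'   of planted known/novel repeat families.
#' @param n_known_families,n_novel_families,known_family_len,novel_family_len
#'   family counts and element lengths in bp.
#' @param divergence_known,divergence_novel per-copy substitution rates.
#' @param ssr_per_kb planted SSR loci per kb of genome.
#' @param ssr_motifs data frame with columns `motif`, `weight`, `min_units`,
#'   `max_units`; `NULL` for the built-in AT-biased pool.
#' @param gene_fraction,gene_len_range genic fraction and fragment length
#'   range in bp.
#' @param organelle_size length of each of the two toy organelle genomes.
#' @param contamination probability that a read is organellar.
#' @param vector_len,vector_rate,vector_prefix_len cloning-vector length, the
#'   probability a read carries a vector tail, and the tail length.
#' @param n_clones number of BAC clones sequenced from both ends.
#' @param insert_meanlog,insert_sdlog,insert_min,insert_max truncated
#'   lognormal insert-size model in bp.
#' @param read_len_mean,read_len_sd,read_len_min,read_len_max truncated
#'   normal read-length model in bp.
#' @param unpaired_fraction probability that a clone yields only its forward
#'   read.
#' @param quality_model `"clean"` (all bases at `q_good`) or `"markov"`
#'   (two-state good/bad chain producing trimmable low-quality read ends).
#' @param q_good,q_bad,p_bad_start,p_bad_to_good,p_good_to_bad quality-model
#'   parameters.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_size = 5e6,
                       gc_content = 0.38,
                       known_repeat_fraction = 0.12,
                       novel_repeat_fraction = 0.18,
                       n_known_families = 4L,
                       n_novel_families = 4L,
                       known_family_len = 800L,
                       novel_family_len = 700L,
                       divergence_known = 0.03,
                       divergence_novel = 0.05,
                       ssr_per_kb = 0.5,
                       ssr_motifs = NULL,
                       gene_fraction = 0.05,
                       gene_len_range = c(400L, 800L),
                       organelle_size = 20e3,
                       contamination = 0.007,
                       vector_len = 120L,
                       vector_rate = 0.5,
                       vector_prefix_len = 40L,
                       n_clones = 1200L,
                       insert_meanlog = log(9.5e4),
                       insert_sdlog = 0.55,
                       insert_min = 15e3,
                       insert_max = 305e3,
                       read_len_mean = 658,
                       read_len_sd = 120,
                       read_len_min = 100L,
                       read_len_max = 945L,
                       unpaired_fraction = 0.1,
                       quality_model = c("clean", "markov"),
                       q_good = 40L, q_bad = 10L,
                       p_bad_start = 0.3, p_bad_to_good = 0.15,
                       p_good_to_bad = 0.002) {
  cfg <- as.list(environment())
  cfg$quality_model <- match.arg(quality_model)
  stopifnot(cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$contamination >= 0, cfg$contamination <= 1,
            cfg$vector_rate >= 0, cfg$vector_rate <= 1,
            cfg$unpaired_fraction >= 0, cfg$unpaired_fraction <= 1,
            cfg$insert_min < cfg$insert_max,
            cfg$read_len_min < cfg$read_len_max)
  if (is.null(cfg$ssr_motifs)) cfg$ssr_motifs <- default_ssr_motif_pool()
  class(cfg) <- "sim_config"
  cfg
}

default_ssr_motif_pool <- function() {
  data.frame(
    motif = c("A", "T", "AT", "AG", "AC", "TC",
              "AAT", "ATT", "AAG", "CCG",
              "AAAT", "AACCT", "AACGAT"),
    weight = c(0.35, 0.20, 0.15, 0.08, 0.05, 0.03,
               0.06, 0.03, 0.02, 0.01,
               0.013, 0.004, 0.003),
    min_units = c(20L, 20L, 8L, 8L, 8L, 8L, 5L, 5L, 5L, 5L, 4L, 3L, 3L),
    max_units = c(35L, 35L, 15L, 15L, 15L, 15L, 10L, 10L, 10L, 10L, 6L, 5L, 4L),
    stringsAsFactors = FALSE)
}

rand_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## break every qualifying SSR run in a sequence by a middle-base substitution
scrub_ssrs <- function(s, min_len = default_ssr_min_len(), max_iter = 5L) {
  for (it in seq_len(max_iter)) {
    loci <- find_perfect_ssrs(c(x = s), min_len = min_len)
    if (nrow(loci) == 0L) return(s)
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(loci))) {
      mid <- (loci$start[i] + loci$end[i]) %/% 2L
      forbid <- unique(c(x[mid], x[max(1L, mid - 1L)],
                         x[min(length(x), mid + 1L)]))
      x[mid] <- setdiff(c("A", "C", "G", "T"), forbid)[1]
    }
    s <- paste(x, collapse = "")
  }
  s
}

mutate_copy <- function(s, divergence) {
  if (divergence <= 0) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  n_mut <- stats::rbinom(1L, length(x), divergence)
  if (n_mut == 0L) return(s)
  pos <- sample.int(length(x), n_mut)
  x[pos] <- vapply(x[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1))
  paste(x, collapse = "")
}

## class paths assigned cyclically to known families
known_class_paths <- function(n) {
  pool <- c("Class I retrotransposon|LTR retrotransposons|Ty1/copia",
            "Class I retrotransposon|LTR retrotransposons|Gypsy/DIRS",
            "Class I retrotransposon|Non-LTR retrotransposons|LINE",
            "Class II DNA transposons|hobo-Activator")
  pool[(seq_len(n) - 1L) %% length(pool) + 1L]
}

#' Simulate a toy genome with planted features
#'
#' Background sequence at the target GC is scrubbed of chance SSRs; repeat
#' copies (mutated at the configured divergence), SSR loci and gene fragments
#' are planted non-overlapping with at least 110 bp of background between
#' features (so planted SSRs never merge into compounds); SSR flanks are
#' fixed so each planted run is maximal.  Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list of class `bes_sim_genome`: `genome` (string), `truth`
#'   (data frames `repeats`, `ssrs`, `genes`), `components` (named family
#'   libraries, organelle genomes, vector sequence), `stage_seeds`, `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(2147483646L, 4L)
  set.seed(stage_seeds[1])
  G <- config$genome_size

  ## component sequences (scrubbed of chance SSRs)
  mk_family <- function(prefix, n, len) {
    fams <- stats::setNames(
      vapply(seq_len(n), function(i) scrub_ssrs(rand_seq(len, 0.42)),
             character(1)),
      paste0(prefix, seq_len(n)))
    fams
  }
  known_lib <- mk_family("knownFam", config$n_known_families,
                         config$known_family_len)
  novel_lib <- mk_family("novelFam", config$n_novel_families,
                         config$novel_family_len)
  organelles <- c(mito = scrub_ssrs(rand_seq(config$organelle_size, 0.37)),
                  chloro = scrub_ssrs(rand_seq(config$organelle_size, 0.37)))
  vector_seq <- scrub_ssrs(rand_seq(config$vector_len, 0.45))

  ## feature roster
  kn_copies <- round(config$known_repeat_fraction * G /
                       (config$n_known_families * config$known_family_len))
  nv_copies <- round(config$novel_repeat_fraction * G /
                       (config$n_novel_families * config$novel_family_len))
  kn_paths <- known_class_paths(config$n_known_families)
  feats <- list()
  add <- function(kind, seqs, meta) {
    feats[[length(feats) + 1L]] <<- list(kind = kind, seqs = seqs, meta = meta)
  }
  rep_feats <- list()
  for (i in seq_along(known_lib)) {
    for (cp in seq_len(kn_copies)) {
      rep_feats[[length(rep_feats) + 1L]] <- list(
        seq = mutate_copy(known_lib[[i]], config$divergence_known),
        family = names(known_lib)[i], class_path = kn_paths[i],
        source = "known")
    }
  }
  for (i in seq_along(novel_lib)) {
    for (cp in seq_len(nv_copies)) {
      rep_feats[[length(rep_feats) + 1L]] <- list(
        seq = mutate_copy(novel_lib[[i]], config$divergence_novel),
        family = names(novel_lib)[i], class_path = "Unclassified",
        source = "novel")
    }
  }
  n_ssr <- round(config$ssr_per_kb * G / 1000)
  pool <- config$ssr_motifs
  pick <- sample.int(nrow(pool), n_ssr, replace = TRUE, prob = pool$weight)
  ssr_feats <- lapply(pick, function(p) {
    n_units <- sample(pool$min_units[p]:pool$max_units[p], 1L)
    list(motif = pool$motif[p], n_units = n_units,
         seq = strrep(pool$motif[p], n_units))
  })
  mean_gene <- mean(config$gene_len_range)
  n_genes <- round(config$gene_fraction * G / mean_gene)
  gene_feats <- lapply(seq_len(n_genes), function(i) {
    len <- sample(config$gene_len_range[1]:config$gene_len_range[2], 1L)
    list(seq = scrub_ssrs(rand_seq(len, 0.45)), gene_id = paste0("gene", i))
  })

  items <- c(lapply(rep_feats, function(f) c(f, kind = "repeat")),
             lapply(ssr_feats, function(f) c(f, kind = "ssr")),
             lapply(gene_feats, function(f) c(f, kind = "gene")))
  items <- items[sample.int(length(items))]
  lens <- vapply(items, function(f) nchar(f$seq), integer(1))

  ## gap allocation: >= 110 bp of background between/around features
  guard <- 110L
  n_feat <- length(items)
  s_free <- G - sum(lens) - guard * (n_feat + 1L)
  if (s_free < 0) {
    stop_contract("infeasible packing: planted features exceed the genome")
  }
  extras <- diff(c(0, sort(stats::runif(n_feat, 0, s_free)), s_free))
  gaps <- as.integer(guard + floor(extras))
  gaps[n_feat + 1L] <- as.integer(G - sum(lens) -
                                    sum(gaps[seq_len(n_feat)]))

  background <- scrub_ssrs(rand_seq(G - sum(lens), config$gc_content))
  bg <- strsplit(background, "", fixed = TRUE)[[1]]
  x <- character(G)
  pos <- 1L
  stopifnot(is.integer(gaps))
  bgpos <- 1L
  starts <- integer(n_feat)
  for (i in seq_len(n_feat)) {
    g <- gaps[i]
    x[pos:(pos + g - 1L)] <- bg[bgpos:(bgpos + g - 1L)]
    pos <- pos + g
    bgpos <- bgpos + g
    fx <- strsplit(items[[i]]$seq, "", fixed = TRUE)[[1]]
    starts[i] <- pos
    x[pos:(pos + length(fx) - 1L)] <- fx
    pos <- pos + length(fx)
  }
  g <- gaps[n_feat + 1L]
  if (g > 0L) x[pos:(pos + g - 1L)] <- bg[bgpos:(bgpos + g - 1L)]

  ## truth tables
  kinds <- vapply(items, `[[`, "", "kind")
  ends <- starts + lens - 1L
  rsel <- kinds == "repeat"
  repeats <- data.frame(
    start = starts[rsel], end = ends[rsel],
    family = vapply(items[rsel], `[[`, "", "family"),
    class_path = vapply(items[rsel], `[[`, "", "class_path"),
    source = vapply(items[rsel], `[[`, "", "source"),
    stringsAsFactors = FALSE)
  ssel <- kinds == "ssr"
  ssrs <- data.frame(
    start = starts[ssel], end = ends[ssel],
    motif = vapply(items[ssel], `[[`, "", "motif"),
    unit_len = nchar(vapply(items[ssel], `[[`, "", "motif")),
    n_units = vapply(items[ssel], function(f) as.integer(f$n_units),
                     integer(1)),
    stringsAsFactors = FALSE)
  gsel <- kinds == "gene"
  genes <- data.frame(
    gene_id = vapply(items[gsel], `[[`, "", "gene_id"),
    start = starts[gsel], end = ends[gsel], stringsAsFactors = FALSE)

  ## make every planted SSR run maximal: the base just outside each flank
  ## must break the period
  for (i in seq_len(nrow(ssrs))) {
    s <- ssrs$start[i]; e <- ssrs$end[i]; k <- ssrs$unit_len[i]
    if (s > 1L && x[s - 1L] == x[s + k - 1L]) {
      x[s - 1L] <- setdiff(c("A", "C", "G", "T"),
                           unique(c(x[s + k - 1L], x[max(1L, s - 2L)])))[1]
    }
    if (e < G && x[e + 1L] == x[e + 1L - k]) {
      x[e + 1L] <- setdiff(c("A", "C", "G", "T"),
                           unique(c(x[e + 1L - k], x[min(G, e + 2L)])))[1]
    }
  }
  genome <- paste(x, collapse = "")

  ## scrub any qualifying run that is not a planted SSR (feature boundaries,
  ## repeat-copy mutations); such runs never overlap planted loci
  for (it in 1:3) {
    det <- find_perfect_ssrs(c(g = genome))
    key <- paste(det$start, det$end, det$motif)
    tkey <- paste(ssrs$start, ssrs$end, ssrs$motif)
    extra <- det[!(key %in% tkey), , drop = FALSE]
    if (nrow(extra) == 0L) break
    ir_e <- IRanges::IRanges(extra$start, extra$end)
    ir_t <- IRanges::IRanges(ssrs$start, ssrs$end)
    if (length(IRanges::findOverlaps(ir_e, ir_t))) {
      stop("internal: chance SSR overlapping a planted locus")
    }
    xg <- strsplit(genome, "", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(extra))) {
      mid <- (extra$start[j] + extra$end[j]) %/% 2L
      forbid <- unique(c(xg[mid], xg[max(1L, mid - 1L)],
                         xg[min(G, mid + 1L)]))
      xg[mid] <- setdiff(c("A", "C", "G", "T"), forbid)[1]
    }
    genome <- paste(xg, collapse = "")
  }

  out <- list(genome = genome,
              truth = list(repeats = repeats, ssrs = ssrs, genes = genes),
              components = list(known_library = known_lib,
                                novel_library = novel_lib,
                                organelles = organelles,
                                vector_seq = vector_seq,
                                known_class_paths = stats::setNames(
                                  kn_paths, names(known_lib))),
              stage_seeds = stage_seeds,
              config = config)
  class(out) <- "bes_sim_genome"
  out
}
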