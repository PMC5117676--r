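## End-to-end orchestration: qc -> repeat census -> ssr -> coding -> synteny
## -> library stats, writing a survey-style report bundle.  Every report
## number is a pure function of the inputs and the configuration.

#' Default pipeline configuration
#'
#' Thresholds default to the conventional survey values: terminal Phred
#' >= 20, minimum read length 100 bp, organelle E-value 1e-15, EST/CDS
#' E-value 1e-10, protein E-value 1e-06, SSR minima 20 bp (mono) / 15 bp
#' (di-hexa) with a 100 bp compound gap, and synteny filters of >= 70%
#' identity, >= 50 bp alignment, E <= 1e-06 with a 15-350 kb collinear span.
#'
#' @param ... overrides for any default entry (input paths, thresholds,
#'   `outdir`).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    reads = NULL, reads_format = "fastq", qual = NULL,
    vector = NULL, organelle_hits = NULL,
    known_annotations = NULL, known_annotations_format = "gff3",
    novel_library = NULL,
    est_hits = NULL, protein_hits = NULL, reference_hits = NULL,
    insert_sizes = NULL, n_clones = NULL,
    genome_size_range = c(2.2e9, 3.0e9), mean_gene_len = 1379,
    qmin = 20, min_read_len = 100, org_evalue = 1e-15,
    est_evalue = 1e-10, protein_evalue = 1e-06,
    ssr_mono_min = 20, ssr_other_min = 15, ssr_max_gap = 100,
    syn_min_ident = 70, syn_min_len = 50, syn_evalue = 1e-06,
    span_min = 15e3, span_max = 350e3,
    mask_min_match = 50, mask_min_ident = 80,
    outdir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_contract("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] entries.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_kv <- function(x, path) {
  df <- data.frame(key = names(x),
                   value = vapply(x, function(v) paste(format(v), collapse = ","),
                                  character(1)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the whole survey pipeline
#'
#' Stages whose inputs are absent from the configuration are skipped; report
#' files for the executed stages are written under `config$outdir` (when
#' set): `dataset_stats.tsv`, `repeat_census.tsv`, `ssr_summary.tsv`,
#' `coding_summary.tsv`, `synteny_summary.tsv`, `libstats.tsv` and `run.log`
#' recording all thresholds and per-stage record counts.
#'
#' @param config a [pipeline_config()] (or path to its YAML form).
#' @return invisibly, a list with the stage results (`stats`, `census`,
#'   `ssr`, `coding`, `synteny`, `libstats`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (key in c("reads", "vector", "organelle_hits", "known_annotations",
                "novel_library", "est_hits", "protein_hits",
                "reference_hits", "insert_sizes")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop_contract("missing input '", key, "': ", p)
    }
  }
  if (is.null(config$reads)) stop_contract("config$reads is required")
  log_lines <- c(sprintf("bessurvey pipeline, package version %s",
                         as.character(utils::packageVersion("bessurvey"))),
                 sprintf("parameters: qmin=%g min_read_len=%g org_evalue=%g est_evalue=%g protein_evalue=%g ssr=%g/%g gap=%g synteny=%g%%/%gbp/E%g span=[%g,%g] mask=%g/%g%%",
                         config$qmin, config$min_read_len, config$org_evalue,
                         config$est_evalue, config$protein_evalue,
                         config$ssr_mono_min, config$ssr_other_min,
                         config$ssr_max_gap, config$syn_min_ident,
                         config$syn_min_len, config$syn_evalue,
                         config$span_min, config$span_max,
                         config$mask_min_match, config$mask_min_ident))
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  ## --- QC ------------------------------------------------------------
  records <- read_sequences(config$reads, format = config$reads_format,
                            qual_path = config$qual)
  note("input reads: %d", nrow(records))
  vec <- if (!is.null(config$vector)) {
    as.character(Biostrings::readDNAStringSet(config$vector))[1]
  } else NULL
  org_hits <- if (!is.null(config$organelle_hits)) {
    read_hits(config$organelle_hits)
  } else NULL
  qc <- qc_reads(records, vector_seq = vec, organelle_hits = org_hits,
                 qmin = config$qmin, min_len = config$min_read_len,
                 e_cutoff = config$org_evalue)
  note("after QC: %d clean, %d short, %d organellar",
       nrow(qc$records), nrow(qc$removed_short), nrow(qc$organellar))
  clean <- qc$records
  total_bp <- qc$stats$total_bp

  ## --- repeat census -------------------------------------------------
  census <- NULL
  known_pct <- novel_pct <- NA_real_
  masked <- clean
  known_ann <- if (!is.null(config$known_annotations)) {
    read_annotations(config$known_annotations,
                     format = config$known_annotations_format,
                     type = "repeat")
  } else empty_repeat_annotations()
  if (nrow(known_ann)) {
    masked <- mask_annotations(masked, known_ann)
    note("known-repeat annotations: %d", nrow(known_ann))
  }
  novel_ann <- empty_repeat_annotations()
  if (!is.null(config$novel_library)) {
    lib <- as.character(Biostrings::readDNAStringSet(config$novel_library))
    mk <- mask_with_library(masked, lib,
                            min_match = config$mask_min_match,
                            min_ident = config$mask_min_ident)
    novel_ann <- mk$annotations
    masked <- mk$records
    note("novel-library annotations: %d", nrow(novel_ann))
  }
  if (nrow(known_ann) || nrow(novel_ann)) {
    comb <- rbind(as.data.frame(known_ann), as.data.frame(novel_ann))
    census <- build_census(
      repeat_annotations(comb$query_id, comb$q_start, comb$q_end,
                         comb$class_path, comb$family, comb$source),
      total_bp = total_bp)
    known_pct <- pct2(sum_union_bp(known_ann), total_bp)
    novel_pct <- pct2(sum_union_bp(novel_ann), total_bp)
  }

  ## --- SSR -----------------------------------------------------------
  min_len <- c(config$ssr_mono_min, rep(config$ssr_other_min, 5))
  perfect <- find_perfect_ssrs(clean, min_len = min_len)
  loci <- merge_compound(perfect, max_gap = config$ssr_max_gap)
  ssr_sum <- ssr_summary(loci, total_bp)
  note("SSRs: %d perfect, %d compound", ssr_sum$n_perfect,
       ssr_sum$n_compound)

  ## --- coding --------------------------------------------------------
  ## hit tables may describe the raw reads; only QC-surviving reads count
  keep_clean <- function(h) h[h$query_id %in% clean$read_id, , drop = FALSE]
  coding <- list()
  if (!is.null(config$est_hits)) {
    coding$est <- coding_summary(keep_clean(read_hits(config$est_hits)),
                                 total_bp, e_cutoff = config$est_evalue)
  }
  if (!is.null(config$protein_hits)) {
    coding$protein <- coding_summary(
      keep_clean(read_hits(config$protein_hits)), total_bp,
      e_cutoff = config$protein_evalue)
  }
  coding$extrapolation <- if (length(coding)) {
    base <- coding$protein %||% coding$est
    extrapolate_genome(base$pct_of_total, config$genome_size_range,
                       config$mean_gene_len)
  } else NULL

  ## --- synteny -------------------------------------------------------
  synteny <- NULL
  if (!is.null(config$reference_hits)) {
    ref <- filter_hits(keep_clean(read_hits(config$reference_hits)),
                       min_ident = config$syn_min_ident,
                       min_len = config$syn_min_len,
                       e_cutoff = config$syn_evalue)
    pairs <- classify_clone_pairs(ref, span_min = config$span_min,
                                  span_max = config$span_max)
    synteny <- list(pairs = pairs, summary = synteny_summary(pairs),
                    coverage = reference_coverage(ref, by = "query"))
    note("synteny: %d clones classified", nrow(pairs))
  }

  ## --- library stats -------------------------------------------------
  libstats <- NULL
  if (!is.null(config$insert_sizes)) {
    sizes <- scan(config$insert_sizes, quiet = TRUE)
    isd <- insert_size_distribution(sizes)
    n_clones <- config$n_clones %||% length(sizes)
    libstats <- list(
      distribution = isd,
      coverage = genome_coverage(n_clones, isd$mean_insert,
                                 config$genome_size_range),
      single_copy_p = single_copy_probability(n_clones, isd$mean_insert,
                                              max(config$genome_size_range)))
  }

  res <- list(stats = qc$stats, counts = qc$counts, census = census,
              known_pct = known_pct, novel_pct = novel_pct,
              ssr = ssr_sum, ssr_loci = loci, coding = coding,
              synteny = synteny, libstats = libstats, records = clean,
              masked_records = masked)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    st <- qc$stats
    write_kv(list(n_reads = st$n_reads, n_paired = st$n_paired,
                  n_unpaired = st$n_unpaired, total_bp = st$total_bp,
                  min_len = st$min_len, max_len = st$max_len,
                  mean_len = sprintf("%.2f", st$mean_len),
                  gc_percent = sprintf("%.2f", st$gc_percent),
                  n_organellar_removed = st$n_organellar_removed),
             file.path(config$outdir, "dataset_stats.tsv"))
    if (!is.null(census)) {
      utils::write.table(as.data.frame(census),
                         file.path(config$outdir, "repeat_census.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      file.create(file.path(config$outdir, "repeat_census.tsv"))
    }
    write_kv(list(n_ssrs = ssr_sum$n_ssrs, n_perfect = ssr_sum$n_perfect,
                  n_compound = ssr_sum$n_compound,
                  n_class_I = ssr_sum$n_class_I,
                  n_class_II = ssr_sum$n_class_II,
                  density_kb = ssr_sum$density_kb,
                  by_unit = paste(ssr_sum$unit_len_labels,
                                  ssr_sum$by_unit_len, sep = ":",
                                  collapse = ";")),
             file.path(config$outdir, "ssr_summary.tsv"))
    cod <- list()
    for (nm in intersect(c("est", "protein"), names(coding))) {
      cs <- coding[[nm]]
      cod[[paste0(nm, "_reads")]] <- cs$n_reads_with_hits
      cod[[paste0(nm, "_bp")]] <- cs$cumulative_match_bp
      cod[[paste0(nm, "_pct")]] <- sprintf("%.2f", cs$pct_of_total)
    }
    if (!is.null(coding$extrapolation)) {
      cod$gene_count_range <- paste(coding$extrapolation$gene_count_range,
                                    collapse = "-")
    }
    write_kv(cod, file.path(config$outdir, "coding_summary.tsv"))
    if (!is.null(synteny)) {
      write_kv(c(as.list(synteny$summary),
                 list(union_bp = synteny$coverage$union_bp,
                      coverage_pct = sprintf(
                        "%.2f", pct2(synteny$coverage$union_bp, total_bp)))),
               file.path(config$outdir, "synteny_summary.tsv"))
    } else {
      file.create(file.path(config$outdir, "synteny_summary.tsv"))
    }
    if (!is.null(libstats)) {
      write_kv(list(mean_insert = sprintf("%.0f", libstats$distribution$mean_insert),
                    pct_gt90 = libstats$distribution$pct[[">90 kb"]],
                    pct_40_90 = libstats$distribution$pct[["40-90 kb"]],
                    pct_lt40 = libstats$distribution$pct[["<40 kb"]],
                    pct_no_insert = libstats$distribution$pct[["no insert"]],
                    coverage_fold = paste(sprintf("%.2f", libstats$coverage),
                                          collapse = "-"),
                    single_copy_p = sprintf("%.4f", libstats$single_copy_p)),
               file.path(config$outdir, "libstats.tsv"))
    } else {
      file.create(file.path(config$outdir, "libstats.tsv"))
    }
    writeLines(log_lines, file.path(config$outdir, "run.log"))
  }
  invisible(res)
}

## summed per-read union bp of an annotation table
sum_union_bp <- function(annotations) {
  if (nrow(annotations) == 0L) return(0L)
  sum(vapply(split(annotations, annotations$query_id), function(q) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(q$q_start,
                                                        q$q_end))))
  }, integer(1)))
}
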