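## Domain containers and file I/O.
##
## Conventions used throughout the package:
##   * all in-memory coordinates as well as everything on disk are 1-based
##     inclusive (the BLAST/GFF3 convention); interval arithmetic goes through
##     IRanges so there is no open/half-open bookkeeping to get wrong;
##   * minus-strand alignments are encoded by s_start > s_end, as in tabular
##     BLAST output, and a derived `strand` column is carried alongside;
##   * any base outside {A,C,G,T} is stored as N.

#' Construct a set of BAC-end records
#'
#' A `bes_set` is a data frame with one row per end read carrying the read id,
#' the clone id and end direction parsed from it, the bases, and (optionally)
#' per-base Phred qualities as a list column.
#'
#' @param read_id character vector of read identifiers.  By default the leading
#'   `F`/`R` letter gives the end direction and the remainder is the clone id
#'   (e.g. `F358H9` / `R358H9`).
#' @param bases character vector of sequences over `A,C,G,T,N` (anything else
#'   is converted to `N`).
#' @param quality optional list of integer Phred vectors, one per read, each
#'   the same length as its sequence.
#' @param id_pattern regular expression with two capture groups (direction
#'   letter, clone id) used to parse `read_id`.
#' @return a data frame of class `bes_set` with columns `read_id`, `clone_id`,
#'   `direction`, `bases` and list column `quality`.
#' @export
bes_set <- function(read_id, bases,
                    quality = NULL,
                    id_pattern = "^([FR])(.+)$") {
  read_id <- as.character(read_id)
  bases <- normalize_bases(as.character(bases))
  if (length(read_id) != length(bases)) {
    stop_contract("read_id and bases must have the same length")
  }
  if (any(!nzchar(bases))) {
    stop_contract("empty sequence for read(s): ",
                  paste(read_id[!nzchar(bases)], collapse = ", "))
  }
  m <- regmatches(read_id, regexec(id_pattern, read_id))
  ok <- lengths(m) == 3L
  direction <- rep(NA_character_, length(read_id))
  clone_id <- read_id
  direction[ok] <- ifelse(vapply(m[ok], `[`, "", 2L) == "F",
                          "forward", "reverse")
  clone_id[ok] <- vapply(m[ok], `[`, "", 3L)
  if (is.null(quality)) {
    quality <- rep(list(NULL), length(read_id))
  } else {
    stopifnot(length(quality) == length(read_id))
    bad <- !vapply(quality, is.null, logical(1)) &
      lengths(quality) != nchar(bases)
    if (any(bad)) {
      stop_contract("quality length differs from sequence length for read(s): ",
                    paste(read_id[bad], collapse = ", "))
    }
    quality <- lapply(quality, function(q) if (is.null(q)) NULL else as.integer(q))
  }
  out <- data.frame(read_id = read_id, clone_id = clone_id,
                    direction = direction, bases = bases,
                    stringsAsFactors = FALSE)
  out$quality <- quality
  # bases removed from the 5' end by QC, for mapping back to the raw read
  out$offset5 <- rep(0L, nrow(out))
  class(out) <- c("bes_set", "data.frame")
  out
}

#' @export
print.bes_set <- function(x, ...) {
  cat(sprintf("bes_set: %d reads, %d clones, total %s bp\n",
              nrow(x), length(unique(x$clone_id)),
              format(sum(nchar(x$bases)), big.mark = ",")))
  invisible(x)
}

read_lengths <- function(records) nchar(records$bases)

#' Read BAC-end sequences from FASTA/FASTQ/FASTA+QUAL
#'
#' @param path input file.
#' @param format one of `"fasta"`, `"fastq"`, `"fasta-qual"` (alias
#'   `"fasta+qual"`).
#' @param qual_path companion `.qual` file of whitespace-separated Phred
#'   scores; required for `fasta-qual`.
#' @param id_pattern passed to [bes_set()].
#' @return a [bes_set()].
#' @export
read_sequences <- function(path, format = c("fasta", "fastq", "fasta-qual"),
                           qual_path = NULL, id_pattern = "^([FR])(.+)$") {
  format <- match.arg(sub("\\+", "-", format[1]),
                      c("fasta", "fastq", "fasta-qual"))
  if (!file.exists(path)) stop_contract("no such file: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path, format = "fasta")
    recs <- bes_set(names(ss), as.character(ss), id_pattern = id_pattern)
  } else if (format == "fastq") {
    ## validate the 4-line record structure up front: the Biostrings reader
    ## silently pads a short quality string
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) {
      stop_contract("malformed FASTQ in ", path, ": line count ",
                    length(lines), " is not a multiple of 4")
    }
    if (length(lines)) {
      slen <- nchar(lines[seq(2L, length(lines), by = 4L)])
      qlen <- nchar(lines[seq(4L, length(lines), by = 4L)])
      bad <- which(slen != qlen)
      if (length(bad)) {
        stop_contract("malformed FASTQ in ", path, ": record ", bad[1],
                      " (line ", 4L * bad[1] - 2L,
                      ") has sequence/quality length mismatch")
      }
    }
    parsed <- withCallingHandlers(
      tryCatch({
        ss <- Biostrings::readQualityScaledDNAStringSet(path)
        list(bases = as.character(ss), ids = names(ss),
             qual = as.list(as(Biostrings::quality(ss), "IntegerList")))
      }, error = function(e) {
        stop_contract("malformed FASTQ in ", path, ": ", conditionMessage(e))
      }),
      ## the reader always warns about dropping its own metadata columns
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    if (any(lengths(parsed$qual) != nchar(parsed$bases))) {
      stop_contract("malformed FASTQ in ", path,
                    ": quality length differs from sequence length")
    }
    recs <- bes_set(parsed$ids, parsed$bases, quality = parsed$qual,
                    id_pattern = id_pattern)
  } else {
    if (is.null(qual_path)) stop_contract("fasta-qual format needs qual_path")
    ss <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- read_qual_file(qual_path)
    if (!identical(names(ss), names(qual))) {
      stop_contract("sequence and quality files disagree on read ids")
    }
    recs <- bes_set(names(ss), as.character(ss), quality = unname(qual),
                    id_pattern = id_pattern)
  }
  if (nrow(recs) == 0L) warning("no records in ", path)
  recs
}

## parse a phrap-style .qual file: '>id' headers, integers on following lines
read_qual_file <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr) && length(lines)) stop_contract("not a qual file: ", path)
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  vals <- split(lines[!hdr], grp[!hdr])
  out <- lapply(vals, function(v) {
    as.integer(scan(text = paste(v, collapse = " "), quiet = TRUE))
  })
  names(out) <- ids
  out
}

#' Write BAC-end sequences to FASTA or FASTQ
#'
#' @param records a [bes_set()].
#' @param path output file.
#' @param format `"fasta"` or `"fastq"` (FASTQ requires qualities).
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ss <- Biostrings::DNAStringSet(records$bases)
  names(ss) <- records$read_id
  if (format == "fasta") {
    Biostrings::writeXStringSet(ss, path)
  } else {
    if (any(vapply(records$quality, is.null, logical(1)))) {
      stop_contract("FASTQ output requires per-base qualities")
    }
    q <- Biostrings::PhredQuality(vapply(records$quality, function(qq) {
      rawToChar(as.raw(as.integer(qq) + 33L))
    }, character(1)))
    qss <- Biostrings::QualityScaledDNAStringSet(ss, q)
    Biostrings::writeQualityScaledXStringSet(qss, path)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## tabular alignment hits (12-column BLAST dialect)

hit_columns <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

#' Construct an alignment-hit table
#'
#' Columns follow the 12-column tabular BLAST dialect.  The strand is minus
#' iff `s_start > s_end`; a derived `strand` column is added.
#' @param df data frame with the 12 standard columns (see
#'   `bessurvey:::hit_columns`).
#' @return data frame of class `bes_hits`.
#' @export
as_hits <- function(df) {
  missing_cols <- setdiff(hit_columns, names(df))
  if (length(missing_cols)) {
    stop_contract("hit table lacks columns: ",
                  paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[hit_columns]
  int_cols <- c("aln_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  df$pct_identity <- as.numeric(df$pct_identity)
  df$evalue <- as.numeric(df$evalue)
  df$bitscore <- as.numeric(df$bitscore)
  if (any(df$q_start > df$q_end)) {
    stop_contract("q_start > q_end is not allowed (query coordinates are ",
                  "always ascending)")
  }
  if (any(df$aln_length < 1L)) stop_contract("aln_length must be >= 1")
  if (any(df$evalue < 0)) stop_contract("negative E-value")
  df$strand <- ifelse(df$s_start > df$s_end, "-", "+")
  class(df) <- c("bes_hits", "data.frame")
  df
}

#' An empty hit table
#' @return a zero-row hit table with the standard columns.
#' @export
empty_hits <- function() {
  as_hits(stats::setNames(
    data.frame(character(), character(), numeric(), integer(), integer(),
               integer(), integer(), integer(), integer(), integer(),
               numeric(), numeric(), stringsAsFactors = FALSE),
    hit_columns))
}

#' Read a 12-column tabular alignment file
#'
#' @param path whitespace- or tab-separated file with the standard 12 columns.
#' @return a hit table (see [as_hits()]); minus strand inferred from
#'   `s_start > s_end`.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop_contract("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) {
    stop_contract("row ", bad[1], " of ", path, " has ",
                  lengths(fields)[bad[1]], " columns (12 expected)")
  }
  mat <- do.call(rbind, fields)
  df <- data.frame(query_id = mat[, 1], subject_id = mat[, 2],
                   stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(v)) {
      stop_contract("row ", which(is.na(v))[1], " of ", path,
                    ": non-numeric value '", mat[which(is.na(v))[1], j],
                    "' in column ", j)
    }
    df[[hit_columns[j]]] <- v
  }
  as_hits(df)
}

#' Write a hit table in the 12-column tabular dialect
#' @param hits a hit table.
#' @param path output file.
#' @export
write_hits <- function(hits, path) {
  df <- as.data.frame(hits)[hit_columns]
  df$evalue <- format(df$evalue, scientific = TRUE, digits = 3)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## repeat taxonomy

#' Default repeat-classification taxonomy
#'
#' Hierarchy of repeat classes used by the census: Class I retrotransposons
#' (LTR: Ty1/copia, Gypsy/DIRS, Others; non-LTR: SINE, LINE), Class II DNA
#' transposons (named superfamilies), plus Unclassified, Small RNA,
#' Satellites, Simple repeats and Low complexity.  Paths are `|`-joined.
#'
#' @return character vector of all node paths, class `repeat_taxonomy`.
#' @export
default_repeat_taxonomy <- function() {
  paths <- c(
    "Class I retrotransposon",
    "Class I retrotransposon|LTR retrotransposons",
    "Class I retrotransposon|LTR retrotransposons|Ty1/copia",
    "Class I retrotransposon|LTR retrotransposons|Gypsy/DIRS",
    "Class I retrotransposon|LTR retrotransposons|Others",
    "Class I retrotransposon|Non-LTR retrotransposons",
    "Class I retrotransposon|Non-LTR retrotransposons|SINE",
    "Class I retrotransposon|Non-LTR retrotransposons|LINE",
    "Class II DNA transposons",
    "Class II DNA transposons|hobo-Activator",
    "Class II DNA transposons|TcMar",
    "Class II DNA transposons|CMC-EnSpm",
    "Class II DNA transposons|MULE-MuDR",
    "Class II DNA transposons|RC/Helitron",
    "Class II DNA transposons|PiggyBac",
    "Class II DNA transposons|Tourist/Harbinger",
    "Class II DNA transposons|Others",
    "Unclassified",
    "Small RNA",
    "Satellites",
    "Simple repeats",
    "Low complexity")
  class(paths) <- c("repeat_taxonomy", "character")
  paths
}

#' Read a taxonomy from a YAML file
#'
#' The YAML is a nested map mirroring the class hierarchy; leaves are `~`.
#' @param path YAML file.
#' @return a `repeat_taxonomy` (character vector of `|`-joined paths).
#' @export
read_taxonomy <- function(path) {
  tree <- yaml::read_yaml(path)
  walk <- function(node, prefix) {
    if (is.null(node)) return(character())
    out <- character()
    for (nm in names(node)) {
      p <- if (nzchar(prefix)) paste(prefix, nm, sep = "|") else nm
      out <- c(out, p, walk(node[[nm]], p))
    }
    out
  }
  paths <- walk(tree, "")
  class(paths) <- c("repeat_taxonomy", "character")
  paths
}

## ---------------------------------------------------------------------------
## annotation containers

#' Construct a repeat-annotation table
#'
#' One row per masked interval on a read, with its hierarchical class path.
#'
#' @param query_id read ids.
#' @param q_start,q_end 1-based inclusive coordinates on the read.
#' @param class_path `|`-joined path in the repeat taxonomy (e.g.
#'   `"Class I retrotransposon|LTR retrotransposons|Ty1/copia"`).
#' @param family repeat family name.
#' @param source `"known"` or `"novel"`.
#' @param taxonomy taxonomy to validate against; paths that do not resolve are
#'   routed to `"Unclassified"` with a warning.
#' @return data frame of class `repeat_annotations`.
#' @export
repeat_annotations <- function(query_id, q_start, q_end, class_path,
                               family = NA_character_, source = "known",
                               taxonomy = default_repeat_taxonomy()) {
  df <- data.frame(query_id = as.character(query_id),
                   q_start = as.integer(q_start),
                   q_end = as.integer(q_end),
                   class_path = as.character(class_path),
                   family = as.character(family),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  if (any(df$q_start > df$q_end)) stop_contract("q_start > q_end")
  if (!all(df$source %in% c("known", "novel"))) {
    stop_contract("source must be 'known' or 'novel'")
  }
  unknown <- !(df$class_path %in% taxonomy)
  if (any(unknown)) {
    warning(sum(unknown), " annotation(s) with unresolvable class_path ",
            "routed to 'Unclassified'")
    df$class_path[unknown] <- "Unclassified"
  }
  class(df) <- c("repeat_annotations", "data.frame")
  df
}

empty_repeat_annotations <- function() {
  repeat_annotations(character(), integer(), integer(), character(),
                     character(), character())
}

## ---------------------------------------------------------------------------
## GFF3 / TSV serialization of SSR loci and repeat annotations

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("&", "%26", x, fixed = TRUE)
}

gff3_unescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  x <- gsub("%26", "&", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

## named character vector -> 'k1=v1;k2=v2', dropping NA values
gff3_attr_string <- function(attrs) {
  keep <- !is.na(attrs)
  paste(paste0(names(attrs)[keep], "=", gff3_escape(attrs[keep])),
        collapse = ";")
}

gff3_parse_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(gff3_unescape(vapply(kv, `[`, "", 2L)),
                  vapply(kv, `[`, "", 1L))
}

#' Write SSR loci or repeat annotations to GFF3 or TSV
#'
#' GFF3 output is 1-based inclusive with feature types
#' `microsatellite_region` (SSRs) and `repeat_region` (repeats); attributes
#' carry the motif / class-path metadata so that the matching reader
#' round-trips losslessly.
#'
#' @param records an `ssr_loci` or `repeat_annotations` data frame.
#' @param path output file.
#' @param format `"gff3"` or `"tsv"`.
#' @export
write_annotations <- function(records, path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  is_ssr <- inherits(records, "ssr_loci")
  if (format == "tsv") {
    df <- as.data.frame(records)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(records) == 0L) return(invisible(path))
  if (is_ssr) {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      attrs <- c(ID = paste0("ssr", i),
                 motif = r$motif, canonical_motif = r$canonical_motif,
                 motif_class = r$motif_class,
                 unit_len = as.character(r$unit_len),
                 n_units = as.character(r$n_units),
                 kind = r$kind, length_class = r$length_class,
                 members = r$members)
      paste(r$seq_id, "bessurvey", "microsatellite_region",
            r$start, r$end, ".", "+", ".", gff3_attr_string(attrs),
            sep = "\t")
    }, character(1))
  } else {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      attrs <- c(ID = paste0("rep", i),
                 class_path = r$class_path, family = r$family,
                 source = r$source)
      paste(r$query_id, "bessurvey", "repeat_region",
            r$q_start, r$q_end, ".", "+", ".", gff3_attr_string(attrs),
            sep = "\t")
    }, character(1))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read SSR loci or repeat annotations written by [write_annotations()]
#'
#' @param path input file.
#' @param format `"gff3"` or `"tsv"`.
#' @param type `"ssr"` or `"repeat"`; for GFF3 the feature type column is also
#'   checked.
#' @return an `ssr_loci` or `repeat_annotations` data frame.
#' @export
read_annotations <- function(path, format = c("gff3", "tsv"),
                             type = c("ssr", "repeat")) {
  format <- match.arg(format)
  type <- match.arg(type)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = NA, check.names = FALSE)
    if (type == "ssr") return(as_ssr_loci(df))
    if (nrow(df) == 0L) return(empty_repeat_annotations())
    return(repeat_annotations(df$query_id, df$q_start, df$q_end,
                              df$class_path, df$family, df$source))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) {
    return(if (type == "ssr") empty_ssr_loci() else empty_repeat_annotations())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) stop_contract("malformed GFF3 line ", bad[1], " in ", path)
  mat <- do.call(rbind, fields)
  attrs <- lapply(mat[, 9], gff3_parse_attrs)
  getattr <- function(key) {
    vapply(attrs, function(a) if (key %in% names(a)) a[[key]] else NA_character_,
           character(1))
  }
  if (type == "ssr") {
    df <- data.frame(seq_id = mat[, 1],
                     start = as.integer(mat[, 4]),
                     end = as.integer(mat[, 5]),
                     motif = getattr("motif"),
                     canonical_motif = getattr("canonical_motif"),
                     motif_class = getattr("motif_class"),
                     unit_len = as.integer(getattr("unit_len")),
                     n_units = as.integer(getattr("n_units")),
                     kind = getattr("kind"),
                     length_class = getattr("length_class"),
                     members = getattr("members"),
                     stringsAsFactors = FALSE)
    as_ssr_loci(df)
  } else {
    repeat_annotations(mat[, 1], as.integer(mat[, 4]), as.integer(mat[, 5]),
                       getattr("class_path"), getattr("family"),
                       getattr("source"))
  }
}
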