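test_that("read ids parse into clone id and end direction", {
  recs <- bes_set(c("F0001A1", "R0001A1"), c("ACGT", "TTAA"))
  expect_equal(recs$clone_id, c("0001A1", "0001A1"))
  expect_equal(recs$direction, c("forward", "reverse"))
  expect_s3_class(recs, "bes_set")
})

test_that("bes_set enforces its invariants", {
  expect_error(bes_set("F1", ""), "empty sequence")
  expect_error(bes_set("F1", "ACGTACGTAC", quality = list(1:9)),
               "quality length")
  recs <- bes_set("F1", "acgtxACGT")
  expect_equal(recs$bases, "ACGTNACGT")  # lowercase normalized, X -> N
})

test_that("FASTA and FASTQ round-trip through files", {
  recs <- bes_set(c("F0001A1", "R0001A1", "F0002B2"),
                  c("ACGTACGTAC", "TTAACCGGTT", "GATTACAGAT"),
                  quality = list(rep(30L, 10), rep(40L, 10), 11:20))
  fq <- tempfile(fileext = ".fastq")
  write_sequences(recs, fq, format = "fastq")
  back <- read_sequences(fq, format = "fastq")
  expect_equal(back$read_id, recs$read_id)
  expect_equal(back$bases, recs$bases)
  expect_equal(back$quality, recs$quality)
  fa <- tempfile(fileext = ".fa")
  write_sequences(recs, fa, format = "fasta")
  back_fa <- read_sequences(fa, format = "fasta")
  expect_equal(back_fa$bases, recs$bases)
  expect_true(all(vapply(back_fa$quality, is.null, logical(1))))
})

test_that("malformed FASTQ and empty files are handled", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@F1", "ACGTACGTAC", "+", "IIIIIIIII"), bad)  # 10 bp, 9 quals
  expect_error(read_sequences(bad, format = "fastq"), "malformed|length")
  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_warning(recs <- read_sequences(empty, format = "fasta"),
                 "no records")
  expect_equal(nrow(recs), 0L)
})

test_that("FASTA+QUAL pairs read with per-base scores", {
  fa <- tempfile(fileext = ".fa")
  qa <- tempfile(fileext = ".qual")
  writeLines(c(">F1", "ACGTA", ">R1", "TTAAC"), fa)
  writeLines(c(">F1", "20 30 40 30 20", ">R1", "10 10", "10 10 10"), qa)
  recs <- read_sequences(fa, format = "fasta-qual", qual_path = qa)
  expect_equal(recs$quality[[1]], c(20L, 30L, 40L, 30L, 20L))
  expect_equal(recs$quality[[2]], rep(10L, 5))
})

test_that("tabular hit parsing types fields and infers strand", {
  p <- tempfile()
  writeLines(c("q1\ts1\t98.0\t100\t2\t0\t1\t100\t200\t101\t1e-30\t180",
               "q2\ts1\t85.5\t60\t5\t1\t10\t69\t500\t559\t3.2e-05\t90"), p)
  h <- read_hits(p)
  expect_equal(h$strand, c("-", "+"))
  expect_equal(h$evalue[2], 3.2e-05)
  expect_equal(h$s_start[1], 200L)
  bad <- tempfile()
  writeLines("q1 s1 98.0 100 2 0 1 100 200 101 1e-30", bad)  # 11 columns
  expect_error(read_hits(bad), "row 1")
  bad2 <- tempfile()
  writeLines("q1 s1 98.0 100 2 0 1 xx 200 101 1e-30 180", bad2)
  expect_error(read_hits(bad2), "non-numeric")
})

test_that("hit tables round-trip through write_hits", {
  h <- random_hit_table(25)
  p <- tempfile()
  write_hits(h, p)
  back <- read_hits(p)
  for (cc in c("query_id", "q_start", "q_end", "s_start", "s_end", "strand")) {
    expect_equal(back[[cc]], h[[cc]])
  }
  expect_equal(back$evalue, h$evalue, tolerance = 1e-3)
})

test_that("strand inference is an involution under coordinate swap", {
  set.seed(5)
  for (i in 1:20) {
    a <- sample.int(1000, 1)
    b <- a + sample.int(500, 1)
    h1 <- ref_hit("q", "s", a, b, "+")
    swapped <- h1
    swapped$s_start <- h1$s_end
    swapped$s_end <- h1$s_start
    h2 <- as_hits(as.data.frame(swapped)[bessurvey:::hit_columns])
    expect_false(h1$strand == h2$strand)
  }
})

test_that("SSR loci round-trip through GFF3 and TSV", {
  loci <- find_perfect_ssrs(c(r1 = paste0("GG", strrep("AT", 8), strrep("C", 3),
                                          strrep("AAG", 6), "TT",
                                          strrep("A", 21))))
  loci <- merge_compound(loci, max_gap = 10)
  expect_true(any(loci$kind == "compound"))
  g <- tempfile(fileext = ".gff3")
  write_annotations(loci, g, format = "gff3")
  expect_equal(read_annotations(g, "gff3", "ssr"), loci)
  tsv <- tempfile(fileext = ".tsv")
  write_annotations(loci, tsv, format = "tsv")
  expect_equal(read_annotations(tsv, "tsv", "ssr"), loci)
})

test_that("GFF3 coordinates are 1-based inclusive and empty sets give a header-only file", {
  loci <- find_perfect_ssrs(c(x = paste0("GGGG", strrep("AT", 8), "GGGG")))
  expect_equal(loci$start, 5L)
  expect_equal(loci$end, 20L)
  g <- tempfile(fileext = ".gff3")
  write_annotations(loci, g, "gff3")
  line <- readLines(g)[2]
  expect_match(line, "\tmicrosatellite_region\t5\t20\t")
  g2 <- tempfile(fileext = ".gff3")
  write_annotations(bessurvey:::empty_ssr_loci(), g2, "gff3")
  expect_equal(readLines(g2), "##gff-version 3")
  expect_equal(nrow(read_annotations(g2, "gff3", "ssr")), 0L)
})

test_that("repeat annotations round-trip and unknown classes are rerouted", {
  ann <- repeat_annotations(
    c("F1", "F1", "R2"), c(10L, 200L, 1L), c(150L, 400L, 90L),
    c("Class I retrotransposon|LTR retrotransposons|Ty1/copia",
      "Class II DNA transposons|hobo-Activator", "Unclassified"),
    family = c("famA", "famB", "famC"), source = c("known", "known", "novel"))
  g <- tempfile(fileext = ".gff3")
  write_annotations(ann, g, "gff3")
  expect_equal(read_annotations(g, "gff3", "repeat"), ann)
  expect_warning(
    bad <- repeat_annotations("F1", 1L, 10L, "No Such Class"),
    "Unclassified")
  expect_equal(bad$class_path, "Unclassified")
})

test_that("a YAML taxonomy loads to the same paths as the built-in one", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("Class I retrotransposon:",
               "  LTR retrotransposons:",
               "    Ty1/copia: ~",
               "Unclassified: ~"), y)
  tax <- read_taxonomy(y)
  expect_true(all(tax %in% default_repeat_taxonomy()))
  expect_length(tax, 4L)
})
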