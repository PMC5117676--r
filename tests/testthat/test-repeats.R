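test_that("census bp use interval union within a class", {
  ann <- repeat_annotations(
    c("F1", "F1"), c(1L, 51L), c(100L, 150L),
    rep("Class I retrotransposon|LTR retrotransposons|Ty1/copia", 2),
    family = "famA")
  cen <- build_census(ann, total_bp = 1000)
  row <- cen[cen$class_path == "Class I retrotransposon", ]
  expect_equal(row$masked_bp, 150L)   # 1-100 U 51-150
  expect_equal(row$n_elements, 2L)    # element counts are not merged
  expect_equal(cen$masked_bp[cen$class_path == "Total repetitive DNA"], 150L)
})

test_that("an empty annotation set gives an all-zero census", {
  cen <- build_census(bessurvey:::empty_repeat_annotations(), total_bp = 100)
  expect_true(all(cen$masked_bp == 0L))
  expect_true(all(cen$pct_of_total == 0))
  expect_equal(nrow(cen), length(default_repeat_taxonomy()) + 2L)
})

test_that("the grand total row unions across classes, class rows within class", {
  # the same read interval annotated under two classes counts once in the
  # total but fully in each class row
  ann <- repeat_annotations(
    c("F1", "F1"), c(1L, 41L), c(100L, 120L),
    c("Class I retrotransposon|LTR retrotransposons|Ty1/copia",
      "Simple repeats"), family = c("famA", "(AT)n"))
  cen <- build_census(ann, total_bp = 1000)
  expect_equal(cen$masked_bp[cen$class_path == "Class I retrotransposon"], 100L)
  expect_equal(cen$masked_bp[cen$class_path == "Simple repeats"], 80L)
  expect_equal(cen$masked_bp[cen$class_path == "Total repetitive DNA"], 120L)
})

test_that("census percentages reproduce the worked example", {
  ann <- repeat_annotations("F1", 1L, 924646L, "Unclassified")
  cen <- build_census(ann, total_bp = 7595261)
  expect_equal(cen$pct_of_total[cen$class_path == "Total repetitive DNA"],
               12.17)
})

test_that("class shares recompute from a stored census", {
  p <- system.file("extdata", "sweetpotato_bes_census.tsv",
                   package = "bessurvey")
  cen <- read.table(p, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(census_share(cen, "Class I retrotransposon",
                            "Total repetitive DNA"), 69.92)
  expect_equal(census_share(cen,
                            "Class I retrotransposon|LTR retrotransposons",
                            "Class I retrotransposon"), 86.52)
})

test_that("known and novel percentages add on the already-rounded scale", {
  expect_equal(total_repeat_fraction(12.17, 18.31), 30.48)
  expect_equal(total_repeat_fraction(0, 0), 0)
  expect_error(total_repeat_fraction(60, 50), "100")
})

test_that("library masking finds planted copies and is idempotent", {
  set.seed(12)
  fam <- bessurvey:::scrub_ssrs(random_dna(200, 0.45))
  insert <- bessurvey:::scrub_ssrs(random_dna(300))
  recs <- bes_set(c("F1", "F2"),
                  c(paste0(substr(insert, 1, 100), fam,
                           substr(insert, 101, 300)),
                    random_dna(250)))
  mk <- mask_with_library(recs, c(famA = fam))
  expect_equal(nrow(mk$annotations), 1L)
  expect_equal(mk$annotations$q_start, 101L)
  expect_equal(mk$annotations$q_end, 300L)
  expect_equal(substr(mk$records$bases[1], 101, 300), strrep("N", 200))
  # the untouched read has no annotation
  expect_false("F2" %in% mk$annotations$query_id)
  # re-masking the masked output adds nothing
  mk2 <- mask_with_library(mk$records, c(famA = fam))
  expect_equal(nrow(mk2$annotations), 0L)
})

test_that("masking finds reverse-strand copies", {
  set.seed(13)
  fam <- bessurvey:::scrub_ssrs(random_dna(150, 0.45))
  recs <- bes_set("F1", paste0(random_dna(80), revcomp(fam), random_dna(80)))
  mk <- mask_with_library(recs, c(famA = fam))
  expect_equal(nrow(mk$annotations), 1L)
  expect_equal(mk$annotations$q_start, 81L)
  expect_equal(mk$annotations$q_end, 230L)
})

test_that("per-class masked bp equal a per-base oracle on random instances", {
  set.seed(14)
  paths <- default_repeat_taxonomy()
  leaf <- paths[c(3, 4, 10, 22)]
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    a <- sample.int(400, n, replace = TRUE)
    b <- pmin(500L, a + sample.int(120, n, replace = TRUE))
    cls <- sample(leaf, n, replace = TRUE)
    qid <- sample(c("F1", "R1"), n, replace = TRUE)
    ann <- repeat_annotations(qid, a, b, cls, family = "f")
    cen <- build_census(ann, total_bp = 1000)
    want_total <- sum(vapply(unique(qid), function(q) {
      sel <- qid == q
      per_base_union(a[sel], b[sel], 500)
    }, numeric(1)))
    expect_equal(cen$masked_bp[cen$class_path == "Total repetitive DNA"],
                 want_total)
    for (cl in unique(cls)) {
      want <- sum(vapply(unique(qid[cls == cl]), function(q) {
        sel <- qid == q & cls == cl
        per_base_union(a[sel], b[sel], 500)
      }, numeric(1)))
      expect_equal(cen$masked_bp[cen$class_path == cl], want)
    }
  }
})

test_that("novel masking on simulated reads recovers the planted fraction", {
  sb <- small_sim()
  qc <- qc_reads(sb$records, vector_seq = sb$components$vector_seq,
                 organelle_hits = sb$truth$hits$organelle)
  known <- truth_repeat_annotations(sb, "known", qc$records)
  masked <- mask_annotations(qc$records, known)
  mk <- mask_with_library(masked, sb$components$novel_library)
  total_bp <- sum(nchar(qc$records$bases))
  truth <- expected_read_features(sb, qc$records)$repeats
  truth_novel_bp <- sum(truth$end[truth$source == "novel"] -
                          truth$start[truth$source == "novel"] + 1L)
  got_pct <- 100 * sum(mk$annotations$q_end - mk$annotations$q_start + 1L) /
    total_bp
  expect_lt(abs(got_pct - 100 * truth_novel_bp / total_bp), 1)
})
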