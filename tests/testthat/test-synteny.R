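test_that("hit filtering uses inclusive boundaries", {
  h <- rbind(ref_hit("F1", "chr1", 100L, 159L, "+"),
             ref_hit("F2", "chr1", 100L, 149L, "+"))
  h$pct_identity <- c(69.9, 70.0)
  h$evalue <- c(1e-10, 1e-06)
  kept <- filter_hits(as_hits(h))
  expect_equal(kept$query_id, "F2")  # 70.0 / 50 bp / 1e-06 all inclusive
})

test_that("filtering equals a brute-force predicate scan on random hits", {
  set.seed(51)
  for (i in 1:20) {
    h <- random_hit_table(10)
    kept <- filter_hits(h)
    want <- h[h$pct_identity >= 70 & h$aln_length >= 50 &
                h$evalue <= 1e-06, ]
    expect_equal(kept$query_id, want$query_id)
    expect_equal(nrow(kept), nrow(want))
  }
})

test_that("best-hit selection is deterministic through every tie-break", {
  h <- rbind(ref_hit("F1", "chr1", 1L, 100L, "+"),
             ref_hit("F1", "chr1", 200L, 299L, "+"))
  h$bitscore <- c(180, 200)
  expect_equal(best_hit(as_hits(h))$s_start, 200L)
  h$bitscore <- c(200, 200)
  h$evalue <- c(1e-30, 1e-20)
  expect_equal(best_hit(as_hits(h))$s_start, 1L)
  h$evalue <- c(1e-30, 1e-30)
  h$subject_id <- c("chr2", "chr1")
  expect_equal(best_hit(as_hits(h))$subject_id, "chr1")
  expect_error(best_hit(empty_hits()), "at least one")
})

test_that("a published-style collinear pair classifies with the right span", {
  # reverse end beginning at 65,487,266 and forward end terminating at
  # 65,556,186 on one chromosome, facing inward
  rev_hit <- ref_hit("R358H9", "chr3", 65487266L, 65487865L, "+")
  fwd_hit <- ref_hit("F358H9", "chr3", 65555587L, 65556186L, "-")
  cp <- classify_pair(fwd_hit, rev_hit)
  expect_equal(cp$category, "PE_collinear")
  expect_equal(cp$span, 68921)
})

test_that("the category rule table is exhaustive over the 12-cell grid", {
  mk <- function(same_subject, orientation_ok, span) {
    plus <- ref_hit("F1", "chrA", 1000L, 1599L, "+")
    hi <- 999L + span
    minus <- ref_hit("R1", if (same_subject) "chrA" else "chrB",
                     hi - 599L, hi, if (orientation_ok) "-" else "+")
    classify_pair(plus, minus)
  }
  spans <- c(below = 5e3, inside = 100e3, above = 500e3)
  for (sp in names(spans)) {
    expect_equal(mk(FALSE, TRUE, spans[[sp]])$category, "PE_non_colocalized")
    expect_equal(mk(FALSE, FALSE, spans[[sp]])$category, "PE_non_colocalized")
    expect_equal(mk(TRUE, FALSE, spans[[sp]])$category, "PE_rearranged")
  }
  expect_equal(mk(TRUE, TRUE, spans[["inside"]])$category, "PE_collinear")
  expect_equal(mk(TRUE, TRUE, spans[["below"]])$category, "PE_gapped")
  expect_equal(mk(TRUE, TRUE, spans[["above"]])$category, "PE_gapped")
  # outward-facing opposite strands are wrong orientation, hence rearranged
  left_minus <- ref_hit("R1", "chrA", 1000L, 1599L, "-")
  right_plus <- ref_hit("F1", "chrA", 99400L, 99999L, "+")
  expect_equal(classify_pair(right_plus, left_minus)$category,
               "PE_rearranged")
  # single ends
  expect_equal(classify_pair(ref_hit("F1", "chrA", 1L, 100L, "+"),
                             NULL)$category, "SE")
  expect_error(classify_pair(NULL, NULL), "at least one")
})

test_that("classification is symmetric under swapping the two ends", {
  set.seed(52)
  for (i in 1:200) {
    same <- runif(1) < 0.5
    a <- ref_hit("F1", "chrA", 1000L, 1599L, sample(c("+", "-"), 1))
    hi <- 999L + sample(c(5e3, 1e5, 5e5), 1)
    b <- ref_hit("R1", if (same) "chrA" else "chrB",
                 as.integer(hi - 599), as.integer(hi),
                 sample(c("+", "-"), 1))
    c1 <- classify_pair(a, b)
    c2 <- classify_pair(b, a)
    expect_equal(c1$category, c2$category)
    expect_equal(c1$span, c2$span)
  }
})

test_that("clone pairing assigns exactly one category per clone", {
  sb <- small_sim()
  ref <- filter_hits(sb$truth$hits$reference)
  pairs <- classify_clone_pairs(ref)
  expect_equal(anyDuplicated(pairs$clone_id), 0L)
  expect_true(all(pairs$category %in%
                    c("SE", "PE_non_colocalized", "PE_collinear",
                      "PE_rearranged", "PE_gapped")))
  expect_equal(sum(synteny_summary(pairs)), nrow(pairs))
})

test_that("simulated clones with both clean ends are all collinear at true span", {
  sb <- small_sim()
  pairs <- classify_clone_pairs(filter_hits(sb$truth$hits$reference))
  cl <- sb$truth$clones
  good <- cl[cl$both_ends & !cl$any_organellar, ]
  p <- pairs[match(good$clone_id, pairs$clone_id), ]
  expect_true(all(p$category == "PE_collinear"))
  expect_equal(p$span, good$insert_size)
})

test_that("reference coverage counts queries, subjects and union bp", {
  h <- rbind(ref_hit("F1", "chr1", 1L, 100L, "+"),
             ref_hit("F1", "chr1", 51L, 150L, "+"),
             ref_hit("R2", "chr2", 10L, 60L, "+"))
  h <- as_hits(h)
  h$q_start <- c(1L, 51L, 10L)
  h$q_end <- c(100L, 150L, 60L)
  cov <- reference_coverage(h, by = "query")
  expect_equal(cov$n_queries_matched, 2L)
  expect_equal(cov$n_subjects_matched, 2L)
  expect_equal(cov$union_bp, 150L + 51L)
  covs <- reference_coverage(h, by = "subject")
  expect_equal(covs$union_bp, 150L + 51L)
  # worked example: 6,229,456 bp of 7,595,261 bp covered is 82.02%
  expect_equal(coding_fraction(6229456, 7595261), 82.02)
})
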