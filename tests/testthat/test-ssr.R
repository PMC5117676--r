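test_that("detection thresholds sit exactly at the published boundaries", {
  # mono needs 20 bp
  expect_equal(nrow(find_perfect_ssrs(c(x = strrep("A", 20)))), 1L)
  expect_equal(nrow(find_perfect_ssrs(c(x = strrep("A", 19)))), 0L)
  # di needs 15 bp of whole units => 8 units = 16 bp
  got <- find_perfect_ssrs(c(x = paste0("GG", strrep("AT", 8), "GG")))
  expect_equal(got$n_units, 8L)
  expect_equal(got$end - got$start + 1L, 16L)
  expect_equal(nrow(find_perfect_ssrs(c(x = paste0("GG", strrep("AT", 7),
                                                   "GG")))), 0L)
  # tri >= 5, tetra >= 4, penta >= 3, hexa >= 3 whole units
  for (case in list(c("ATC", 5, 1), c("ATC", 4, 0), c("AGAT", 4, 1),
                    c("AGAT", 3, 0), c("AACGT", 3, 1), c("AACGT", 2, 0),
                    c("AACGTC", 3, 1), c("AACGTC", 2, 0))) {
    s <- paste0("G", strrep(case[1], as.integer(case[2])), "G")
    expect_equal(nrow(find_perfect_ssrs(c(x = s))), as.integer(case[3]),
                 info = paste(case, collapse = "x"))
  }
})

test_that("the smallest primitive unit wins and N breaks runs", {
  # a poly-A run is (A)n, never (AA)n
  got <- find_perfect_ssrs(c(x = strrep("A", 24)))
  expect_equal(got$unit_len, 1L)
  expect_equal(got$n_units, 24L)
  # N interrupts: two half-runs below threshold detect nothing
  s <- paste0(strrep("A", 12), "N", strrep("A", 12))
  expect_equal(nrow(find_perfect_ssrs(c(x = s))), 0L)
  # partial trailing units are excluded
  got2 <- find_perfect_ssrs(c(x = paste0("CC", strrep("AT", 8), "A", "GG")))
  expect_equal(got2$end - got2$start + 1L, 16L)
})

test_that("motif canonicalization groups rotations and strands", {
  expect_equal(motif_class("TTA"), "AAT/ATT")
  expect_equal(standardize_motif("TTA"), "AAT")
  expect_equal(motif_class("CT"), "AG/CT")
  expect_equal(motif_class("AT"), "AT/AT")
  expect_equal(motif_class("A"), "A/T")
  expect_error(standardize_motif("ATAT"), "primitive")
})

test_that("canonicalization is idempotent, rotation- and strand-invariant", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    if (!bessurvey:::is_primitive_motif(m)) next
    cm <- standardize_motif(m)
    expect_equal(standardize_motif(cm), cm)
    expect_equal(standardize_motif(revcomp(m)), cm)
    rot <- bessurvey:::rotations(m)[sample(k, 1)]
    expect_equal(standardize_motif(rot), cm)
  }
})

test_that("compound merging follows the gap rule transitively", {
  s <- paste0("GG", strrep("AT", 8), random_dna(5, 0.5), strrep("AAG", 6))
  loci <- merge_compound(find_perfect_ssrs(c(x = s)), max_gap = 100)
  expect_equal(loci$kind, "compound")
  expect_equal(bessurvey:::count_members(loci$members), 2L)
  # gap of 101 bp stays two perfect loci
  set.seed(40)
  gap101 <- scrub <- bessurvey:::scrub_ssrs(random_dna(101, 0.5))
  s2 <- paste0("GG", strrep("AT", 8), gap101, strrep("AAG", 6))
  loci2 <- merge_compound(find_perfect_ssrs(c(x = s2)), max_gap = 100)
  expect_equal(sort(loci2$kind), c("perfect", "perfect"))
  # chain A-B-C with gaps 50, 50 merges into one compound of three members
  g50a <- bessurvey:::scrub_ssrs(random_dna(50, 0.5))
  g50b <- bessurvey:::scrub_ssrs(random_dna(50, 0.5))
  s3 <- paste0("GG", strrep("AT", 8), g50a, strrep("AAG", 6), g50b,
               strrep("A", 21))
  loci3 <- merge_compound(find_perfect_ssrs(c(x = s3)), max_gap = 100)
  expect_equal(loci3$kind, "compound")
  expect_equal(bessurvey:::count_members(loci3$members), 3L)
})

test_that("length classes split perfect SSRs at 20 bp", {
  loci <- find_perfect_ssrs(c(x = paste0(
    "GG", strrep("AT", 10),                      # 20 bp -> I
    bessurvey:::scrub_ssrs(random_dna(150, 0.5)),
    strrep("AAG", 5),                            # 15 bp -> II
    bessurvey:::scrub_ssrs(random_dna(150, 0.5)),
    strrep("A", 20))))                           # 20 bp -> I
  expect_equal(classify_length(loci), c("I", "II", "I"))
  comp <- merge_compound(find_perfect_ssrs(
    c(x = paste0("GG", strrep("AT", 8), "CCCG", strrep("AAG", 6)))),
    max_gap = 100)
  expect_error(classify_length(comp), "perfect")
})

test_that("the scan summary reports counts, splits and density", {
  sb <- small_sim()
  qc <- qc_reads(sb$records, vector_seq = sb$components$vector_seq,
                 organelle_hits = sb$truth$hits$organelle)
  loci <- merge_compound(find_perfect_ssrs(qc$records))
  sm <- ssr_summary(loci, total_bp = qc$stats$total_bp)
  expect_equal(sm$n_ssrs, sm$n_perfect + sm$n_compound)
  expect_equal(sm$n_class_I + sm$n_class_II, sm$n_perfect)
  expect_equal(sm$density_kb,
               round(qc$stats$total_bp / sm$n_ssrs / 1000, 2),
               tolerance = 0.01)
  # worked example: 3,846 loci over 7,595,261 bp is one SSR per 1.97 kb
  fake <- bessurvey:::empty_ssr_loci()
  expect_equal(ssr_summary(fake[0, ], 100)$density_kb, NA_real_)
  ten <- find_perfect_ssrs(c(x = paste0(
    strrep("A", 20), bessurvey:::scrub_ssrs(random_dna(120, 0.5)),
    strrep("AT", 8))))
  sm10 <- ssr_summary(ten, 1000)
  expect_equal(sm10$by_unit_len_pct[1], 50.00)
})

test_that("detector agrees with the brute-force oracle on random sequences", {
  set.seed(77)
  for (i in 1:150) {
    s <- random_dna(2000)
    got <- find_perfect_ssrs(c(x = s))
    want <- brute_force_ssrs(s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$motif, want$motif)
    }
  }
})

test_that("reverse-complementing a sequence preserves canonical classes and lengths", {
  set.seed(78)
  for (i in 1:25) {
    s <- paste0(random_dna(300), strrep("CT", 9), random_dna(300),
                strrep("TTA", 7), random_dna(300))
    f <- find_perfect_ssrs(c(x = s))
    r <- find_perfect_ssrs(c(x = revcomp(s)))
    expect_equal(sort(table(f$motif_class)), sort(table(r$motif_class)))
    expect_equal(sort(f$end - f$start), sort(r$end - r$start))
  }
})

test_that("planted SSRs are recovered exactly on clean simulated reads", {
  sb <- small_sim()
  qc <- qc_reads(sb$records, vector_seq = sb$components$vector_seq,
                 organelle_hits = sb$truth$hits$organelle)
  det <- find_perfect_ssrs(qc$records)
  want <- expected_read_features(sb, qc$records)$ssrs
  kd <- paste(det$seq_id, det$start, det$end, det$motif)
  ke <- paste(want$read_id, want$start, want$end, want$motif)
  expect_gt(length(ke), 10)
  expect_setequal(kd, ke)
})
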