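test_that("quality trimming removes low-quality ends only", {
  r <- bes_set("F1", "GACGTT", quality = list(c(5L, 30L, 30L, 30L, 5L, 4L)))
  t1 <- trim_by_quality(r, qmin = 20)
  expect_equal(t1$bases, "ACG")
  expect_equal(t1$quality[[1]], rep(30L, 3))
  expect_equal(t1$offset5, 1L)

  r2 <- bes_set("F2", "ACGGT", quality = list(c(30L, 20L, 5L, 20L, 40L)))
  expect_equal(trim_by_quality(r2)$bases, "ACGGT")  # interior low-Q retained

  r3 <- bes_set("F3", "ACGT", quality = list(rep(10L, 4)))
  t3 <- trim_by_quality(r3)
  expect_equal(t3$bases, "")
  expect_equal(t3$offset5, 4L)
  expect_error(trim_by_quality(bes_set("F4", "ACGT")), "qualities")
})

test_that("vector screening trims terminal matches and masks internal ones", {
  set.seed(9)
  vec <- random_dna(80, gc = 0.5)
  insert <- random_dna(200)
  r <- bes_set("F1", paste0(substr(vec, 1, 30), insert))
  out <- screen_vector(r, vec)
  expect_equal(out$bases, insert)
  expect_equal(out$offset5, 30L)

  clean <- bes_set("F2", insert)
  expect_equal(screen_vector(clean, vec)$bases, insert)

  pure <- bes_set("F3", substr(vec, 1, 60))
  expect_equal(screen_vector(pure, vec)$bases, "")

  internal <- bes_set("F4", paste0(substr(insert, 1, 100), substr(vec, 1, 40),
                                   substr(insert, 101, 200)))
  got <- screen_vector(internal, vec)$bases
  expect_equal(nchar(got), 240L)
  expect_equal(substr(got, 101, 140), strrep("N", 40))
})

test_that("length filter keeps the >= min_len boundary", {
  recs <- bes_set(paste0("F", 1:3),
                  vapply(c(99, 100, 101), random_dna, ""))
  lf <- filter_length(recs, min_len = 100)
  expect_equal(nchar(lf$kept$bases), c(100L, 101L))
  expect_equal(nrow(lf$removed), 1L)
  lf2 <- filter_length(lf$kept, min_len = 100)
  expect_equal(nrow(lf2$removed), 0L)
})

test_that("organelle partition follows the E-value cutoff exactly", {
  recs <- bes_set(c("F1", "F2", "F3"), replicate(3, random_dna(120)))
  hits <- as_hits(data.frame(
    query_id = c("F1", "F2"), subject_id = "mito", pct_identity = 99,
    aln_length = 100L, mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
    evalue = c(1e-16, 1e-14), bitscore = 180))
  of <- filter_organellar(recs, hits, e_cutoff = 1e-15)
  expect_equal(of$organellar$read_id, "F1")   # 1e-16 <= cutoff
  expect_equal(of$nuclear$read_id, c("F2", "F3"))
  expect_equal(nrow(of$nuclear) + nrow(of$organellar), nrow(recs))

  expect_equal(nrow(filter_organellar(recs, NULL)$organellar), 0L)
  hits$query_id[2] <- "nosuch"
  expect_warning(filter_organellar(recs, hits), "unknown reads")
})

test_that("dataset summary computes GC over called bases and pairs by clone", {
  recs <- bes_set(c("F1", "R1", "F2"), c("ATGC", "AATT", "NNGG"))
  st <- summarize_dataset(recs)
  expect_equal(st$n_paired, 2L)
  expect_equal(st$n_unpaired, 1L)
  expect_equal(st$total_bp, 12L)
  expect_equal(st$mean_len, 4.00)
  # GC over A+C+G+T only: (2 + 0 + 2) / 10, with the Ns excluded
  expect_equal(st$gc_percent, 40.00)
  st2 <- summarize_dataset(bes_set(c("F1", "R1"), c("ATGC", "AATT")))
  expect_equal(st2$gc_percent, 25.00)
  expect_equal(st2$total_bp, 8L)
  expect_error(summarize_dataset(recs[0, ]), "empty")
})

test_that("the QC stage conserves reads and is idempotent", {
  sb <- small_sim()
  qc1 <- qc_reads(sb$records, vector_seq = sb$components$vector_seq,
                  organelle_hits = sb$truth$hits$organelle)
  expect_equal(qc1$counts[["input"]],
               nrow(qc1$records) + nrow(qc1$removed_short) +
                 nrow(qc1$organellar))
  qc2 <- qc_reads(qc1$records, vector_seq = sb$components$vector_seq,
                  organelle_hits = sb$truth$hits$organelle)
  expect_equal(qc2$records$bases, qc1$records$bases)
  expect_equal(nrow(qc2$removed_short), 0L)
})

test_that("the markov quality model yields trimmable ends with tracked offsets", {
  cfg <- sim_config(seed = 301, genome_size = 2e5, n_clones = 25,
                    quality_model = "markov", vector_rate = 0,
                    contamination = 0, insert_meanlog = log(3e4),
                    insert_sdlog = 0.2, insert_min = 15e3, insert_max = 6e4)
  sb <- simulate_bes(simulate_genome(cfg))
  trimmed <- trim_by_quality(sb$records)
  expect_lt(sum(nchar(trimmed$bases)), sum(nchar(sb$records$bases)))
  kept <- trimmed[nchar(trimmed$bases) > 0, ]
  first_q <- vapply(kept$quality, `[`, 0L, 1L)
  last_q <- vapply(kept$quality, function(q) q[length(q)], 0L)
  expect_true(all(first_q >= 20 & last_q >= 20))
  # offset5 maps trimmed coordinates back onto the raw read
  i <- which(trimmed$offset5 > 0)[1]
  raw <- sb$records$bases[i]
  expect_equal(substr(raw, trimmed$offset5[i] + 1,
                      trimmed$offset5[i] + nchar(trimmed$bases[i])),
               trimmed$bases[i])
})

test_that("organellar removal is exact against simulation truth", {
  sb <- small_sim()
  qc <- qc_reads(sb$records, vector_seq = sb$components$vector_seq,
                 organelle_hits = sb$truth$hits$organelle)
  truth_org <- sb$truth$reads$read_id[sb$truth$reads$organellar]
  expect_setequal(qc$organellar$read_id, truth_org)
  expect_equal(qc$stats$n_organellar_removed, length(truth_org))
})
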