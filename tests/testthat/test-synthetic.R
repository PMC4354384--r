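test_that("simulated references hit their GC targets and are reproducible", {
  ref <- simulate_reference(c(chr1 = 50000), gc = 0.5, seed = 1L)
  freq <- Biostrings::letterFrequency(ref[[1]], c("C", "G"))
  gc_frac <- sum(freq) / 50000
  expect_lt(abs(gc_frac - 0.5), 0.01)        # ~4.5 binomial sd

  all_gc <- simulate_reference(c(chr1 = 1000), gc = 1, seed = 2L)
  expect_equal(sum(Biostrings::letterFrequency(all_gc[[1]], c("C", "G"))), 1000)

  expect_identical(as.character(simulate_reference(c(a = 2000), 0.4, seed = 3L)),
                   as.character(simulate_reference(c(a = 2000), 0.4, seed = 3L)))

  # region overrides
  reg <- data.frame(chrom = "chr1", start = 1L, end = 5000L, gc = 0.9)
  ref2 <- simulate_reference(c(chr1 = 10000), gc = reg, seed = 4L)
  head_gc <- sum(Biostrings::letterFrequency(
    Biostrings::subseq(ref2[[1]], 1, 5000), c("C", "G"))) / 5000
  tail_gc <- sum(Biostrings::letterFrequency(
    Biostrings::subseq(ref2[[1]], 5001, 10000), c("C", "G"))) / 5000
  expect_gt(head_gc, 0.85)
  expect_lt(abs(tail_gc - 0.5), 0.05)
})

test_that("the read simulator enforces its low-quality quotas exactly", {
  s1 <- small_s1(n = 2000L, seed = 5L)
  truth <- s1$sim$truth
  expect_equal(sum(truth$is_lowq_read), round(0.09 * 2000))
  expect_equal(sum(truth$n_lowq_bases), round(0.03 * 2000 * 100))

  # truth log agrees with the quality strings themselves
  reads <- decode_qualities(s1$sim$reads, quality_encoding("illumina-1.8"))
  nlow <- vapply(reads$scores, function(s) sum(s < 20), integer(1))
  expect_equal(nlow, truth$n_lowq_bases)

  # reads come from where the truth log says (error-free reads match the reference)
  clean <- which(truth$n_errors == 0 & is.na(truth$adapter_start))[1:50]
  chrom <- as.character(s1$ref[["chr1"]])
  for (i in clean) {
    expect_equal(reads$seq[i],
                 substr(chrom, truth$start[i], truth$start[i] + 99L))
  }
})

test_that("adapter contamination follows the fragment-size model", {
  s1 <- small_s1(n = 2000L, seed = 6L)
  truth <- s1$sim$truth
  contaminated <- !is.na(truth$adapter_start)
  # P(fragment < 100) for Normal(150, 50) is about 16%
  expect_gt(mean(contaminated), 0.10)
  expect_lt(mean(contaminated), 0.23)
  # the adapter prefix really is at the logged position
  idx <- which(contaminated & truth$n_errors == 0)[1:30]
  for (i in idx) {
    tail_len <- 100L - truth$adapter_start[i] + 1L
    expect_equal(substring(s1$sim$reads$seq[i], truth$adapter_start[i]),
                 substr(ILLUMINA_SE_ADAPTER1, 1, tail_len))
  }
  # far-tail fragment distribution: no contamination
  far <- small_s1(n = 500L, seed = 7L, fragment_mean = 400, fragment_sd = 20)
  expect_equal(sum(!is.na(far$sim$truth$adapter_start)), 0L)
})

test_that("the error model is position-increasing with the configured mean", {
  s1 <- small_s1(n = 5000L, seed = 8L, pct_lowq_bases = 0, pct_lowq_reads = 0,
                 fragment_mean = 400, fragment_sd = 20)
  truth <- s1$sim$truth
  rate <- sum(truth$n_errors) / (5000 * 100)
  expect_lt(abs(rate - 0.02), 0.002)
  # errors concentrate in the 3' half (exponential decay curve, shape 3)
  chrom <- as.character(s1$ref[["chr1"]])
  originals <- substring(chrom, truth$start, truth$start + 99L)
  mism_pos <- unlist(lapply(which(truth$n_errors > 0)[1:500], function(i) {
    which(strsplit(s1$sim$reads$seq[i], "")[[1]] != strsplit(originals[i], "")[[1]])
  }))
  expect_gt(mean(mism_pos > 50), 0.70)
})

test_that("infeasible quality quotas are rejected up front", {
  ref <- simulate_reference(c(chr1 = 10000), gc = 0.5, seed = 9L)
  # 50% low-quality reads need >= 11 bases each; 0.1% of bases cannot cover that
  cfg <- sim_config(n_reads = 1000L, pct_lowq_reads = 50, pct_lowq_bases = 0.1,
                    seed = 9L)
  expect_error(simulate_reads(ref, cfg), class = "rdprep_config_error")
})

test_that("simulators are pure functions of (config, seed)", {
  ref <- simulate_reference(c(chr1 = 100000), gc = 0.45, seed = 10L)
  cfg <- sim_config(n_reads = 500L, seed = 11L)
  a <- simulate_reads(ref, cfg)
  b <- simulate_reads(ref, cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)

  d1 <- inject_duplicates(a$reads, cfg)
  d2 <- inject_duplicates(a$reads, cfg)
  expect_identical(d1$reads, d2$reads)

  s1 <- ideal_alignment_sam(ref, coverage = 3, read_len = 50, seed = 12L)
  s2 <- ideal_alignment_sam(ref, coverage = 3, read_len = 50, seed = 12L)
  expect_identical(s1, s2)
})

test_that("duplicate injection respects fraction, protected prefix and mismatch bounds", {
  s1 <- small_s1(n = 1400L, seed = 13L)
  cfg <- s1$cfg
  s2 <- inject_duplicates(s1$sim$reads, cfg)
  n_dup <- nrow(s2$truth)
  expect_equal(n_dup, round(0.3 / 0.7 * 1400))
  expect_equal(nrow(s2$reads), 1400L + n_dup)
  # copies sit after all originals so the collapse seed is always the source
  expect_equal(s2$reads$id[1:1400], s1$sim$reads$id)

  by_id <- setNames(s1$sim$reads$seq, s1$sim$reads$id)
  for (j in seq_len(n_dup)) {
    src <- by_id[[s2$truth$source_id[j]]]
    copy <- s2$reads$seq[1400L + j]
    expect_equal(substr(copy, 1, 25), substr(src, 1, 25))
    d <- hamming(substring(copy, 26), substring(src, 26))
    expect_equal(d, s2$truth$n_mismatches[j])
    expect_gte(d, 1L)
    expect_lte(d, cfg$dup_max_suffix_mismatch)
  }

  # dup_fraction 0: identity
  cfg0 <- sim_config(n_reads = 1400L, dup_fraction = 0, seed = 13L)
  expect_identical(inject_duplicates(s1$sim$reads, cfg0)$reads, s1$sim$reads)
})

test_that("dedup recovers the injected duplicates via the truth log", {
  s1 <- small_s1(n = 1400L, seed = 14L)
  s2 <- inject_duplicates(s1$sim$reads, s1$cfg)
  res <- dedup_library(s2$reads, dedup_policy(25, 1))
  # every copy is collapsed into its source's representative
  expect_lte(sum(s2$truth$copy_id %in% res$reads$id), 2L)
  expect_gte(res$stats$removed, nrow(s2$truth) - 2L)
})

test_that("the ideal aligner yields the expected mean window depth", {
  ref <- simulate_reference(c(chr1 = 100000), gc = 0.5, seed = 15L)
  aln <- ideal_alignment_sam(ref, coverage = 30, read_len = 100, seed = 16L)
  expect_equal(nrow(aln), 30000L)
  expect_true(all(aln$mapq == 60L))
  expect_true(all(aln$cigar == "100M"))
  expect_true(all(aln$pos >= 1L & aln$pos <= 100000L - 99L))
  tr <- raw_rd(aln, gc_signal(ref, 100))
  expect_equal(sum(tr$raw_rd), nrow(aln))
  expect_lt(abs(mean(tr$raw_rd) - 30), 1)   # coverage * L / read_len
})
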