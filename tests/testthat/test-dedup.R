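test_that("prefix keys are base-5 positional values with the A<C<G<T<N digit map", {
  expect_equal(encode_prefix(strrep("A", 27), 27), "0")
  expect_equal(encode_prefix("CA", 2), "5")                 # 1*5 + 0
  expect_equal(encode_prefix("ACGTN", 5), "194")            # 0,1,2,3,4 base-5
  # order preservation on lexicographic prefix order under A<C<G<T<N
  seqs <- c("AAAA", "AACA", "ACGT", "CAAA", "TGCA", "NNNN")
  keys <- as.numeric(encode_prefix(seqs, 4))
  expect_true(all(diff(keys) > 0))
  # limits
  expect_error(encode_prefix("ACGT", 28), "27")
  expect_error(encode_prefix("ACG", 4), "shorter")
})

test_that("chunk codes are decimal digit concatenations with exact mismatch localization", {
  expect_equal(encode_chunk(c("CA", "AAAA", "NT")), c("10", "0", "43"))
  expect_error(encode_chunk(strrep("A", 20)), "19")

  expect_true(is.na(leftmost_mismatch(encode_chunk("ACGT"), encode_chunk("ACGT"), 4)))
  expect_equal(leftmost_mismatch(encode_chunk("AT"), encode_chunk("CT"), 2), 0L)
  expect_equal(leftmost_mismatch(encode_chunk("CT"), encode_chunk("CA"), 2), 1L)
  # partial cancellation: |03 - 10| = 7 still localizes position 0 exactly
  expect_equal(leftmost_mismatch(encode_chunk("AT"), encode_chunk("CA"), 2), 0L)

  # randomized agreement with direct character comparison
  withr::local_seed(31L)
  for (i in 1:200) {
    a <- rand_seqs(1, 12, with_n = TRUE)
    b <- rand_seqs(1, 12, with_n = TRUE)
    expected <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])[1] - 1L
    got <- leftmost_mismatch(encode_chunk(a), encode_chunk(b), 12)
    if (a == b) expect_true(is.na(got)) else expect_equal(got, expected)
  }
})

test_that("chunked mismatch counting equals the Hamming distance up to the cap", {
  expect_equal(count_mismatches("ACGTACGT", "ACGTACGT", 3), 0L)
  expect_equal(count_mismatches("ACGTACGT", "ACGAACGT", 1), 1L)
  expect_gt(count_mismatches("AAAAAAAA", "TTTAAAAT", 1), 1L)   # early abort
  expect_error(count_mismatches("ACG", "ACGT", 1), "equal length")

  # randomized at read scale (length 75) against the plain R oracle
  withr::local_seed(7L)
  for (i in 1:300) {
    a <- rand_seqs(1, 75, with_n = TRUE)
    nmut <- sample(0:6, 1)
    b <- a
    if (nmut > 0) {
      pos <- sample(75, nmut)
      for (p in pos) {
        old <- substr(b, p, p)
        substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T", "N"), old), 1)
      }
    }
    h <- hamming(a, b)
    m <- sample(0:6, 1)
    got <- count_mismatches(a, b, m, chunk_len = sample(c(3L, 7L, 19L), 1))
    if (h <= m) expect_equal(got, h) else expect_gt(got, m)
  }
})

test_that("prefix clustering equals hash-grouping by the literal k-prefix", {
  # 4 reads, two sharing a prefix
  cl <- cluster_by_prefix(c("AAACG", "AAATT", "CCCGG", "GGGTT"), 3)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(length(unique(cl$cluster)), 3L)

  expect_equal(nrow(cluster_by_prefix(character(), 5)), 0L)

  # short reads are set aside with NA
  cl <- cluster_by_prefix(c("ACGTACGT", "ACG"), 5)
  expect_true(is.na(cl$cluster[2]))

  # random libraries: same partition as grouping by substring
  withr::local_seed(11L)
  for (k in c(2L, 5L, 11L)) {
    seqs <- rand_seqs(400, 12, with_n = TRUE)
    got <- cluster_by_prefix(seqs, k)$cluster
    oracle <- as.integer(factor(substr(seqs, 1, k)))
    expect_equal(length(unique(got)), length(unique(oracle)))
    # identical partitions: co-membership must agree
    expect_true(all(tapply(oracle, got, function(v) length(unique(v))) == 1))
  }
})

test_that("greedy collapse condenses duplicates and leaves representatives > m apart", {
  pol <- dedup_policy(prefix_len = 4, max_mismatches = 1)
  base <- "AAAATTTTGGGGCCCC"
  mut <- function(s, pos) { substr(s, pos, pos) <- "A"; s }
  reads <- make_reads(c(base, mut(base, 6), mut(mut(mut(base, 6), 8), 10)))

  res <- collapse_cluster(reads, 1:3, pol)
  expect_equal(nrow(res$representatives), 2L)    # seed+1mm collapse; 3mm survives
  expect_equal(res$removed, 1L)
  expect_equal(res$seeds, c(1L, 3L))

  # identical reads collapse to one for any m
  same <- make_reads(rep(base, 4))
  res0 <- collapse_cluster(same, 1:4, dedup_policy(4, 0))
  expect_equal(nrow(res0$representatives), 1L)
  expect_equal(res0$removed, 3L)

  # singleton untouched
  res1 <- collapse_cluster(reads, 2L, pol)
  expect_equal(res1$removed, 0L)
  expect_equal(res1$representatives$seq, reads$seq[2])
})

test_that("consensus is per-position majority with ties resolved to the seed", {
  same <- make_reads(c("ACGT", "ACGT"))
  expect_equal(build_consensus(same)$seq, "ACGT")
  maj <- make_reads(c("ACGT", "ACGA", "ACGA"))
  expect_equal(build_consensus(maj)$seq, "ACGA")
  tie <- make_reads(c("ACGT", "ACGA"))
  expect_equal(build_consensus(tie)$seq, "ACGT")
  # id and quality come from the seed
  out <- build_consensus(make_reads(c("ACGA", "ACGT"), quals = c("!!!!", "IIII"),
                                    ids = c("seed", "dup")))
  expect_equal(out$id, "seed")
  expect_equal(out$qual, "!!!!")
})

test_that("dedup at k with m=0 equals exact-string deduplication", {
  withr::local_seed(13L)
  seqs <- sample(rand_seqs(40, 30, with_n = TRUE), 150, replace = TRUE)
  reads <- make_reads(seqs)
  res <- dedup_library(reads, dedup_policy(prefix_len = 27, max_mismatches = 0))
  expect_equal(sort(unique(seqs)), sort(res$reads$seq))
  expect_equal(res$stats$removed, length(seqs) - length(unique(seqs)))
})

test_that("reads shorter than the prefix bypass dedup and are kept", {
  reads <- make_reads(c("ACGTACGTACGT", "ACG", "ACG", "ACGTACGTACGT"))
  res <- dedup_library(reads, dedup_policy(prefix_len = 8, max_mismatches = 0))
  expect_equal(res$stats$short_reads, 2L)
  expect_equal(sum(res$reads$seq == "ACG"), 2L)     # short duplicates survive
  expect_equal(res$stats$removed, 1L)
})

test_that("surviving representatives within a cluster are pairwise > m apart", {
  withr::local_seed(23L)
  pol <- dedup_policy(prefix_len = 5, max_mismatches = 1)
  # many reads sharing few prefixes so clusters are deep
  prefixes <- rand_seqs(6, 5)
  seqs <- paste0(sample(prefixes, 300, replace = TRUE),
                 rand_seqs(300, 10, with_n = TRUE))
  res <- dedup_library(make_reads(seqs), pol)
  surv <- res$reads$seq
  by_prefix <- split(surv, substr(surv, 1, 5))
  for (grp in by_prefix) {
    grp <- grp[order(grp)]
    if (length(grp) < 2) next
    for (i in seq_along(grp)) {
      for (j in seq_len(i - 1L)) {
        if (nchar(grp[i]) != nchar(grp[j])) next
        d <- hamming(substring(grp[i], 6), substring(grp[j], 6))
        expect_gt(d, pol$max_mismatches)
      }
    }
  }
})

test_that("removal is monotone in the allowed mismatches and deterministic", {
  withr::local_seed(29L)
  prefixes <- rand_seqs(10, 6)
  seqs <- paste0(sample(prefixes, 400, replace = TRUE),
                 sample(rand_seqs(60, 12), 400, replace = TRUE))
  reads <- make_reads(seqs)
  removed <- vapply(c(0L, 1L, 3L), function(m) {
    dedup_library(reads, dedup_policy(6, m))$stats$removed
  }, integer(1))
  expect_true(all(diff(removed) >= 0))

  # byte-identical output across reruns
  p <- write_tmp_fastq(reads)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(dedup_library(p, dedup_policy(6, 1))$reads, f1)
  write_fastq(dedup_library(p, dedup_policy(6, 1))$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("paired layouts are rejected and policies validated", {
  expect_error(dedup_library(make_reads("ACGT"), paired = TRUE),
               class = "rdprep_unsupported_layout")
  expect_error(dedup_policy(prefix_len = 28), class = "rdprep_config_error")
  expect_error(dedup_policy(chunk_len = 20), class = "rdprep_config_error")
  expect_error(dedup_policy(max_mismatches = -1), class = "rdprep_config_error")
})
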