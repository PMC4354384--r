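ref_of <- function(...) Biostrings::DNAStringSet(c(...))

test_that("window GC uses informative bases with half-up rounding and a validity rule", {
  ref <- ref_of(chr1 = paste0(strrep("GC", 50),          # 100% GC
                              paste0(strrep("A", 50), strrep("G", 50)),  # 50%
                              strrep("N", 100)))          # uninformative
  gc <- gc_signal(ref, 100)
  expect_equal(gc$gc_pct, c(100L, 50L, NA))
  expect_equal(gc$valid, c(TRUE, TRUE, FALSE))
  expect_equal(gc$start, c(0L, 100L, 200L))
  expect_equal(gc$end, c(100L, 200L, 300L))

  # terminal window shorter than half the window length is invalid
  gc2 <- gc_signal(ref_of(chr1 = strrep("ACGT", 30)), 100)   # 120 bp
  expect_equal(gc2$valid, c(TRUE, FALSE))

  # empty sequence: zero windows
  expect_equal(nrow(gc_signal(ref_of(chr1 = ""), 100)), 0L)

  # half-up rounding of the percentage
  gc3 <- gc_signal(ref_of(chr1 = paste0(strrep("G", 45), strrep("A", 55),
                                        strrep("G", 46), strrep("A", 54))), 100)
  expect_equal(gc3$gc_pct, c(45L, 46L))
})

test_that("window assignment follows the read-center rule", {
  aln <- tibble::tibble(pos = c(1L, 951L, 1L), aln_span = c(100L, 100L, 1L),
                        mapped = TRUE)
  expect_equal(assign_window(aln, 100, "center"), c(0L, 9L, 0L))
  expect_equal(assign_window(aln, 100, "start"), c(0L, 9L, 0L))
  # start vs center differ when the footprint crosses a boundary
  aln2 <- tibble::tibble(pos = 95L, aln_span = 100L, mapped = TRUE)
  expect_equal(assign_window(aln2, 100, "start"), 0L)
  expect_equal(assign_window(aln2, 100, "center"), 1L)
})

test_that("raw read depth counts assigned alignments and conserves their total", {
  ref <- simulate_reference(c(chrA = 3000, chrB = 2000), gc = 0.5, seed = 21L)
  gc <- gc_signal(ref, 100)

  empty <- tibble::tibble(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          aln_span = integer(), score = integer(),
                          mapped = logical())
  tr0 <- raw_rd(empty, gc)
  expect_true(all(tr0$raw_rd == 0L))

  three <- tibble::tibble(qname = c("a", "b", "c"), flag = 0L, rname = "chrA",
                          pos = c(210L, 220L, 260L), mapq = 60L, cigar = "20M",
                          aln_span = 20L, score = NA_integer_, mapped = TRUE)
  tr3 <- raw_rd(three, gc)
  expect_equal(tr3$raw_rd[tr3$chrom == "chrA" & tr3$window == 2L], 3L)
  expect_equal(sum(tr3$raw_rd), 3L)

  # conservation under random placement on both chromosomes
  aln <- ideal_alignment_sam(ref, coverage = 5, read_len = 50, seed = 22L)
  for (rule in c("center", "start")) {
    tr <- raw_rd(aln, gc, rule)
    expect_equal(sum(tr$raw_rd), nrow(aln))
  }
  # alignments on unknown sequences are skipped with a warning
  stray <- dplyr::mutate(three, rname = c("chrA", "chrZ", "chrZ"))
  expect_warning(trs <- raw_rd(stray, gc), "skipped")
  expect_equal(sum(trs$raw_rd), 1L)
})

test_that("GC correction rescales bins to the global mean (worked two-bin case)", {
  # two valid windows in bins 40 and 60 with raw depths 10 and 20
  track <- tibble::tibble(
    chrom = "c", window = 0:1, start = c(0L, 100L), end = c(100L, 200L),
    informative = 100L, gc_pct = c(40L, 60L), valid = TRUE,
    raw_rd = c(10L, 20L))
  attr(track, "window_len") <- 100L
  class(track) <- c("rdprep_rd_track", class(track))
  corr <- gc_correct(track)
  expect_equal(corr$corrected_rd, c(15, 15))

  # all windows in one bin: correction collapses to the identity
  track1 <- dplyr::mutate(track, gc_pct = 50L)
  attr(track1, "window_len") <- 100L
  class(track1) <- c("rdprep_rd_track", class(track1))
  expect_equal(gc_correct(track1)$corrected_rd, c(10, 20))

  # degree-1 homogeneity: doubling raw doubles corrected
  track2 <- dplyr::mutate(track, raw_rd = raw_rd * 2L)
  attr(track2, "window_len") <- 100L
  class(track2) <- c("rdprep_rd_track", class(track2))
  expect_equal(gc_correct(track2)$corrected_rd, 2 * corr$corrected_rd)
})

test_that("corrected bin means equal the global mean and invalid windows stay raw", {
  ref <- simulate_reference(c(chr1 = 200000), gc = 0.45, seed = 23L)
  aln <- ideal_alignment_sam(ref, coverage = 10, read_len = 100, seed = 24L)
  gc <- gc_signal(ref, 100)
  corr <- gc_correct(raw_rd(aln, gc))
  grand <- mean(corr$raw_rd[corr$valid])
  bin_means <- tapply(corr$corrected_rd[corr$valid], corr$gc_pct[corr$valid], mean)
  expect_true(all(abs(bin_means - grand) / grand < 1e-9))
  expect_equal(mean(corr$corrected_rd[corr$valid]), grand, tolerance = 1e-12)
  # zero raw stays zero
  expect_true(all(corr$corrected_rd[corr$raw_rd == 0] == 0))

  # genome scope pools chromosomes
  ref2 <- simulate_reference(c(a = 50000, b = 50000), gc = c(0.3, 0.6), seed = 25L)
  aln2 <- ideal_alignment_sam(ref2, coverage = 8, read_len = 50, seed = 26L)
  tr2 <- raw_rd(aln2, gc_signal(ref2, 100))
  corr2 <- gc_correct(tr2, scope = "genome")
  g2 <- mean(corr2$raw_rd[corr2$valid])
  bm2 <- tapply(corr2$corrected_rd[corr2$valid], corr2$gc_pct[corr2$valid], mean)
  expect_true(all(abs(bm2 - g2) / g2 < 1e-9))
})

test_that("invalid windows are flagged uncorrected and keep their raw value", {
  ref <- ref_of(chr1 = paste0(strrep("AG", 100), strrep("N", 100)))
  gc <- gc_signal(ref, 100)
  aln <- tibble::tibble(qname = c("a", "b"), flag = 0L, rname = "chr1",
                        pos = c(10L, 210L), mapq = 60L, cigar = "10M",
                        aln_span = 10L, score = NA_integer_, mapped = TRUE)
  corr <- gc_correct(raw_rd(aln, gc))
  inval <- corr[!corr$valid, ]
  expect_equal(inval$corrected_rd, as.numeric(inval$raw_rd))
  expect_false(any(inval$corrected))
})

test_that("track TSV and bedGraph exports round-trip and tile the genome", {
  ref <- simulate_reference(c(chr1 = 5000), gc = 0.5, seed = 27L)
  aln <- ideal_alignment_sam(ref, coverage = 4, read_len = 50, seed = 28L)
  corr <- gc_correct(raw_rd(aln, gc_signal(ref, 100)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_track(corr, tsv, bedgraph = bg)
  back <- read_track(tsv)
  expect_equal(back$raw_rd, corr$raw_rd)
  expect_equal(back$corrected_rd, corr$corrected_rd)
  expect_equal(back$gc_pct, corr$gc_pct)

  lines <- strsplit(readLines(bg), "\t")
  starts <- as.integer(vapply(lines, `[`, character(1), 2))
  ends <- as.integer(vapply(lines, `[`, character(1), 3))
  expect_equal(starts, seq(0L, 4900L, by = 100L))   # each tile exactly once
  expect_equal(ends, c(seq(100L, 5000L, by = 100L)))

  # empty track: header-only TSV
  write_track(corr[0, ], tsv)
  expect_equal(length(readLines(tsv)), 1L)
})

test_that("track plots build without error", {
  ref <- simulate_reference(c(chr1 = 5000), gc = 0.5, seed = 29L)
  aln <- ideal_alignment_sam(ref, coverage = 4, read_len = 50, seed = 30L)
  tr <- raw_rd(aln, gc_signal(ref, 100))
  corr <- gc_correct(tr)
  expect_s3_class(autoplot(corr), "ggplot")
  expect_s3_class(autoplot(gc_profile(tr)), "ggplot")
  expect_s3_class(glance(corr), "tbl_df")
})
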