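#' Low-quality read filter policy
#'
#' A base is low quality when its Phred score is *below* `qual_threshold`.
#' A read is removed when the percentage of low-quality bases strictly
#' exceeds `100 - min_good_pct` (with the usual settings, threshold 20 and
#' 90% required good bases, a 100 bp read with 11 low-quality bases is
#' removed and one with 10 is kept).
#'
#' @param qual_threshold Phred score below which a base counts as low quality.
#' @param min_good_pct Minimum percentage of good (non-low-quality) bases a
#'   read must have to be kept, in \[0, 100\].
#' @param paired_mode When `TRUE`, a read pair is removed if either mate fails.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(qual_threshold = 20L, min_good_pct = 90, paired_mode = FALSE) {
  if (min_good_pct < 0 || min_good_pct > 100) {
    rlang::abort("min_good_pct must be in [0, 100]", class = "rdprep_config_error")
  }
  structure(list(qual_threshold = as.integer(qual_threshold),
                 min_good_pct = as.numeric(min_good_pct),
                 paired_mode = isTRUE(paired_mode)),
            class = "filter_policy")
}

# count of bases with score < threshold, per read (fast path on raw quals)
low_quality_counts <- function(reads, qual_threshold) {
  enc <- reads_encoding(reads)
  count_below_cpp(reads$qual, enc$ascii_offset + as.integer(qual_threshold))
}

# removal predicate shared by filter_low_quality() and quality_report()
fails_filter <- function(reads, policy) {
  nlow <- low_quality_counts(reads, policy$qual_threshold)
  len <- nchar(reads$seq)
  fail <- rep(TRUE, nrow(reads))        # zero-length reads are removed
  nz <- len > 0L
  fail[nz] <- 100 * nlow[nz] / len[nz] > (100 - policy$min_good_pct)
  fail
}

#' Remove reads with too many low-quality bases
#'
#' Applies the strict-exceed rule of [filter_policy()] read by read (or pair
#' by pair), preserving input order. The result is the kept tibble with a
#' `stats` attribute; use [glance()] to retrieve the counts.
#'
#' @param reads Read tibble with decoded qualities (see [decode_qualities()]);
#'   undecoded tibbles are assumed Illumina 1.8+ (offset 33).
#' @param policy A [filter_policy()].
#' @param mate Optional mate tibble for paired libraries: a pair is removed
#'   when either mate fails, keeping the two files synchronized.
#' @return Kept reads (class `rdprep_filter`), or `list(reads=, mate=)` in
#'   paired mode; both carry a `stats` attribute with `total`, `removed`,
#'   `kept` and `pct_removed`.
#' @export
filter_low_quality <- function(reads, policy = filter_policy(), mate = NULL) {
  stopifnot(inherits(policy, "filter_policy"))
  if (any(nchar(reads$seq) == 0L)) {
    rlang::warn(sprintf("%d zero-length read(s) removed", sum(nchar(reads$seq) == 0L)))
  }
  fail <- fails_filter(reads, policy)
  if (!is.null(mate)) {
    if (nrow(mate) != nrow(reads)) {
      rlang::abort("paired filtering requires equally sized mate tibbles",
                   class = "rdprep_contract_error")
    }
    fail <- fail | fails_filter(mate, policy)
    stats <- tibble::tibble(total = nrow(reads), removed = sum(fail),
                            kept = sum(!fail),
                            pct_removed = 100 * sum(fail) / max(1L, nrow(reads)))
    out <- list(reads = reads[!fail, , drop = FALSE],
                mate = mate[!fail, , drop = FALSE])
    attr(out, "stats") <- stats
    class(out) <- c("rdprep_filter_pair", class(out))
    return(out)
  }
  kept <- reads[!fail, , drop = FALSE]
  attr(kept, "stats") <- tibble::tibble(
    total = nrow(reads), removed = sum(fail), kept = sum(!fail),
    pct_removed = 100 * sum(fail) / max(1L, nrow(reads)))
  class(kept) <- c("rdprep_filter", class(kept))
  kept
}

#' Mask low-quality bases with N
#'
#' Replaces every base whose Phred score is below `qual_threshold` with `N`.
#' Read ids, lengths and quality strings are unchanged, so masking is
#' idempotent (a masked `N` keeps its low score but is already `N`).
#'
#' @inheritParams filter_low_quality
#' @param qual_threshold Phred score below which a base is masked.
#' @return The read tibble with masked `seq` (class `rdprep_mask`) and a
#'   `stats` attribute (`bases`, `masked`, `pct_masked`).
#' @export
mask_low_quality <- function(reads, qual_threshold = 20L) {
  enc <- reads_encoding(reads)
  cutoff <- enc$ascii_offset + as.integer(qual_threshold)
  n_masked <- sum(count_below_cpp(reads$qual, cutoff))
  reads$seq <- mask_low_cpp(reads$seq, reads$qual, cutoff)
  total <- sum(nchar(reads$seq))
  attr(reads, "stats") <- tibble::tibble(
    bases = total, masked = n_masked,
    pct_masked = 100 * n_masked / max(1L, total))
  class(reads) <- unique(c("rdprep_mask", class(reads)))
  reads
}

#' Summarize low-quality content of a library
#'
#' Computes the same per-base and per-read statistics the filter and masker
#' act on: counts of bases below `qual_threshold` and of reads failing the
#' strict-exceed rule at `min_good_pct`.
#'
#' @inheritParams filter_low_quality
#' @param qual_threshold Phred score below which a base counts as low quality.
#' @param min_good_pct Minimum good-base percentage used for the per-read rule.
#' @return One-row tibble: `reads`, `bases`, `lowq_bases`, `pct_lowq_bases`,
#'   `lowq_reads`, `pct_lowq_reads`.
#' @export
quality_report <- function(reads, qual_threshold = 20L, min_good_pct = 90) {
  policy <- filter_policy(qual_threshold, min_good_pct)
  if (nrow(reads) == 0L) {
    return(tibble::tibble(reads = 0L, bases = 0L, lowq_bases = 0L,
                          pct_lowq_bases = 0, lowq_reads = 0L,
                          pct_lowq_reads = 0))
  }
  nlow <- low_quality_counts(reads, qual_threshold)
  n_reads <- nrow(reads)
  n_bases <- sum(nchar(reads$seq))
  fail <- fails_filter(reads, policy)
  tibble::tibble(
    reads = n_reads,
    bases = n_bases,
    lowq_bases = sum(nlow),
    pct_lowq_bases = 100 * sum(nlow) / max(1L, n_bases),
    lowq_reads = sum(fail),
    pct_lowq_reads = 100 * sum(fail) / n_reads)
}

#' @export
glance.rdprep_filter <- function(x, ...) attr(x, "stats")

#' @export
glance.rdprep_filter_pair <- function(x, ...) attr(x, "stats")

#' @export
glance.rdprep_mask <- function(x, ...) attr(x, "stats")
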