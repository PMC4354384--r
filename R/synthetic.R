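#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults reproduce
#' the study conditions the rest of the package is validated against:
#' 100 bp single-end reads carrying 2% substitution errors whose per-base
#' rate follows an exponential-decay curve (errors increase towards the 3'
#' end), 3' contamination with Illumina single-end adapter 1 under normally
#' distributed fragment sizes, quality strings with exactly 3% low-quality
#' bases (Phred < 20) and 9% low-quality reads, and a duplicated-read stage
#' producing 30% duplicates that are identical over their first 25 bases and
#' carry at most 1 suffix mismatch.
#'
#' @param n_reads Number of reads to simulate.
#' @param read_len Read length in bases.
#' @param error_rate Mean per-base substitution error rate.
#' @param decay_shape Shape of the exponential error curve
#'   `p(i) = A exp(decay_shape * i / read_len)`, scaled so the mean is
#'   `error_rate`.
#' @param pct_lowq_bases Target percentage of bases below `qual_threshold`,
#'   enforced exactly.
#' @param pct_lowq_reads Target percentage of reads failing the
#'   (`qual_threshold`, `min_good_pct`) filter rule, enforced exactly.
#' @param qual_threshold Phred threshold defining a low-quality base.
#' @param min_good_pct Good-base percentage of the filter rule the low-quality
#'   read quota refers to.
#' @param adapter Contaminating 3' adapter sequence.
#' @param fragment_mean,fragment_sd Normal fragment-size parameters (bases);
#'   reads from fragments shorter than `read_len` get adapter read-through.
#' @param dup_fraction Fraction of the final library that is duplicated
#'   copies (see [inject_duplicates()]).
#' @param dup_prefix_protect Number of leading bases kept error-free in every
#'   duplicated copy.
#' @param dup_max_suffix_mismatch Maximum suffix mismatches per copy; every
#'   copy carries at least one.
#' @param coverage Fold coverage for [ideal_alignment_sam()].
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 100000L, read_len = 100L, error_rate = 0.02,
                       decay_shape = 3, pct_lowq_bases = 3, pct_lowq_reads = 9,
                       qual_threshold = 20L, min_good_pct = 90,
                       adapter = ILLUMINA_SE_ADAPTER1,
                       fragment_mean = 150, fragment_sd = 50,
                       dup_fraction = 0.30, dup_prefix_protect = 25L,
                       dup_max_suffix_mismatch = 1L, coverage = 30,
                       seed = 1L) {
  cfg <- list(n_reads = as.integer(n_reads), read_len = as.integer(read_len),
              error_rate = error_rate, decay_shape = decay_shape,
              pct_lowq_bases = pct_lowq_bases, pct_lowq_reads = pct_lowq_reads,
              qual_threshold = as.integer(qual_threshold),
              min_good_pct = min_good_pct, adapter = toupper(adapter),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              dup_fraction = dup_fraction,
              dup_prefix_protect = as.integer(dup_prefix_protect),
              dup_max_suffix_mismatch = as.integer(dup_max_suffix_mismatch),
              coverage = coverage, seed = as.integer(seed))
  bad <- c(
    if (cfg$error_rate < 0 || cfg$error_rate > 1) "error_rate must be in [0, 1]",
    if (cfg$pct_lowq_bases < 0 || cfg$pct_lowq_bases > 100) "pct_lowq_bases must be in [0, 100]",
    if (cfg$pct_lowq_reads < 0 || cfg$pct_lowq_reads > 100) "pct_lowq_reads must be in [0, 100]",
    if (cfg$fragment_sd < 0) "fragment_sd must be >= 0",
    if (cfg$dup_fraction < 0 || cfg$dup_fraction >= 1) "dup_fraction must be in [0, 1)",
    if (cfg$dup_prefix_protect > cfg$read_len) "dup_prefix_protect must be <= read_len",
    if (cfg$dup_max_suffix_mismatch > cfg$read_len - cfg$dup_prefix_protect)
      "dup_max_suffix_mismatch exceeds the unprotected suffix length")
  if (length(bad) > 0L) {
    rlang::abort(bad[1L], class = "rdprep_config_error")
  }
  class(cfg) <- "sim_config"
  cfg
}

sample_bases_codes <- function(len, gc) {
  # codepoints: A=65 C=67 G=71 T=84
  is_gc <- runif(len) < gc
  pick <- runif(len) < 0.5
  codes <- integer(len)
  codes[is_gc] <- ifelse(pick[is_gc], 71L, 67L)
  codes[!is_gc] <- ifelse(pick[!is_gc], 65L, 84L)
  codes
}

#' Simulate a reference genome with controlled GC content
#'
#' Draws i.i.d. bases with a specified GC fraction, either uniform per
#' chromosome or with region-level overrides, so the expected window GC of
#' the result is known by construction.
#'
#' @param lengths Integer vector of chromosome lengths (names become
#'   chromosome names; unnamed sequences are called `chr1`, `chr2`, ...).
#' @param gc GC fraction: a scalar, a vector recycled over chromosomes, or a
#'   data frame with columns `chrom`, `start`, `end` (1-based closed) and
#'   `gc` overriding regions.
#' @param seed Integer seed.
#' @param path Optional FASTA path to write.
#' @return A `Biostrings::DNAStringSet`.
#' @export
simulate_reference <- function(lengths, gc = 0.5, seed = 1L, path = NULL) {
  stopifnot(all(lengths >= 1L))
  nm <- names(lengths) %||% paste0("chr", seq_along(lengths))
  regions <- NULL
  if (is.data.frame(gc)) {
    regions <- gc
    gc_base <- rep(0.5, length(lengths))
  } else {
    gc_base <- rep_len(as.numeric(gc), length(lengths))
  }
  ref <- withr::with_seed(as.integer(seed), {
    seqs <- lapply(seq_along(lengths), function(i) {
      len <- as.integer(lengths[i])
      p <- rep(gc_base[i], len)
      if (!is.null(regions)) {
        rows <- regions[regions$chrom == nm[i], , drop = FALSE]
        for (j in seq_len(nrow(rows))) {
          p[rows$start[j]:min(rows$end[j], len)] <- rows$gc[j]
        }
      }
      intToUtf8(sample_bases_codes(len, p))
    })
    Biostrings::DNAStringSet(setNames(unlist(seqs), nm))
  })
  if (!is.null(path)) Biostrings::writeXStringSet(ref, path)
  ref
}

# per-base error curve: A * exp(shape * i / L), scaled to mean error_rate
error_curve <- function(read_len, error_rate, decay_shape) {
  raw <- exp(decay_shape * seq_len(read_len) / read_len)
  p <- error_rate * read_len * raw / sum(raw)
  if (any(p > 1)) {
    rlang::abort("error curve exceeds probability 1; reduce decay_shape or error_rate",
                 class = "rdprep_config_error")
  }
  p
}

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

substitute_bases <- function(seqs, idx, pos, rng_u) {
  # replace seqs[idx] at pos with a uniformly drawn different base
  cur <- substr(seqs[idx], pos, pos)
  alt <- vapply(seq_along(idx), function(j) {
    choices <- OTHER_BASES[[cur[j]]]
    choices[ceiling(rng_u[j] * length(choices))]
  }, character(1L))
  substr(seqs[idx], pos, pos) <- alt
  seqs
}

# exact allocation of `total` extra units over reads with capacities `cap`
allocate_exact <- function(total, cap) {
  extra <- integer(length(cap))
  rem <- total
  while (rem > 0L) {
    avail <- which(extra < cap)
    if (length(avail) == 0L) {
      rlang::abort("low-quality base quota infeasible under the per-read caps",
                   class = "rdprep_config_error")
    }
    if (rem <= length(avail)) {
      idx <- if (length(avail) == 1L) avail else sample(avail, rem)
      extra[idx] <- extra[idx] + 1L
      rem <- 0L
    } else {
      extra[avail] <- extra[avail] + 1L
      rem <- rem - length(avail)
    }
  }
  extra
}

#' Simulate an error-bearing, adapter-contaminated read library
#'
#' Emulates a standard short-read simulation: reads drawn uniformly from the
#' reference; substitution errors with per-base probability
#' `A exp(decay_shape * i / read_len)` scaled so the mean equals
#' `error_rate`; fragment sizes drawn from
#' `Normal(fragment_mean, fragment_sd)` with 3' adapter read-through whenever
#' the fragment is shorter than the read; and quality strings constructed so
#' that *exactly* `round(pct_lowq_reads/100 * n)` reads fail the
#' (`qual_threshold`, `min_good_pct`) filter rule and *exactly*
#' `round(pct_lowq_bases/100 * n * read_len)` bases score below
#' `qual_threshold`. Erroneous bases are preferentially assigned the low
#' scores; the exact quotas are enforced by post-adjustment. Qualities are
#' written on the Phred+33 (Illumina 1.8+) scale.
#'
#' @param reference A `DNAStringSet` or FASTA path.
#' @param config A [sim_config()].
#' @return List with `reads` (tibble `id`, `seq`, `qual`) and `truth`
#'   (tibble `id`, `chrom`, `start`, `frag_len`, `adapter_start`, `n_errors`,
#'   `n_lowq_bases`, `is_lowq_read`).
#' @export
simulate_reads <- function(reference, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ref <- as_dna_set(reference)
  n <- config$n_reads
  L <- config$read_len
  if (any(Biostrings::width(ref) < L)) {
    rlang::abort("every reference sequence must be at least read_len long",
                 class = "rdprep_config_error")
  }
  chrom_names <- sub("\\s.*$", "", names(ref) %||% paste0("chr", seq_along(ref)))
  chrom_seqs <- as.character(ref)
  widths <- Biostrings::width(ref)

  withr::with_seed(config$seed, {
    ## origin
    chrom_i <- sample.int(length(ref), n, replace = TRUE,
                          prob = widths - L + 1)
    start <- floor(runif(n) * (widths[chrom_i] - L + 1)) + 1L
    seqs <- unname(substr(chrom_seqs[chrom_i], start, start + L - 1L))

    ## adapter read-through for short fragments
    alen <- nchar(config$adapter)
    frag <- as.integer(round(rnorm(n, config$fragment_mean, config$fragment_sd)))
    frag <- pmax(frag, L - alen)     # adapter prefix exactly fills the 3' end
    contaminated <- frag < L
    adapter_start <- ifelse(contaminated, frag + 1L, NA_integer_)
    if (any(contaminated)) {
      ci <- which(contaminated)
      seqs[ci] <- paste0(substr(seqs[ci], 1L, frag[ci]),
                         substring(config$adapter, 1L, L - frag[ci]))
    }

    ## position-dependent substitution errors
    p <- error_curve(L, config$error_rate, config$decay_shape)
    err_read <- integer(0)
    err_pos <- integer(0)
    for (i in seq_len(L)) {
      hit <- which(runif(n) < p[i])
      if (length(hit) > 0L) {
        seqs <- substitute_bases(seqs, hit, i, runif(length(hit)))
        err_read <- c(err_read, hit)
        err_pos <- c(err_pos, rep.int(i, length(hit)))
      }
    }
    n_errors <- tabulate(err_read, nbins = n)
    err_by_read <- split(err_pos, factor(err_read, levels = seq_len(n)))

    ## low-quality quotas (exact)
    bad_limit <- L * (100 - config$min_good_pct) / 100
    bad_fail <- floor(bad_limit + 1e-9) + 1L     # smallest count failing the filter
    bad_keep <- floor(bad_limit)                 # largest count still kept
    n_lq <- as.integer(round(config$pct_lowq_reads / 100 * n))
    target <- as.integer(round(config$pct_lowq_bases / 100 * (as.numeric(n) * L)))
    if (target < n_lq * bad_fail) {
      rlang::abort(sprintf(
        "infeasible quotas: %d low-quality reads need >= %d low-quality bases but the base quota is %d",
        n_lq, n_lq * bad_fail, target), class = "rdprep_config_error")
    }
    is_lq <- rep(FALSE, n)
    if (n_lq > 0L) is_lq[sample.int(n, n_lq)] <- TRUE
    counts <- integer(n)
    counts[is_lq] <- bad_fail
    cap <- ifelse(is_lq, L - bad_fail, bad_keep)
    counts <- counts + allocate_exact(target - n_lq * bad_fail, cap)

    ## score matrix: good scores 28..40, low scores 2..19 (both < / >= threshold 20)
    scores <- matrix(sample.int(13L, n * L, replace = TRUE) + 27L, nrow = n)
    for (i in which(counts > 0L)) {
      ei <- err_by_read[[i]]
      c_i <- counts[i]
      pos_low <- if (length(ei) >= c_i) {
        if (length(ei) == 1L) ei else sample(ei, c_i)
      } else {
        rest <- setdiff(seq_len(L), ei)
        extra_n <- c_i - length(ei)
        c(ei, if (extra_n == 1L && length(rest) == 1L) rest else sample(rest, extra_n))
      }
      scores[i, pos_low] <- sample.int(18L, c_i, replace = TRUE) + 1L
    }
    quals <- vapply(seq_len(n), function(i) intToUtf8(scores[i, ] + 33L),
                    character(1L))

    ids <- sprintf("r%07d", seq_len(n))
    list(
      reads = tibble::tibble(id = ids, seq = seqs, qual = quals),
      truth = tibble::tibble(
        id = ids, chrom = chrom_names[chrom_i], start = start,
        frag_len = frag, adapter_start = adapter_start,
        n_errors = n_errors, n_lowq_bases = counts, is_lowq_read = is_lq))
  })
}

#' Inject near-duplicate reads into a library
#'
#' Appends PCR-duplicate-like copies of randomly chosen source reads until
#' the copies make up `dup_fraction` of the final library. Every copy is
#' identical to its source over the first `dup_prefix_protect` bases and
#' carries between 1 and `dup_max_suffix_mismatch` substitution mismatches in
#' the remaining suffix (never an indel), the number drawn from a
#' `Binomial(suffix_len, error_rate)` clamped to that range. Copies are
#' appended after the source library, so under greedy seed-first collapse the
#' seed of every duplicate group is the original read.
#'
#' @param reads Read tibble (e.g. from [simulate_reads()]).
#' @param config A [sim_config()]; uses `dup_fraction`,
#'   `dup_prefix_protect`, `dup_max_suffix_mismatch`, `error_rate`, `seed`.
#' @return List with `reads` (original + copies) and `truth` (tibble
#'   `copy_id`, `source_id`, `n_mismatches`).
#' @export
inject_duplicates <- function(reads, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(reads)
  f <- config$dup_fraction
  protect <- config$dup_prefix_protect
  maxm <- config$dup_max_suffix_mismatch
  if (maxm > config$read_len - protect) {
    rlang::abort("dup_max_suffix_mismatch exceeds the unprotected suffix length",
                 class = "rdprep_config_error")
  }
  n_dup <- as.integer(round(f / (1 - f) * n))
  if (n_dup == 0L) {
    return(list(reads = reads,
                truth = tibble::tibble(copy_id = character(),
                                       source_id = character(),
                                       n_mismatches = integer())))
  }
  withr::with_seed(config$seed + 1L, {
    eligible <- which(nchar(reads$seq) > protect)
    if (length(eligible) == 0L) {
      rlang::abort("no read is longer than dup_prefix_protect; cannot inject duplicates",
                   class = "rdprep_config_error")
    }
    src <- sample(eligible, n_dup, replace = TRUE)
    seqs <- reads$seq[src]
    lens <- nchar(seqs)
    suffix_len <- lens - protect
    nmis <- pmin(pmax(rbinom(n_dup, suffix_len, config$error_rate), 1L),
                 pmin(maxm, suffix_len))
    for (j in seq_len(n_dup)) {
      pos <- protect + (if (suffix_len[j] == 1L) 1L
                        else sample.int(suffix_len[j], nmis[j]))
      for (p in pos) {
        seqs <- substitute_bases(seqs, j, p, runif(1L))
      }
    }
    copy_id <- paste0(reads$id[src], "_dup", seq_len(n_dup))
    copies <- tibble::tibble(id = copy_id, seq = seqs, qual = reads$qual[src])
    list(reads = dplyr::bind_rows(reads[, c("id", "seq", "qual")], copies),
         truth = tibble::tibble(copy_id = copy_id,
                                source_id = reads$id[src],
                                n_mismatches = nmis))
  })
}

#' Simulate an ideal-aligner SAM file
#'
#' Places reads uniformly at random on the reference and emits one primary,
#' perfect-match alignment per read (full-length CIGAR match, maximal MAPQ),
#' the way an error-free aligner with unique mappings would. The number of
#' reads is `round(coverage * genome_length / read_len)`, so the expected
#' raw depth of an `L`-base window is `coverage * L / read_len`.
#'
#' @param reference A `DNAStringSet` or FASTA path.
#' @param coverage Fold coverage.
#' @param read_len Read length in bases.
#' @param seed Integer seed.
#' @param path Optional SAM path to write.
#' @return An alignment tibble (as from [read_sam()]) with a `header`
#'   attribute.
#' @export
ideal_alignment_sam <- function(reference, coverage = 30, read_len = 100L,
                                seed = 1L, path = NULL) {
  stopifnot(coverage > 0)
  ref <- as_dna_set(reference)
  read_len <- as.integer(read_len)
  chrom_names <- sub("\\s.*$", "", names(ref) %||% paste0("chr", seq_along(ref)))
  widths <- Biostrings::width(ref)
  if (any(widths < read_len)) {
    rlang::abort("every reference sequence must be at least read_len long",
                 class = "rdprep_config_error")
  }
  n <- as.integer(round(coverage * sum(as.numeric(widths)) / read_len))
  aln <- withr::with_seed(as.integer(seed), {
    chrom_i <- sample.int(length(ref), n, replace = TRUE,
                          prob = as.numeric(widths))
    pos <- floor(runif(n) * (widths[chrom_i] - read_len + 1)) + 1L
    tibble::tibble(
      qname = sprintf("sim%08d", seq_len(n)),
      flag = 0L,
      rname = chrom_names[chrom_i],
      pos = as.integer(pos),
      mapq = 60L,
      cigar = paste0(read_len, "M"),
      aln_span = read_len,
      score = NA_integer_,
      mapped = TRUE)
  })
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", chrom_names, "\tLN:", widths))
  attr(aln, "header") <- header
  if (!is.null(path)) write_sam(aln, path)
  aln
}
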