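as_dna_set <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  rlang::abort("reference must be a DNAStringSet or a path to a FASTA file",
               class = "rdprep_io_error")
}

#' Windowed GC-content signal of a reference
#'
#' Tiles every sequence with non-overlapping windows of `window_len` bases
#' (the last window may be short) and computes the integer GC percentage of
#' each window over its informative (non-N) bases, rounding half up. A window
#' with fewer than `window_len / 2` informative bases is flagged invalid and
#' gets an `NA` GC bin; invalid windows are excluded from the correction
#' statistics of [gc_correct()]. Windows use 0-based half-open coordinates
#' (BED convention).
#'
#' @param reference A `Biostrings::DNAStringSet` or FASTA path.
#' @param window_len Window length in bases.
#' @return A tibble of class `rdprep_gc_signal`: `chrom`, `window` (0-based
#'   index), `start`, `end` (0-based half-open), `informative`, `gc_pct`
#'   (integer or `NA`), `valid`; attribute `window_len`.
#' @export
gc_signal <- function(reference, window_len = 100L) {
  window_len <- as.integer(window_len)
  stopifnot(window_len >= 1L)
  ref <- as_dna_set(reference)
  per_chrom <- lapply(seq_along(ref), function(i) {
    chrom <- names(ref)[i] %||% as.character(i)
    chrom <- sub("\\s.*$", "", chrom)
    len <- Biostrings::width(ref)[i]
    if (len == 0L) {
      return(tibble::tibble(chrom = character(), window = integer(),
                            start = integer(), end = integer(),
                            informative = integer(), gc_pct = integer(),
                            valid = logical()))
    }
    starts <- seq.int(1L, len, by = window_len)
    ends <- pmin(starts + window_len - 1L, len)
    v <- Biostrings::Views(ref[[i]], start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    informative <- as.integer(rowSums(freq))
    gc <- as.integer(freq[, "C"] + freq[, "G"])
    gc_pct <- ifelse(informative > 0L,
                     as.integer(floor(100 * gc / informative + 0.5)),
                     NA_integer_)
    valid <- 2L * informative >= window_len
    tibble::tibble(chrom = chrom, window = seq_along(starts) - 1L,
                   start = starts - 1L, end = ends,
                   informative = informative,
                   gc_pct = ifelse(valid, gc_pct, NA_integer_),
                   valid = valid)
  })
  out <- dplyr::bind_rows(per_chrom)
  attr(out, "window_len") <- window_len
  class(out) <- unique(c("rdprep_gc_signal", class(out)))
  out
}

#' Assign alignments to read-depth windows
#'
#' Under the default `"center"` rule the window holding the center of the
#' alignment's reference footprint is used: for a record at 1-based position
#' `pos` consuming `aln_span` reference bases, the center is
#' `floor((2 * pos + aln_span - 1) / 2)` and the 0-based window index is
#' `(center - 1) %/% window_len`. Under `"start"` the window holding `pos`
#' is used.
#'
#' @param alignments Alignment tibble (see [read_sam()]).
#' @param window_len Window length in bases.
#' @param rule `"center"` (default) or `"start"`.
#' @return Integer vector of 0-based window indices.
#' @export
assign_window <- function(alignments, window_len, rule = c("center", "start")) {
  rule <- rlang::arg_match(rule)
  window_len <- as.integer(window_len)
  if (rule == "center") {
    centre <- (2L * alignments$pos + alignments$aln_span - 1L) %/% 2L
    (centre - 1L) %/% window_len
  } else {
    (alignments$pos - 1L) %/% window_len
  }
}

#' Raw read-depth track over a window grid
#'
#' Counts, for every window of the GC signal, the alignments assigned to it
#' by [assign_window()]. Alignments on sequences absent from the grid, or
#' whose assigned window falls outside it, are skipped and counted. The sum
#' of `raw_rd` over all windows equals the number of assigned alignments.
#'
#' @param alignments Mapped, filtered alignment tibble.
#' @param gc A `rdprep_gc_signal` from [gc_signal()]; its windows define the
#'   grid.
#' @param rule Window-assignment rule, see [assign_window()].
#' @return A tibble of class `rdprep_rd_track` = the GC signal plus `raw_rd`;
#'   attributes `window_len`, `assigned`, `skipped`.
#' @export
raw_rd <- function(alignments, gc, rule = c("center", "start")) {
  rule <- rlang::arg_match(rule)
  stopifnot(inherits(gc, "rdprep_gc_signal"))
  window_len <- attr(gc, "window_len")
  aln <- alignments[alignments$mapped & !is.na(alignments$pos), , drop = FALSE]
  aln$.win <- assign_window(aln, window_len, rule)
  counts <- aln |>
    dplyr::count(.data$rname, .data$.win, name = "raw_rd") |>
    dplyr::rename(chrom = "rname", window = ".win")
  out <- gc |>
    dplyr::left_join(counts, by = c("chrom", "window")) |>
    dplyr::mutate(raw_rd = dplyr::coalesce(.data$raw_rd, 0L))
  assigned <- sum(out$raw_rd)
  skipped <- nrow(aln) - assigned
  if (skipped > 0L) {
    rlang::warn(sprintf(
      "%d alignment(s) skipped (sequence absent from grid or window out of range)",
      skipped))
  }
  attr(out, "window_len") <- window_len
  attr(out, "assigned") <- assigned
  attr(out, "skipped") <- skipped
  class(out) <- unique(c("rdprep_rd_track", setdiff(class(out), "rdprep_gc_signal")))
  out
}

#' GC profile of a read-depth track
#'
#' Mean raw read depth per integer GC bin over valid windows, plus the global
#' mean over all valid windows, computed per chromosome or genome-wide.
#'
#' @param track A `rdprep_rd_track`.
#' @param scope `"chromosome"` (statistics per sequence, the default) or
#'   `"genome"` (one set of statistics for the whole track).
#' @return A tibble of class `rdprep_gc_profile`: `group`, `gc_pct`,
#'   `n_windows`, `mean_raw`, `grand_mean`.
#' @export
gc_profile <- function(track, scope = c("chromosome", "genome")) {
  scope <- rlang::arg_match(scope)
  valid <- track[track$valid, , drop = FALSE]
  valid$group <- if (scope == "chromosome") valid$chrom else "genome"
  prof <- valid |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(grand_mean = mean(.data$raw_rd)) |>
    dplyr::group_by(.data$group, .data$gc_pct, .data$grand_mean) |>
    dplyr::summarise(n_windows = dplyr::n(),
                     mean_raw = mean(.data$raw_rd), .groups = "drop") |>
    dplyr::select("group", "gc_pct", "n_windows", "mean_raw", "grand_mean")
  class(prof) <- unique(c("rdprep_gc_profile", class(prof)))
  prof
}

#' GC-bias correction of a read-depth track
#'
#' Rescales the raw read depth of every valid window by the ratio of the
#' global mean depth to the mean depth of windows sharing its GC bin:
#' `corrected = raw * mean(RD) / mean(RD | GC bin)`. Windows with zero raw
#' depth get zero; invalid windows keep their raw value and are flagged
#' uncorrected. After correction the mean of `corrected_rd` within every GC
#' bin (over valid windows) equals the global mean, so the bin-level GC trend
#' is removed while total signal is preserved. Statistics run per chromosome
#' by default; `scope = "genome"` pools them.
#'
#' @inheritParams gc_profile
#' @return The track with columns `corrected_rd` and `corrected` (logical
#'   flag); attribute `gc_profile` holds the profile used.
#' @export
gc_correct <- function(track, scope = c("chromosome", "genome")) {
  scope <- rlang::arg_match(scope)
  stopifnot(inherits(track, "rdprep_rd_track"))
  prof <- gc_profile(track, scope)
  track$group <- if (scope == "chromosome") track$chrom else "genome"
  out <- track |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(prof), "group", "gc_pct",
                    "mean_raw", "grand_mean"),
      by = c("group", "gc_pct"))
  # a valid window with raw > 0 contributes its own count to its bin,
  # so its bin mean cannot be zero
  stopifnot(!any(out$valid & out$raw_rd > 0 &
                   (is.na(out$mean_raw) | out$mean_raw == 0)))
  out$corrected <- out$valid & !is.na(out$mean_raw) & out$mean_raw > 0
  out$corrected_rd <- ifelse(!out$valid, as.numeric(out$raw_rd),
                             ifelse(out$raw_rd == 0, 0,
                                    out$raw_rd * out$grand_mean / out$mean_raw))
  out$group <- NULL
  out$mean_raw <- NULL
  out$grand_mean <- NULL
  attr(out, "window_len") <- attr(track, "window_len")
  attr(out, "assigned") <- attr(track, "assigned")
  attr(out, "gc_profile") <- prof
  class(out) <- unique(c("rdprep_rd_track", class(out)))
  out
}

#' Write / read a read-depth track
#'
#' `write_track()` writes a TSV with columns `chrom`, `start`, `end`,
#' `gc_pct`, `raw_rd`, `corrected_rd`, `valid` (0-based half-open
#' coordinates) and optionally a bedGraph of the corrected signal;
#' `read_track()` reads the TSV back.
#'
#' @param track A `rdprep_rd_track`.
#' @param path Destination TSV path.
#' @param bedgraph Optional path for a bedGraph export of `corrected_rd`
#'   (raw depth when the track is uncorrected).
#' @return The TSV path, invisibly.
#' @export
write_track <- function(track, path, bedgraph = NULL) {
  out <- tibble::tibble(
    chrom = track$chrom, start = track$start, end = track$end,
    gc_pct = track$gc_pct, raw_rd = track$raw_rd,
    corrected_rd = if ("corrected_rd" %in% names(track)) track$corrected_rd else NA_real_,
    valid = track$valid)
  readr::write_tsv(out, path)
  if (!is.null(bedgraph)) {
    score <- if ("corrected_rd" %in% names(track)) track$corrected_rd else track$raw_rd
    writeLines(paste(track$chrom, track$start, track$end, score, sep = "\t"),
               bedgraph)
  }
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), gc_pct = readr::col_integer(),
    raw_rd = readr::col_integer(), corrected_rd = readr::col_double(),
    valid = readr::col_logical()))
  class(out) <- unique(c("rdprep_rd_track", class(out)))
  out
}

#' @export
glance.rdprep_rd_track <- function(x, ...) {
  tibble::tibble(
    windows = nrow(x),
    valid_windows = sum(x$valid),
    assigned = attr(x, "assigned") %||% NA_integer_,
    mean_raw = mean(x$raw_rd[x$valid]),
    mean_corrected = if ("corrected_rd" %in% names(x))
      mean(x$corrected_rd[x$valid]) else NA_real_)
}

#' @export
tidy.rdprep_rd_track <- function(x, ...) tibble::as_tibble(x)

#' Plot a read-depth track
#'
#' Corrected (where available) and raw read depth along each chromosome.
#'
#' @param object A `rdprep_rd_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdprep_rd_track <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$midpoint <- (df$start + df$end) / 2
  long <- tidyr::pivot_longer(
    df, dplyr::any_of(c("raw_rd", "corrected_rd")),
    names_to = "signal", values_to = "rd")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$midpoint, y = .data$rd,
                                     colour = .data$signal)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "read depth",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a GC profile
#'
#' Mean raw read depth per GC bin with the global mean as reference line;
#' deviations from the line are the bias removed by [gc_correct()].
#'
#' @param object A `rdprep_gc_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdprep_gc_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gc_pct, y = .data$mean_raw,
                                   size = .data$n_windows)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$grand_mean),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "window GC (%)", y = "mean raw read depth",
                  size = "windows") +
    ggplot2::theme_minimal()
}
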