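#' Illumina single-end adapter 1
#'
#' Default 3' adapter sequence used by the trimmer and the read simulator.
#' @export
ILLUMINA_SE_ADAPTER1 <- "ACACTCTTTCCCTACACGACGCTGTTCCATCT"

#' Adapter trimming specification
#'
#' @param adapter 3' adapter sequence to search for.
#' @param max_error_rate Maximum fraction of mismatches allowed in the
#'   read/adapter overlap, in \[0, 0.5).
#' @param min_overlap Minimum overlap (bases) between read suffix and adapter
#'   prefix for a match to count.
#' @param min_length Reads shorter than this after trimming are discarded.
#' @return A list of class `adapter_spec`.
#' @export
adapter_spec <- function(adapter = ILLUMINA_SE_ADAPTER1, max_error_rate = 0.1,
                         min_overlap = 3L, min_length = 0L) {
  if (min_overlap < 1L) {
    rlang::abort("min_overlap must be >= 1", class = "rdprep_config_error")
  }
  if (max_error_rate < 0 || max_error_rate >= 0.5) {
    rlang::abort("max_error_rate must be in [0, 0.5)", class = "rdprep_config_error")
  }
  structure(list(adapter = toupper(adapter),
                 max_error_rate = as.numeric(max_error_rate),
                 min_overlap = as.integer(min_overlap),
                 min_length = as.integer(min_length)),
            class = "adapter_spec")
}

#' Trim a 3' adapter from reads
#'
#' Mismatch-only (no indels) 3' adapter search: for each read, the leftmost
#' suffix matching a prefix of the adapter with overlap at least
#' `min_overlap` and mismatch fraction at most `max_error_rate` is removed,
#' cutting sequence and quality at the same point. Reads shorter than
#' `min_length` after trimming are discarded. Trimming never lengthens a
#' read and keeps sequence and quality lengths equal.
#'
#' @param reads Read tibble.
#' @param spec An [adapter_spec()].
#' @return The trimmed read tibble (class `rdprep_trim`) with a `stats`
#'   attribute: `total`, `trimmed`, `discarded`.
#' @export
trim_3prime <- function(reads, spec = adapter_spec()) {
  stopifnot(inherits(spec, "adapter_spec"))
  pos <- trim_positions_cpp(reads$seq, spec$adapter,
                            spec$max_error_rate, spec$min_overlap)
  hit <- pos > 0L
  out <- reads
  out$seq[hit] <- substr(out$seq[hit], 1L, pos[hit] - 1L)
  out$qual[hit] <- substr(out$qual[hit], 1L, pos[hit] - 1L)
  short <- nchar(out$seq) < spec$min_length
  stats <- tibble::tibble(total = nrow(reads), trimmed = sum(hit),
                          discarded = sum(short))
  out <- out[!short, , drop = FALSE]
  attr(out, "stats") <- stats
  class(out) <- unique(c("rdprep_trim", class(out)))
  out
}

#' @export
glance.rdprep_trim <- function(x, ...) attr(x, "stats")
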