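#' Read a SAM file into an alignment tibble
#'
#' Parses the text SAM dialect into the minimal record the read-depth
#' pipeline needs: query name, reference, 1-based leftmost position, MAPQ,
#' CIGAR, the reference-consumed span derived from the CIGAR (sum of
#' M/D/N/=/X lengths), the `AS:i` alignment score when present, and a mapped
#' flag (SAM flag bit 0x4). Header lines are preserved as an attribute so
#' [write_sam()] can round-trip them. Lines with fewer than 11 fields are
#' skipped with a warning and counted.
#'
#' @param path Path to a SAM file.
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `aln_span`, `score`, `mapped`; attributes `header` (character)
#'   and `skipped` (count of malformed lines).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("SAM file not found: '%s'", path),
                 class = "rdprep_io_error")
  }
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  skipped <- 0L
  if (length(body) > 0L) {
    nfields <- stringr::str_count(body, stringr::fixed("\t")) + 1L
    bad <- nfields < 11L
    if (any(bad)) {
      skipped <- sum(bad)
      rlang::warn(sprintf("skipped %d malformed SAM line(s) with < 11 fields", skipped))
      body <- body[!bad]
    }
  }
  if (length(body) == 0L) {
    out <- tibble::tibble(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          aln_span = integer(), score = integer(),
                          mapped = logical())
    attr(out, "header") <- header
    attr(out, "skipped") <- skipped
    return(out)
  }
  fields <- stringr::str_split_fixed(body, stringr::fixed("\t"), 12L)
  score <- rep(NA_integer_, nrow(fields))
  has_tags <- nzchar(fields[, 12L])
  if (any(has_tags)) {
    m <- stringr::str_match(fields[has_tags, 12L], "(?:^|\\t)AS:i:(-?\\d+)")[, 2L]
    score[has_tags] <- suppressWarnings(as.integer(m))
  }
  flag <- suppressWarnings(as.integer(fields[, 2L]))
  out <- tibble::tibble(
    qname = fields[, 1L],
    flag = flag,
    rname = fields[, 3L],
    pos = suppressWarnings(as.integer(fields[, 4L])),
    mapq = suppressWarnings(as.integer(fields[, 5L])),
    cigar = fields[, 6L],
    aln_span = cigar_ref_span_cpp(fields[, 6L]),
    score = score,
    mapped = !is.na(flag) & bitwAnd(flag, 4L) == 0L)
  attr(out, "header") <- header
  attr(out, "skipped") <- skipped
  out
}

#' Write an alignment tibble back to SAM text
#'
#' Emits the 11 mandatory columns (placeholders for unavailable ones) plus an
#' `AS:i` tag where a score is present, preceded by the stored header.
#'
#' @param alignments Alignment tibble from [read_sam()].
#' @param path Destination path.
#' @param header Header lines; defaults to the tibble's `header` attribute.
#' @return The path, invisibly.
#' @export
write_sam <- function(alignments, path, header = NULL) {
  header <- header %||% attr(alignments, "header") %||% character()
  body <- character()
  if (nrow(alignments) > 0L) {
    tags <- ifelse(is.na(alignments$score), "",
                   paste0("\tAS:i:", alignments$score))
    body <- paste0(alignments$qname, "\t", alignments$flag, "\t",
                   alignments$rname, "\t", alignments$pos, "\t",
                   alignments$mapq, "\t", alignments$cigar,
                   "\t*\t0\t0\t*\t*", tags)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Drop unmapped and low-MAPQ alignments
#'
#' Unmapped records are removed; mapped records are kept iff
#' `mapq >= min_mapq` (the threshold is inclusive). Input order is preserved.
#'
#' @param alignments Alignment tibble.
#' @param min_mapq Minimum mapping quality to keep.
#' @return Filtered tibble with a `stats` attribute (`total`, `unmapped`,
#'   `below_mapq`, `kept`).
#' @export
filter_mapq <- function(alignments, min_mapq = 0L) {
  unmapped <- !alignments$mapped
  low <- alignments$mapped & alignments$mapq < min_mapq
  out <- alignments[!unmapped & !low, , drop = FALSE]
  attr(out, "stats") <- tibble::tibble(
    total = nrow(alignments), unmapped = sum(unmapped),
    below_mapq = sum(low), kept = nrow(out))
  attr(out, "header") <- attr(alignments, "header")
  out
}

#' Resolve multi-mapped reads
#'
#' Groups alignments by query name and keeps at most one record per read.
#' The best set of a read maximizes the alignment score where present,
#' falling back to MAPQ. Under `"unique"`, a read is emitted only when its
#' best set has exactly one member; under `"random"`, one member of the best
#' set is chosen uniformly with a seeded generator, so the result is
#' deterministic given input order and seed.
#'
#' @param alignments Alignment tibble (mapped records).
#' @param strategy `"unique"` (unique-best) or `"random"` (random-best).
#' @param seed Integer seed for the random-best draw.
#' @return Tibble with at most one record per `qname`, each belonging to its
#'   read's best set; a `stats` attribute records `reads`, `emitted`,
#'   `dropped_ambiguous` (unique-best only).
#' @export
resolve_multimappers <- function(alignments, strategy = c("unique", "random"),
                                 seed = 1L) {
  strategy <- rlang::arg_match(strategy)
  aln <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(aln) == 0L) {
    attr(aln, "stats") <- tibble::tibble(reads = 0L, emitted = 0L,
                                         dropped_ambiguous = 0L)
    return(aln)
  }
  key <- if ("score" %in% names(aln)) {
    dplyr::coalesce(as.numeric(aln$score), as.numeric(aln$mapq))
  } else {
    as.numeric(aln$mapq)
  }
  aln$.key <- key
  if (strategy == "unique") {
    out <- aln |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::group_by(.data$qname) |>
      dplyr::filter(sum(.data$.key == max(.data$.key)) == 1L,
                    .data$.key == max(.data$.key)) |>
      dplyr::ungroup()
    n_reads <- dplyr::n_distinct(aln$qname)
    stats <- tibble::tibble(reads = n_reads, emitted = nrow(out),
                            dropped_ambiguous = n_reads - nrow(out))
    out <- dplyr::arrange(out, .data$.row)
    out$.key <- NULL
    out$.row <- NULL
  } else {
    # uniform tie-break: a seeded uniform draw per record in input order;
    # the tied record with the largest draw wins
    u <- withr::with_seed(as.integer(seed), runif(nrow(aln)))
    aln$.u <- u
    out <- aln |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::group_by(.data$qname) |>
      dplyr::filter(.data$.key == max(.data$.key)) |>
      dplyr::filter(.data$.u == max(.data$.u)) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$.row)
    stats <- tibble::tibble(reads = dplyr::n_distinct(aln$qname),
                            emitted = nrow(out), dropped_ambiguous = 0L)
    out$.key <- NULL
    out$.u <- NULL
    out$.row <- NULL
  }
  # the surviving record represents its read: clear secondary/supplementary bits
  out$flag <- bitwAnd(out$flag, bitwNot(bitwOr(256L, 2048L)))
  attr(out, "stats") <- stats
  attr(out, "header") <- attr(alignments, "header")
  out
}
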