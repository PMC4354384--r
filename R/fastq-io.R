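#' Known Illumina quality encodings
#'
#' Quality strings in FASTQ files store Phred-like scores as ASCII characters
#' with a platform-dependent offset. Three Illumina conventions are supported:
#' Illumina 1.0 (Solexa; scores -5..62, ASCII 59..126, offset 64), Illumina
#' 1.3-1.7 (scores 0..62, ASCII 64..126, offset 64) and Illumina 1.8+
#' (scores 0..93, ASCII 33..126, offset 33).
#'
#' @format A tibble with one row per encoding and columns `name`,
#'   `ascii_offset`, `score_min`, `score_max`, `ascii_min`, `ascii_max`.
#' @export
quality_encodings <- function() {
  tibble::tibble(
    name         = c("illumina-1.0", "illumina-1.3", "illumina-1.8"),
    ascii_offset = c(64L, 64L, 33L),
    score_min    = c(-5L, 0L, 0L),
    score_max    = c(62L, 62L, 93L),
    ascii_min    = c(59L, 64L, 33L),
    ascii_max    = c(126L, 126L, 126L)
  )
}

#' Construct a quality-encoding descriptor
#'
#' @param name One of `"illumina-1.0"`, `"illumina-1.3"`, `"illumina-1.8"`.
#' @return A list of class `quality_encoding` with fields `name`,
#'   `ascii_offset`, `score_min`, `score_max`, `ascii_min`, `ascii_max`.
#' @export
quality_encoding <- function(name = c("illumina-1.8", "illumina-1.3", "illumina-1.0")) {
  name <- rlang::arg_match(name)
  row <- dplyr::filter(quality_encodings(), .data$name == !!name)
  enc <- as.list(row)
  class(enc) <- "quality_encoding"
  enc
}

#' @export
print.quality_encoding <- function(x, ...) {
  cat(sprintf("<quality_encoding> %s (offset %d, scores %d..%d, ASCII %d..%d)\n",
              x$name, x$ascii_offset, x$score_min, x$score_max,
              x$ascii_min, x$ascii_max))
  invisible(x)
}

new_read_tbl <- function(id, seq, qual) {
  tibble::tibble(id = id, seq = seq, qual = qual)
}

#' Read a 4-line FASTQ file into a tibble of reads
#'
#' Parses the strict 4-line FASTQ dialect (`@id`, sequence, `+`, quality).
#' Sequences are upper-cased and any letter outside `{A,C,G,T,N}` is converted
#' to `N` with a warning, so downstream integer encodings always see the
#' 5-symbol alphabet. Gzip-compressed files are accepted by suffix. The input
#' file is never modified.
#'
#' @param path Path to a FASTQ file (optionally `.gz`).
#' @param mate Optional path to the mate FASTQ of a paired library; when given
#'   a list of two read tibbles is returned and the mate counts must agree.
#' @return A tibble with columns `id`, `seq`, `qual` (one row per read), or a
#'   list with elements `reads` and `mate` for paired input.
#' @export
read_fastq <- function(path, mate = NULL) {
  if (!is.null(mate)) {
    r1 <- read_fastq(path)
    r2 <- read_fastq(mate)
    if (nrow(r1) != nrow(r2)) {
      rlang::abort(
        sprintf("mate files disagree: %d reads in '%s' vs %d in '%s'",
                nrow(r1), path, nrow(r2), mate),
        class = "rdprep_parse_error")
    }
    return(list(reads = r1, mate = r2))
  }
  if (!file.exists(path)) {
    rlang::abort(sprintf("FASTQ file not found: '%s'", path),
                 class = "rdprep_io_error")
  }
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) return(new_read_tbl(character(), character(), character()))
  if (n %% 4L != 0L) {
    rlang::abort(
      sprintf("truncated FASTQ record at line %d of '%s' (%d lines is not a multiple of 4)",
              (n %/% 4L) * 4L + 1L, path, n),
      class = "rdprep_parse_error")
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]

  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0L) {
    rlang::abort(
      sprintf("malformed FASTQ record at line %d of '%s': header does not start with '@'",
              (bad_hdr[1L] - 1L) * 4L + 1L, path),
      class = "rdprep_parse_error")
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0L) {
    rlang::abort(
      sprintf("malformed FASTQ record at line %d of '%s': separator line does not start with '+'",
              (bad_plus[1L] - 1L) * 4L + 3L, path),
      class = "rdprep_parse_error")
  }
  bad_len <- which(nchar(seq) != nchar(qual))
  if (length(bad_len) > 0L) {
    i <- bad_len[1L]
    rlang::abort(
      sprintf("record '%s' (line %d of '%s'): sequence length %d != quality length %d",
              sub("^@", "", hdr[i]), (i - 1L) * 4L + 1L, path,
              nchar(seq[i]), nchar(qual[i])),
      class = "rdprep_parse_error")
  }

  seq <- toupper(seq)
  has_other <- grepl("[^ACGTN]", seq)
  if (any(has_other)) {
    rlang::warn(sprintf(
      "%d read(s) contain letters outside {A,C,G,T,N}; converted to N",
      sum(has_other)))
    seq[has_other] <- gsub("[^ACGTN]", "N", seq[has_other])
  }
  new_read_tbl(sub("^@", "", hdr), seq, qual)
}

#' Write reads to a 4-line FASTQ file
#'
#' Byte-faithful inverse of [read_fastq()]: reading the written file back
#' reproduces `id`, `seq`, `qual` exactly.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Destination path; `.gz` suffix enables gzip compression.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) > 0L && any(nchar(reads$seq) != nchar(reads$qual))) {
    rlang::abort("seq and qual lengths differ; refusing to write invalid FASTQ",
                 class = "rdprep_contract_error")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    out <- character(4L * nrow(reads))
    out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
    out[seq(2L, length(out), by = 4L)] <- reads$seq
    out[seq(3L, length(out), by = 4L)] <- "+"
    out[seq(4L, length(out), by = 4L)] <- reads$qual
    writeLines(out, con)
  }
  invisible(path)
}

qual_ascii_range <- function(quals) {
  quals <- quals[nchar(quals) > 0L]
  if (length(quals) == 0L) return(c(NA_integer_, NA_integer_))
  codes <- utf8ToInt(paste(quals, collapse = ""))
  c(min(codes), max(codes))
}

#' Detect the Illumina quality encoding of a read library
#'
#' Scans up to `max_reads` quality strings and classifies the file from the
#' lowest ASCII code observed: below 59 only Illumina 1.8+ is possible; codes
#' in 59..63 only occur under Illumina 1.0; otherwise (all codes >= 64, where
#' the three ranges overlap) Illumina 1.3 is assumed. Deterministic for a
#' fixed sample and insensitive to read order or duplication.
#'
#' @param reads Read tibble from [read_fastq()].
#' @param max_reads Number of leading reads to sample (default 10000).
#' @return A `quality_encoding` object.
#' @export
detect_encoding <- function(reads, max_reads = 10000L) {
  quals <- utils::head(reads$qual, max_reads)
  rng <- qual_ascii_range(quals)
  if (is.na(rng[1L])) {
    rlang::abort("cannot detect quality encoding: no non-empty quality strings in sample",
                 class = "rdprep_quality_error")
  }
  if (rng[1L] < 33L || rng[2L] > 126L) {
    rlang::abort(
      sprintf("invalid quality characters: ASCII codes %d..%d fall outside 33..126",
              rng[1L], rng[2L]),
      class = "rdprep_quality_error")
  }
  name <- if (rng[1L] < 59L) "illumina-1.8"
          else if (rng[1L] <= 63L) "illumina-1.0"
          else "illumina-1.3"
  quality_encoding(name)
}

#' Decode quality strings to integer Phred scores
#'
#' Adds a `scores` list-column with `utf8ToInt(qual) - ascii_offset` per read
#' and records the encoding as an attribute consumed by the quality operators.
#'
#' @param reads Read tibble.
#' @param enc A `quality_encoding`, or `NULL` to auto-detect.
#' @return The tibble with a `scores` list-column and an `encoding` attribute.
#' @export
decode_qualities <- function(reads, enc = NULL) {
  if (is.null(enc)) enc <- detect_encoding(reads)
  stopifnot(inherits(enc, "quality_encoding"))
  rng <- qual_ascii_range(reads$qual)
  if (!is.na(rng[1L]) && (rng[1L] < enc$ascii_min || rng[2L] > enc$ascii_max)) {
    bad <- which(vapply(reads$qual, function(q) {
      if (nchar(q) == 0L) return(FALSE)
      codes <- utf8ToInt(q)
      any(codes < enc$ascii_min | codes > enc$ascii_max)
    }, logical(1L)))[1L]
    codes <- utf8ToInt(reads$qual[bad])
    pos <- which(codes < enc$ascii_min | codes > enc$ascii_max)[1L]
    rlang::abort(
      sprintf("quality character out of range for %s in read '%s' at position %d (ASCII %d)",
              enc$name, reads$id[bad], pos, codes[pos]),
      class = "rdprep_quality_error")
  }
  reads$scores <- lapply(reads$qual, function(q) {
    if (nchar(q) == 0L) integer() else utf8ToInt(q) - enc$ascii_offset
  })
  attr(reads, "encoding") <- enc
  reads
}

reads_encoding <- function(reads, default = "illumina-1.8") {
  enc <- attr(reads, "encoding")
  if (is.null(enc)) enc <- quality_encoding(default)
  enc
}
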