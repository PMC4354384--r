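# shared fixtures: everything is generated in code at test time

make_reads <- function(seqs, quals = NULL, ids = NULL) {
  n <- length(seqs)
  tibble::tibble(
    id = ids %||% sprintf("r%03d", seq_len(n)),
    seq = seqs,
    qual = quals %||% strrep("I", nchar(seqs)))
}

# random sequences over the 4- or 5-letter alphabet
rand_seqs <- function(n, len, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  vapply(seq_len(n),
         function(i) paste(sample(alpha, len, replace = TRUE), collapse = ""),
         character(1L))
}

# independent Hamming oracle (no chunking, plain character comparison)
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# quality string from integer Phred scores, offset 33
phred33 <- function(scores) intToUtf8(scores + 33L)

write_tmp_fastq <- function(reads) {
  path <- withr::local_tempfile(fileext = ".fastq",
                                .local_envir = parent.frame())
  write_fastq(reads, path)
  path
}

small_s1 <- function(n = 2000L, seed = 42L, ref_len = 200000L, ...) {
  ref <- simulate_reference(c(chr1 = ref_len), gc = 0.45, seed = seed)
  cfg <- sim_config(n_reads = n, seed = seed, ...)
  list(ref = ref, cfg = cfg, sim = simulate_reads(ref, cfg))
}
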