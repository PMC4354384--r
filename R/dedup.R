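#' Capacity limits of the 64-bit sequence encodings
#'
#' `prefix_capacity()` is the largest prefix length `k` for which the base-5
#' positional key (A=0, C=1, G=2, T=3, N=4) of every k-prefix fits an unsigned
#' 64-bit integer, i.e. the largest `k` with `5^k <= 2^64`; injectivity of the
#' encoding holds exactly up to this length. `chunk_capacity()` is the largest
#' number of decimal-concatenated digits guaranteed to fit, i.e. the largest
#' `d` with `10^d <= 2^64`. Both are computed at run time by exact unsigned
#' 64-bit arithmetic.
#'
#' @return An integer scalar.
#' @export
prefix_capacity <- function() prefix_capacity_u64()

#' @rdname prefix_capacity
#' @export
chunk_capacity <- function() chunk_capacity_u64()

#' Duplicate-removal policy
#'
#' @param prefix_len Length `k` of the read prefix used for clustering
#'   (1..[prefix_capacity()], i.e. at most 27).
#' @param max_mismatches Maximum number of suffix mismatches `m` for two reads
#'   to be considered duplicates.
#' @param chunk_len Length of the suffix chunks used for the numeric
#'   comparison (1..[chunk_capacity()], i.e. at most 19; default maximal).
#' @return A list of class `dedup_policy`.
#' @export
dedup_policy <- function(prefix_len = 25L, max_mismatches = 1L, chunk_len = chunk_capacity()) {
  prefix_len <- as.integer(prefix_len)
  max_mismatches <- as.integer(max_mismatches)
  chunk_len <- as.integer(chunk_len)
  if (prefix_len < 1L || prefix_len > prefix_capacity()) {
    rlang::abort(sprintf("prefix_len must be in [1, %d]", prefix_capacity()),
                 class = "rdprep_config_error")
  }
  if (chunk_len < 1L || chunk_len > chunk_capacity()) {
    rlang::abort(sprintf("chunk_len must be in [1, %d]", chunk_capacity()),
                 class = "rdprep_config_error")
  }
  if (max_mismatches < 0L) {
    rlang::abort("max_mismatches must be >= 0", class = "rdprep_config_error")
  }
  structure(list(prefix_len = prefix_len, max_mismatches = max_mismatches,
                 chunk_len = chunk_len),
            class = "dedup_policy")
}

#' Integer-encode read prefixes and suffix chunks
#'
#' `encode_prefix()` maps the first `k` bases of each sequence to its base-5
#' positional key (A=0, C=1, G=2, T=3, N=4): equal keys correspond exactly to
#' identical k-prefixes, and the keys preserve lexicographic prefix order
#' under A<C<G<T<N. `encode_chunk()` concatenates the same digits as a
#' decimal number, the representation under which the order of magnitude of a
#' difference localizes the leftmost mismatching base. Both return the exact
#' unsigned 64-bit values as decimal strings (they can exceed the integers a
#' double represents exactly).
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @param k Prefix length (at most [prefix_capacity()]).
#' @return Character vector of decimal-encoded keys.
#' @export
#' @examples
#' encode_prefix("ACGTN", 5) # "194" = ((0*5+1)*5+2)*5+3)*5+4
#' encode_chunk("NT")        # "43": digits 4 and 3 concatenated
encode_prefix <- function(seq, k) {
  encode_prefix_cpp(seq, as.integer(k))
}

#' @rdname encode_prefix
#' @export
encode_chunk <- function(seq) {
  encode_chunk_cpp(seq)
}

#' Locate the leftmost mismatch between two chunk codes
#'
#' Given two equal-length decimal chunk codes, returns the 0-based position of
#' the leftmost differing base, derived from the order of magnitude
#' `q = floor(log10 |x - y|)` of their numerical difference. Because chunk
#' digits are restricted to 0..4, the lower digits contribute less than half
#' of the leading digit's `10^p`, so `q` is either `p` or (under partial
#' cancellation, e.g. codes 03 vs 10) `p - 1`; comparing the single digit at
#' power `q + 1` resolves the ambiguity exactly. Returns `NA` when the codes
#' are equal.
#'
#' @param x,y Chunk codes as decimal strings (from [encode_chunk()]).
#' @param chunk_len Number of bases encoded in each code.
#' @return Integer position (0-based) or `NA`.
#' @export
leftmost_mismatch <- function(x, y, chunk_len) {
  pos <- leftmost_mismatch_cpp(as.character(x), as.character(y), as.integer(chunk_len))
  if (pos < 0L) NA_integer_ else pos
}

#' Count mismatches between two equal-length sequences, chunkwise
#'
#' Splits both sequences into `chunk_len`-base chunks, encodes each chunk as a
#' decimal number and repeatedly localizes and strips the leftmost mismatch
#' from the numeric difference, summing mismatches across chunks. The count
#' equals the Hamming distance whenever it is at most `limit`; once the
#' running count exceeds `limit` the comparison aborts early and some value
#' greater than `limit` is returned.
#'
#' @param a,b Sequences of equal length over `{A,C,G,T,N}`.
#' @param limit Early-stop bound `m`.
#' @param chunk_len Chunk length (default maximal, 19).
#' @return Integer mismatch count (exact when `<= limit`).
#' @export
count_mismatches <- function(a, b, limit, chunk_len = chunk_capacity()) {
  count_mismatches_cpp(a, b, as.integer(limit), as.integer(chunk_len))
}

#' Cluster reads by identical integer-encoded k-prefix
#'
#' Computes the base-5 prefix key of every read of length at least `k` and
#' sorts (key ascending, original index ascending); maximal runs of equal
#' keys form the clusters, exactly the groups of reads sharing an identical
#' k-prefix. Reads shorter than `k` are set aside (`NA` cluster) and always
#' kept by [dedup_library()].
#'
#' @param reads Read tibble (or character vector of sequences).
#' @param k Prefix length (at most [prefix_capacity()]).
#' @return A tibble with columns `read_index`, `cluster` (1-based id in
#'   ascending key order, `NA` for reads shorter than `k`).
#' @export
cluster_by_prefix <- function(reads, k) {
  seqs <- if (is.character(reads)) reads else reads$seq
  tibble::tibble(read_index = seq_along(seqs),
                 cluster = cluster_by_prefix_cpp(seqs, as.integer(k)))
}

#' Per-position majority consensus of duplicate reads
#'
#' Condenses a seed read and its duplicates into one representative: at each
#' position the majority base wins, ties resolve to the seed's (first
#' member's) base. The id and quality string are taken from the seed.
#'
#' @param reads Read tibble whose rows are the seed (first) and its
#'   duplicates; all sequences must have equal length.
#' @return A one-row read tibble.
#' @export
build_consensus <- function(reads) {
  stopifnot(nrow(reads) >= 1L)
  out <- reads[1L, c("id", "seq", "qual")]
  out$seq <- consensus_cpp(reads$seq)
  out
}

#' Greedily collapse one prefix cluster
#'
#' The first remaining member (lowest original index) is the seed; members of
#' equal length whose suffix is within `max_mismatches` of the seed's suffix
#' are its duplicates and are condensed with the seed into one consensus
#' representative. The process repeats on the remainder until the cluster is
#' empty, so any two surviving representatives of equal length are more than
#' `max_mismatches` apart in their suffixes.
#'
#' @param reads Read tibble for the whole library.
#' @param members Integer row indices of the cluster members, ascending.
#' @param policy A [dedup_policy()].
#' @return List with `representatives` (read tibble, one row per surviving
#'   group, in seed order), `seeds` (original row index of each
#'   representative's seed) and `removed` (count of collapsed members).
#' @export
collapse_cluster <- function(reads, members, policy) {
  if (length(members) == 1L) {
    return(list(representatives = reads[members, c("id", "seq", "qual")],
                seeds = members, removed = 0L))
  }
  suffixes <- substring(reads$seq[members], policy$prefix_len + 1L)
  groups <- collapse_cluster_cpp(suffixes, policy$max_mismatches,
                                 policy$chunk_len)
  seeds <- members[vapply(groups, `[`, integer(1L), 1L)]
  seqs <- vapply(groups, function(g) {
    if (length(g) == 1L) reads$seq[members[g]]
    else consensus_cpp(reads$seq[members[g]])
  }, character(1L))
  representatives <- tibble::tibble(id = reads$id[seeds], seq = seqs,
                                    qual = reads$qual[seeds])
  list(representatives = representatives,
       seeds = seeds,
       removed = length(members) - length(groups))
}

#' Remove near-duplicate reads from a single-end library
#'
#' Alignment-free duplicate removal: reads are clustered by identical
#' integer-encoded k-prefix ([cluster_by_prefix()]), and each cluster is
#' greedily collapsed ([collapse_cluster()]) so that duplicates -- reads of
#' equal length whose suffixes differ by at most `max_mismatches` from the
#' seed's -- are condensed into per-position majority consensus
#' representatives. Reads shorter than `prefix_len` bypass deduplication and
#' are always kept. Indels are not modelled: reads of unequal length are
#' never duplicates of one another. Output order is by ascending original
#' index of each representative's seed, with identical input and policy
#' producing identical output.
#'
#' @param reads Read tibble, or a path to a FASTQ file.
#' @param policy A [dedup_policy()].
#' @param paired Set to `TRUE` by callers holding paired data to get the
#'   explicit unsupported-layout error; duplicate removal is single-end only.
#' @return An object of class `rdprep_dedup`: list with `reads` (surviving
#'   tibble) and `stats` (one-row tibble: `total`, `clusters`, `short_reads`,
#'   `removed`, `pct_removed`). [tidy()] returns the surviving reads,
#'   [glance()] the stats.
#' @export
dedup_library <- function(reads, policy = dedup_policy(), paired = FALSE) {
  if (isTRUE(paired)) {
    rlang::abort("duplicate removal supports single-end libraries only",
                 class = "rdprep_unsupported_layout")
  }
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(inherits(policy, "dedup_policy"))
  n <- nrow(reads)
  cl <- cluster_by_prefix_cpp(reads$seq, policy$prefix_len)
  short <- which(is.na(cl))
  groups <- split(which(!is.na(cl)), cl[!is.na(cl)])
  multi <- groups[lengths(groups) > 1L]

  seed_idx <- c(short, unlist(groups[lengths(groups) == 1L], use.names = FALSE))
  ids <- reads$id[seed_idx]
  seqs <- reads$seq[seed_idx]
  quals <- reads$qual[seed_idx]

  removed <- 0L
  if (length(multi) > 0L) {
    all_seq <- reads$seq
    k1 <- policy$prefix_len + 1L
    m <- policy$max_mismatches
    clen <- policy$chunk_len
    rep_seeds <- vector("list", length(multi))
    rep_seqs <- vector("list", length(multi))
    for (ci in seq_along(multi)) {
      members <- multi[[ci]]
      grp <- collapse_cluster_cpp(substring(all_seq[members], k1), m, clen)
      removed <- removed + length(members) - length(grp)
      rep_seeds[[ci]] <- members[vapply(grp, `[`, integer(1L), 1L)]
      rep_seqs[[ci]] <- vapply(grp, function(g) {
        if (length(g) == 1L) all_seq[members[g]]
        else consensus_cpp(all_seq[members[g]])
      }, character(1L))
    }
    rep_seeds <- unlist(rep_seeds, use.names = FALSE)
    seed_idx <- c(seed_idx, rep_seeds)
    ids <- c(ids, reads$id[rep_seeds])
    seqs <- c(seqs, unlist(rep_seqs, use.names = FALSE))
    quals <- c(quals, reads$qual[rep_seeds])
  }
  ord <- order(seed_idx)
  out <- tibble::tibble(id = ids[ord], seq = seqs[ord], qual = quals[ord])
  stats <- tibble::tibble(
    total = n,
    clusters = length(groups),
    short_reads = length(short),
    removed = removed,
    pct_removed = 100 * removed / max(1L, n))
  structure(list(reads = out, stats = stats, policy = policy),
            class = "rdprep_dedup")
}

#' @export
print.rdprep_dedup <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("<rdprep_dedup> %d reads, %d prefix clusters (k=%d), ",
                     "%d removed (%.2f%%) at m=%d\n"),
              s$total, s$clusters, x$policy$prefix_len,
              s$removed, s$pct_removed, x$policy$max_mismatches))
  invisible(x)
}

#' @export
tidy.rdprep_dedup <- function(x, ...) x$reads

#' @export
glance.rdprep_dedup <- function(x, ...) x$stats
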