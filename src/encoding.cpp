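#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Base-5 digit map over the 5-symbol read alphabet: A->0 C->1 G->2 T->3 N->4.
static inline int base5_digit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    case 'N': return 4;
    default:  return -1;
  }
}

static inline uint64_t pow10_u64(int p) {
  uint64_t v = 1;
  for (int i = 0; i < p; ++i) v *= 10ULL;
  return v;
}

static uint64_t parse_u64(const std::string& s) {
  uint64_t v = 0;
  for (char c : s) {
    if (c < '0' || c > '9')
      stop("invalid decimal code '%s'", s.c_str());
    v = v * 10ULL + (uint64_t)(c - '0');
  }
  return v;
}

// Largest k such that every base-5 positional key over k symbols
// (values 0 .. 5^k - 1) fits in an unsigned 64-bit integer.
// [[Rcpp::export]]
int prefix_capacity_u64() {
  uint64_t v = 1;
  int k = 0;
  while (v <= UINT64_MAX / 5ULL) {
    v *= 5ULL;
    ++k;
  }
  return k;
}

// Largest digit count d such that every d-digit decimal concatenation
// (values 0 .. 10^d - 1) fits in an unsigned 64-bit integer.
// [[Rcpp::export]]
int chunk_capacity_u64() {
  uint64_t v = 1;
  int d = 0;
  while (v <= UINT64_MAX / 10ULL) {
    v *= 10ULL;
    ++d;
  }
  return d;
}

static uint64_t prefix_key(const char* s, int k, R_xlen_t read_i) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int d = base5_digit(s[i]);
    if (d < 0)
      stop("invalid base '%c' in read %d (expected A/C/G/T/N)", s[i], (int)(read_i + 1));
    v = v * 5ULL + (uint64_t)d;
  }
  return v;
}

static uint64_t chunk_code(const char* s, int len, R_xlen_t read_i) {
  uint64_t v = 0;
  for (int i = 0; i < len; ++i) {
    int d = base5_digit(s[i]);
    if (d < 0)
      stop("invalid base '%c' in sequence %d (expected A/C/G/T/N)", s[i], (int)(read_i + 1));
    v = v * 10ULL + (uint64_t)d;
  }
  return v;
}

// Base-5 positional prefix keys, returned as exact decimal strings.
// [[Rcpp::export]]
CharacterVector encode_prefix_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > prefix_capacity_u64())
    stop("prefix length k must be in [1, %d]", prefix_capacity_u64());
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if ((int)std::strlen(s) < k)
      stop("sequence %d is shorter than the prefix length k = %d", (int)(i + 1), k);
    out[i] = std::to_string(prefix_key(s, k, i));
  }
  return out;
}

// Decimal digit-concatenation codes for suffix chunks, as exact decimal strings.
// [[Rcpp::export]]
CharacterVector encode_chunk_cpp(CharacterVector subs) {
  int cap = chunk_capacity_u64();
  R_xlen_t n = subs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(subs, i));
    int len = (int)std::strlen(s);
    if (len < 1 || len > cap)
      stop("chunk length must be in [1, %d], got %d", cap, len);
    out[i] = std::to_string(chunk_code(s, len, i));
  }
  return out;
}

// Power (position from the right) of the leftmost differing digit of two
// distinct codes. The order of magnitude q of |x - y| narrows it to {q, q+1}:
// the leading differing digit contributes at least 10^p while all lower
// digits contribute under 0.445 * 10^p (digits are 0..4), so |x - y| lies in
// (0.555 * 10^p, 4.445 * 10^p) and cancellation can pull the magnitude one
// below p. Comparing the single digit at power q+1 settles it.
static inline int leading_mismatch_pow(uint64_t x, uint64_t y) {
  uint64_t diff = x > y ? x - y : y - x;
  int q = 0;
  while (diff >= 10ULL) {
    diff /= 10ULL;
    ++q;
  }
  uint64_t p10 = pow10_u64(q + 1);
  return ((x / p10) % 10ULL) != ((y / p10) % 10ULL) ? q + 1 : q;
}

// Position (0-based within the chunk) of the leftmost differing digit between
// two equal-length chunk codes, located from the order of magnitude of their
// numerical difference; -1 when the codes are equal.
// [[Rcpp::export]]
int leftmost_mismatch_cpp(std::string xcode, std::string ycode, int chunk_len) {
  uint64_t x = parse_u64(xcode);
  uint64_t y = parse_u64(ycode);
  if (x == y) return -1;
  return chunk_len - 1 - leading_mismatch_pow(x, y);
}

// Mismatches between two equal-length chunk codes via the magnitude trick:
// locate the leftmost differing digit, count it, truncate both codes below
// that digit, repeat. Early exit once the running count exceeds `limit`.
static int chunk_mismatches(uint64_t x, uint64_t y, int limit, int counted) {
  int count = 0;
  while (x != y) {
    int p = leading_mismatch_pow(x, y);
    ++count;
    if (counted + count > limit) return count;
    uint64_t mod = pow10_u64(p);
    x %= mod;
    y %= mod;
  }
  return count;
}

static int count_mismatches_impl(const char* a, const char* b, int len,
                                 int limit, int chunk_len, R_xlen_t idx) {
  int count = 0;
  for (int off = 0; off < len; off += chunk_len) {
    int clen = std::min(chunk_len, len - off);
    uint64_t x = chunk_code(a + off, clen, idx);
    uint64_t y = chunk_code(b + off, clen, idx);
    count += chunk_mismatches(x, y, limit, count);
    if (count > limit) return count;
  }
  return count;
}

// Chunked mismatch count between two equal-length strings; returns the exact
// Hamming distance when it is <= limit, otherwise some value > limit.
// [[Rcpp::export]]
int count_mismatches_cpp(std::string a, std::string b, int limit, int chunk_len) {
  if (a.size() != b.size())
    stop("sequences must have equal length (no indels are modelled)");
  if (chunk_len < 1 || chunk_len > chunk_capacity_u64())
    stop("chunk_len must be in [1, %d]", chunk_capacity_u64());
  if ((int)a.size() == 0) return 0;
  return count_mismatches_impl(a.c_str(), b.c_str(), (int)a.size(), limit, chunk_len, 0);
}

// Vectorised form: mismatch count of one seed suffix against many others.
// Entries whose length differs from the seed's get NA (never duplicates).
// [[Rcpp::export]]
IntegerVector count_mismatches_many_cpp(std::string seed, CharacterVector others,
                                        int limit, int chunk_len) {
  if (chunk_len < 1 || chunk_len > chunk_capacity_u64())
    stop("chunk_len must be in [1, %d]", chunk_capacity_u64());
  int len = (int)seed.size();
  R_xlen_t n = others.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* b = CHAR(STRING_ELT(others, i));
    if ((int)std::strlen(b) != len) {
      out[i] = NA_INTEGER;
    } else if (len == 0) {
      out[i] = 0;
    } else {
      out[i] = count_mismatches_impl(seed.c_str(), b, len, limit, chunk_len, i);
    }
  }
  return out;
}

// Cluster reads by their base-5 encoded k-prefix: stable sort of (key, index),
// then maximal runs of equal keys. Returns a 1-based cluster id per read,
// numbered in ascending key order; reads shorter than k get NA.
// [[Rcpp::export]]
IntegerVector cluster_by_prefix_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > prefix_capacity_u64())
    stop("prefix length k must be in [1, %d]", prefix_capacity_u64());
  R_xlen_t n = seqs.size();
  std::vector<uint64_t> keys(n);
  std::vector<R_xlen_t> idx;
  idx.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if ((int)std::strlen(s) < k) continue;
    keys[i] = prefix_key(s, k, i);
    idx.push_back(i);
  }
  std::stable_sort(idx.begin(), idx.end(),
                   [&keys](R_xlen_t a, R_xlen_t b) { return keys[a] < keys[b]; });
  IntegerVector out(n, NA_INTEGER);
  int cluster = 0;
  for (size_t j = 0; j < idx.size(); ++j) {
    if (j == 0 || keys[idx[j]] != keys[idx[j - 1]]) ++cluster;
    out[idx[j]] = cluster;
  }
  return out;
}

// Greedy seed-first collapse of one prefix cluster, on suffixes. Returns a
// list of integer vectors (1-based local indices): each vector is one
// duplicate group, seed first. Suffixes of a length different from the
// seed's are never duplicates of it.
// [[Rcpp::export]]
List collapse_cluster_cpp(CharacterVector suffixes, int m, int chunk_len) {
  int n = suffixes.size();
  std::vector<const char*> s(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(suffixes, i));
    len[i] = (int)std::strlen(s[i]);
  }
  std::vector<bool> done(n, false);
  List groups;
  for (int seed = 0; seed < n; ++seed) {
    if (done[seed]) continue;
    done[seed] = true;
    std::vector<int> group;
    group.push_back(seed + 1);
    for (int j = seed + 1; j < n; ++j) {
      if (done[j] || len[j] != len[seed]) continue;
      int d = len[seed] == 0 ? 0
            : count_mismatches_impl(s[seed], s[j], len[seed], m, chunk_len, j);
      if (d <= m) {
        done[j] = true;
        group.push_back(j + 1);
      }
    }
    groups.push_back(IntegerVector(group.begin(), group.end()));
  }
  return groups;
}

// Per-position majority consensus of equal-length sequences; ties resolve to
// the first (seed) sequence's base.
// [[Rcpp::export]]
String consensus_cpp(CharacterVector seqs) {
  int n = seqs.size();
  if (n < 1) stop("consensus of an empty set");
  const char* first = CHAR(STRING_ELT(seqs, 0));
  int len = (int)std::strlen(first);
  if (n == 1) return String(first);
  std::vector<const char*> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(seqs, i));
    if ((int)std::strlen(s[i]) != len)
      stop("consensus requires equal-length sequences");
  }
  std::string out(first, len);
  static const char alphabet[5] = {'A', 'C', 'G', 'T', 'N'};
  for (int j = 0; j < len; ++j) {
    int counts[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      int d = base5_digit(s[i][j]);
      if (d < 0) stop("invalid base '%c' in consensus input", s[i][j]);
      ++counts[d];
    }
    int best = counts[base5_digit(first[j])];
    for (int d = 0; d < 5; ++d) {
      if (counts[d] > best) {
        best = counts[d];
        out[j] = alphabet[d];
      }
    }
  }
  return String(out);
}

// Leftmost 3' adapter match: smallest 1-based start position where the read
// suffix matches a prefix of the adapter with overlap >= min_overlap and
// mismatch count <= floor(max_error_rate * overlap). 0 = no match.
// [[Rcpp::export]]
IntegerVector trim_positions_cpp(CharacterVector seqs, std::string adapter,
                                 double max_error_rate, int min_overlap) {
  int alen = (int)adapter.size();
  if (alen < 1) stop("adapter must be non-empty");
  if (min_overlap < 1) stop("min_overlap must be >= 1");
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = (int)std::strlen(s);
    int hit = 0;
    for (int start = 0; start + min_overlap <= len; ++start) {
      int overlap = std::min(len - start, alen);
      int allowed = (int)(max_error_rate * overlap);
      int mism = 0;
      for (int j = 0; j < overlap; ++j) {
        if (s[start + j] != adapter[j]) {
          ++mism;
          if (mism > allowed) break;
        }
      }
      if (mism <= allowed) {
        hit = start + 1;
        break;
      }
    }
    out[i] = hit;
  }
  return out;
}

// Per-string count of quality characters with ASCII code < cutoff.
// [[Rcpp::export]]
IntegerVector count_below_cpp(CharacterVector quals, int cutoff) {
  R_xlen_t n = quals.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    int c = 0;
    for (const char* p = q; *p; ++p)
      if ((int)(unsigned char)*p < cutoff) ++c;
    out[i] = c;
  }
  return out;
}

// Replace bases whose quality character has ASCII code < cutoff with 'N'.
// [[Rcpp::export]]
CharacterVector mask_low_cpp(CharacterVector seqs, CharacterVector quals, int cutoff) {
  R_xlen_t n = seqs.size();
  if (quals.size() != n) stop("seq and qual vectors must have equal length");
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    const char* q = CHAR(STRING_ELT(quals, i));
    size_t ls = std::strlen(s);
    if (std::strlen(q) != ls)
      stop("seq/qual length mismatch in record %d", (int)(i + 1));
    buf.assign(s, ls);
    for (size_t j = 0; j < ls; ++j)
      if ((int)(unsigned char)q[j] < cutoff) buf[j] = 'N';
    out[i] = buf;
  }
  return out;
}

// Reference-consumed span of CIGAR strings (sum of M/D/N/=/X lengths);
// NA for "*" or empty.
// [[Rcpp::export]]
IntegerVector cigar_ref_span_cpp(CharacterVector cigars) {
  R_xlen_t n = cigars.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (STRING_ELT(cigars, i) == NA_STRING) {
      out[i] = NA_INTEGER;
      continue;
    }
    const char* c = CHAR(STRING_ELT(cigars, i));
    if (c[0] == '\0' || (c[0] == '*' && c[1] == '\0')) {
      out[i] = NA_INTEGER;
      continue;
    }
    long span = 0, num = 0;
    bool ok = true;
    for (const char* p = c; *p; ++p) {
      if (*p >= '0' && *p <= '9') {
        num = num * 10 + (*p - '0');
      } else {
        switch (*p) {
          case 'M': case 'D': case 'N': case '=': case 'X':
            span += num;
            break;
          case 'I': case 'S': case 'H': case 'P':
            break;
          default:
            ok = false;
        }
        num = 0;
        if (!ok) break;
      }
    }
    out[i] = ok ? (int)span : NA_INTEGER;
  }
  return out;
}

// Exhaustive equivalence check of the chunked mismatch counter against naive
// digit comparison, over all ordered pairs of strings of length `len` on the
// 5-symbol alphabet. Checks both uncapped exactness (limit = len) and the
// capped contract at `limit`. Returns the number of violations.
// [[Rcpp::export]]
double hamming_equiv_exhaustive_cpp(int len, int chunk_len, int limit) {
  if (len < 1 || len > 8) stop("len must be in [1, 8]");
  uint64_t nstr = 1;
  for (int i = 0; i < len; ++i) nstr *= 5ULL;

  // all strings as digit arrays + their per-chunk codes
  int nchunks = (len + chunk_len - 1) / chunk_len;
  std::vector<uint8_t> digits(nstr * len);
  std::vector<uint64_t> codes(nstr * nchunks);
  for (uint64_t v = 0; v < nstr; ++v) {
    uint64_t x = v;
    for (int i = len - 1; i >= 0; --i) {
      digits[v * len + i] = (uint8_t)(x % 5ULL);
      x /= 5ULL;
    }
    for (int c = 0; c < nchunks; ++c) {
      int off = c * chunk_len;
      int clen = std::min(chunk_len, len - off);
      uint64_t code = 0;
      for (int i = 0; i < clen; ++i)
        code = code * 10ULL + digits[v * len + off + i];
      codes[v * nchunks + c] = code;
    }
  }

  double bad = 0;
  for (uint64_t a = 0; a < nstr; ++a) {
    const uint8_t* da = &digits[a * len];
    const uint64_t* ca = &codes[a * nchunks];
    for (uint64_t b = 0; b < nstr; ++b) {
      const uint8_t* db = &digits[b * len];
      const uint64_t* cb = &codes[b * nchunks];
      int naive = 0;
      for (int i = 0; i < len; ++i)
        if (da[i] != db[i]) ++naive;
      // uncapped: chunked counter must equal the naive Hamming distance
      int full = 0;
      for (int c = 0; c < nchunks && full <= len; ++c)
        full += chunk_mismatches(ca[c], cb[c], len, full);
      if (full != naive) ++bad;
      // capped: exact when <= limit, otherwise any value > limit
      int capped = 0;
      for (int c = 0; c < nchunks && capped <= limit; ++c)
        capped += chunk_mismatches(ca[c], cb[c], limit, capped);
      if (naive <= limit ? (capped != naive) : (capped <= limit)) ++bad;
    }
  }
  return bad;
}
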