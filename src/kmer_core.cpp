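// Fast canonical k-mer primitives. k-mers with k <= 31 are packed 2 bits per
// base into a 64-bit word (A=0, C=1, G=2, T=3); the 2-bit order matches
// lexicographic order, so sorting packed keys sorts the decoded strings.
//
// Per-sample counting is sort-based (radix sort of the packed windows, then
// run-length encoding): at tens of millions of windows per sample this is
// markedly faster than hashing because every pass is sequential in memory.
// Bulk aggregation across samples uses an open-addressing hash table.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// ---------------------------------------------------------------- hashing

// open-addressing (linear probing) map; EMPTY sentinel is safe because
// packed k-mers occupy at most 62 bits
struct FlatMap {
  static constexpr uint64_t EMPTY = ~uint64_t(0);
  std::vector<uint64_t> keys;
  std::vector<double> vals;
  size_t mask, n, maxn;

  explicit FlatMap(size_t expected) { init(expected); }

  void init(size_t expected) {
    size_t sz = 64;
    while (sz < expected * 2) sz <<= 1;
    keys.assign(sz, EMPTY);
    vals.assign(sz, 0.0);
    mask = sz - 1;
    n = 0;
    maxn = (size_t)(sz * 0.7);
  }

  static inline uint64_t mix(uint64_t x) {
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
    x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
    x ^= x >> 33;
    return x;
  }

  void grow() {
    std::vector<uint64_t> ok;
    std::vector<double> ov;
    ok.swap(keys); ov.swap(vals);
    keys.assign(ok.size() * 2, EMPTY);
    vals.assign(ok.size() * 2, 0.0);
    mask = keys.size() - 1;
    maxn = (size_t)(keys.size() * 0.7);
    n = 0;
    for (size_t i = 0; i < ok.size(); ++i)
      if (ok[i] != EMPTY) add(ok[i], ov[i]);
  }

  inline void add(uint64_t key, double v) {
    size_t i = mix(key) & mask;
    while (keys[i] != EMPTY && keys[i] != key) i = (i + 1) & mask;
    if (keys[i] == EMPTY) {
      if (n >= maxn) { grow(); add(key, v); return; }
      keys[i] = key;
      ++n;
    }
    vals[i] += v;
  }

  inline double get(uint64_t key) const {
    size_t i = mix(key) & mask;
    while (keys[i] != EMPTY) {
      if (keys[i] == key) return vals[i];
      i = (i + 1) & mask;
    }
    return 0.0;
  }

  inline bool contains(uint64_t key) const {
    size_t i = mix(key) & mask;
    while (keys[i] != EMPTY) {
      if (keys[i] == key) return true;
      i = (i + 1) & mask;
    }
    return false;
  }

  // sorted (key, value) pairs, keeping values >= min_val
  void dump(std::vector<std::pair<uint64_t, double> > &kv,
            double min_val = 0.0) const {
    kv.clear();
    kv.reserve(n);
    for (size_t i = 0; i < keys.size(); ++i)
      if (keys[i] != EMPTY && vals[i] >= min_val)
        kv.push_back(std::make_pair(keys[i], vals[i]));
    std::sort(kv.begin(), kv.end());
  }
};

// ---------------------------------------------------------------- sorting

// LSD radix sort on 16-bit digits (4 sequential passes)
static void radix_sort_u64(std::vector<uint64_t> &a,
                           std::vector<uint64_t> &tmp) {
  const size_t n = a.size();
  if (n < 2) return;
  tmp.resize(n);
  std::vector<size_t> cnt(1 << 16);
  uint64_t *src = a.data(), *dst = tmp.data();
  for (int pass = 0; pass < 4; ++pass) {
    const int shift = 16 * pass;
    // skip passes whose digit is constant (common for high bits)
    uint64_t first = (src[0] >> shift) & 0xFFFF;
    bool constant = true;
    for (size_t i = 1; i < n; ++i)
      if (((src[i] >> shift) & 0xFFFF) != first) { constant = false; break; }
    if (constant) continue;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (size_t i = 0; i < n; ++i) ++cnt[(src[i] >> shift) & 0xFFFF];
    size_t run = 0;
    for (size_t d = 0; d < (1u << 16); ++d) {
      size_t c = cnt[d];
      cnt[d] = run;
      run += c;
    }
    for (size_t i = 0; i < n; ++i) dst[cnt[(src[i] >> shift) & 0xFFFF]++] = src[i];
    std::swap(src, dst);
  }
  if (src != a.data()) std::memcpy(a.data(), src, n * sizeof(uint64_t));
}

// ------------------------------------------------------------- iteration

// Slide over one sequence; windows containing non-ACGT break and restart.
template <typename F>
static inline void for_each_kmer(const char *s, R_xlen_t n, int k,
                                 bool canonical, F f) {
  const uint64_t mask = (uint64_t(1) << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | uint64_t(b)) & mask;
    rev = (rev >> 2) | (uint64_t(3 - b) << shift);
    if (++valid >= k) f(canonical ? std::min(fwd, rev) : fwd);
  }
}

// all packed windows of a read set, appended to buf
static void collect_windows(const CharacterVector &reads, int k,
                            bool canonical, std::vector<uint64_t> &buf,
                            R_xlen_t *n_short) {
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP s = reads[r];
    if (s == NA_STRING) stop("NA read at index %d", (int)(r + 1));
    const char *p = CHAR(s);
    const R_xlen_t len = LENGTH(s);
    if (len < k) { ++(*n_short); continue; }
    for_each_kmer(p, len, k, canonical,
                  [&](uint64_t key) { buf.push_back(key); });
  }
}

static size_t total_bases(const CharacterVector &reads) {
  size_t tot = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) tot += LENGTH(reads[r]);
  return tot;
}

// sort + run-length encode one sample's windows; calls g(key, count) for
// runs with count >= min_count
template <typename G>
static void rle_sample(std::vector<uint64_t> &buf,
                       std::vector<uint64_t> &tmp, double min_count, G g) {
  radix_sort_u64(buf, tmp);
  size_t i = 0;
  const size_t n = buf.size();
  while (i < n) {
    size_t j = i + 1;
    while (j < n && buf[j] == buf[i]) ++j;
    if ((double)(j - i) >= min_count) g(buf[i], (double)(j - i));
    i = j;
  }
}

// ---------------------------------------------------------- composition

// decoded strings straight into a CHARSXP vector
static SEXP pairs_to_strsxp(const std::vector<std::pair<uint64_t, double> > &kv,
                            int k) {
  SEXP ans = PROTECT(Rf_allocVector(STRSXP, (R_xlen_t)kv.size()));
  char buf[32];
  for (R_xlen_t i = 0; i < (R_xlen_t)kv.size(); ++i) {
    uint64_t key = kv[i].first;
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = BITS2BASE[key & 3u];
      key >>= 2;
    }
    SET_STRING_ELT(ans, i, Rf_mkCharLen(buf, k));
  }
  UNPROTECT(1);
  return ans;
}

static List pairs_to_df(const std::vector<std::pair<uint64_t, double> > &kv,
                        int k, double n_short) {
  NumericVector count((R_xlen_t)kv.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)kv.size(); ++i) count[i] = kv[i].second;
  return List::create(_["kmer"] = pairs_to_strsxp(kv, k),
                      _["count"] = count, _["n_too_short"] = n_short);
}

static inline uint64_t pack_kmer(const char *p, int k) {
  uint64_t key = 0;
  for (int j = 0; j < k; ++j) {
    const int b = base2bits(p[j]);
    if (b < 0) stop("non-ACGT character in k-mer");
    key = (key << 2) | uint64_t(b);
  }
  return key;
}

// [[Rcpp::export(name = ".cpp_count_kmers")]]
List cpp_count_kmers(CharacterVector reads, int k, bool canonical) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::vector<uint64_t> buf, tmp;
  buf.reserve(total_bases(reads));
  R_xlen_t n_short = 0;
  collect_windows(reads, k, canonical, buf, &n_short);
  std::vector<std::pair<uint64_t, double> > kv;
  rle_sample(buf, tmp, 0.0, [&](uint64_t key, double cnt) {
    kv.push_back(std::make_pair(key, cnt));
  });
  return pairs_to_df(kv, k, (double)n_short);
}

// Per-sample counting + per-sample min-count filter, aggregated into one
// bulk table in a single pass (same semantics as composing count_kmers,
// filter_singletons and merge_bulk sample by sample).
// [[Rcpp::export(name = ".cpp_count_bulk")]]
List cpp_count_bulk(List reads_by_sample, int k, bool canonical,
                    double min_sample_count) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  FlatMap bulk(1 << 16);
  std::vector<uint64_t> buf, tmp;
  R_xlen_t n_short = 0;
  for (int s = 0; s < reads_by_sample.size(); ++s) {
    CharacterVector reads = reads_by_sample[s];
    buf.clear();
    buf.reserve(total_bases(reads));
    collect_windows(reads, k, canonical, buf, &n_short);
    rle_sample(buf, tmp, min_sample_count,
               [&](uint64_t key, double cnt) { bulk.add(key, cnt); });
  }
  std::vector<std::pair<uint64_t, double> > kv;
  bulk.dump(kv);
  return pairs_to_df(kv, k, (double)n_short);
}

// Fused bulk pipeline: per-sample count + per-sample filter per bulk, bulk
// min-count thresholds, and the outer join of the two thresholded bulk
// tables, without materializing the intermediate tables. N_A / N_B are the
// total occurrences (sums) of the thresholded bulk tables.
// [[Rcpp::export(name = ".cpp_bulk_join")]]
List cpp_bulk_join(List reads_a, List reads_b, int k, bool canonical,
                   double min_sample_count, double min_bulk_count) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::vector<uint64_t> buf, tmp;
  R_xlen_t n_short = 0;
  std::vector<std::pair<uint64_t, double> > ta, tb;
  {
    FlatMap bulk(1 << 16);
    for (int s = 0; s < reads_a.size(); ++s) {
      CharacterVector reads = reads_a[s];
      buf.clear(); buf.reserve(total_bases(reads));
      collect_windows(reads, k, canonical, buf, &n_short);
      rle_sample(buf, tmp, min_sample_count,
                 [&](uint64_t key, double cnt) { bulk.add(key, cnt); });
    }
    bulk.dump(ta, min_bulk_count);
  }
  {
    FlatMap bulk(1 << 16);
    for (int s = 0; s < reads_b.size(); ++s) {
      CharacterVector reads = reads_b[s];
      buf.clear(); buf.reserve(total_bases(reads));
      collect_windows(reads, k, canonical, buf, &n_short);
      rle_sample(buf, tmp, min_sample_count,
                 [&](uint64_t key, double cnt) { bulk.add(key, cnt); });
    }
    bulk.dump(tb, min_bulk_count);
  }
  buf.clear(); tmp.clear();
  buf.shrink_to_fit(); tmp.shrink_to_fit();
  double N_A = 0, N_B = 0;
  for (size_t i = 0; i < ta.size(); ++i) N_A += ta[i].second;
  for (size_t i = 0; i < tb.size(); ++i) N_B += tb[i].second;
  // linear merge of the two sorted tables
  std::vector<std::pair<uint64_t, double> > un;
  un.reserve(ta.size() + tb.size());
  std::vector<double> ka, kb;
  ka.reserve(un.capacity()); kb.reserve(un.capacity());
  size_t ia = 0, ib = 0;
  while (ia < ta.size() || ib < tb.size()) {
    if (ib >= tb.size() || (ia < ta.size() && ta[ia].first < tb[ib].first)) {
      un.push_back(ta[ia]); ka.push_back(ta[ia].second); kb.push_back(0.0);
      ++ia;
    } else if (ia >= ta.size() || tb[ib].first < ta[ia].first) {
      un.push_back(tb[ib]); ka.push_back(0.0); kb.push_back(tb[ib].second);
      ++ib;
    } else {
      un.push_back(ta[ia]); ka.push_back(ta[ia].second);
      kb.push_back(tb[ib].second);
      ++ia; ++ib;
    }
  }
  return List::create(_["kmer"] = pairs_to_strsxp(un, k),
                      _["K_A"] = NumericVector(ka.begin(), ka.end()),
                      _["K_B"] = NumericVector(kb.begin(), kb.end()),
                      _["N_A"] = N_A, _["N_B"] = N_B,
                      _["n_too_short"] = (double)n_short);
}

// Counts of specific query k-mers in a read set, without materializing the
// full count table (used to probe parental read sets for the enriched
// k-mers). Queries must be length k; counts are per query, canonical when
// requested.
// [[Rcpp::export(name = ".cpp_count_lookup")]]
NumericVector cpp_count_lookup(List reads_by_sample, CharacterVector queries,
                               int k, bool canonical) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  FlatMap idx((size_t)queries.size() + 64);
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    SEXP si = queries[i];
    if ((int)LENGTH(si) != k) stop("query k-mer %d is not length k", (int)(i + 1));
    uint64_t key = pack_kmer(CHAR(si), k);
    if (idx.get(key) == 0.0) idx.add(key, (double)(i + 1)); // first wins
  }
  NumericVector out(queries.size());
  for (int s = 0; s < reads_by_sample.size(); ++s) {
    CharacterVector reads = reads_by_sample[s];
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
      SEXP sr = reads[r];
      const char *p = CHAR(sr);
      const R_xlen_t len = LENGTH(sr);
      if (len < k) continue;
      for_each_kmer(p, len, k, canonical, [&](uint64_t key) {
        double j = idx.get(key);
        if (j > 0) out[(R_xlen_t)j - 1] += 1;
      });
    }
  }
  // duplicated queries receive identical counts
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    uint64_t key = pack_kmer(CHAR((SEXP)queries[i]), k);
    double j = idx.get(key);
    if ((R_xlen_t)j - 1 != i) out[i] = out[(R_xlen_t)j - 1];
  }
  return out;
}

// Outer join of two (kmer, count) tables on packed keys: union of k-mers
// with per-bulk counts (0 where absent), lexicographically sorted.
// [[Rcpp::export(name = ".cpp_join_counts")]]
List cpp_join_counts(CharacterVector kmer_a, NumericVector count_a,
                     CharacterVector kmer_b, NumericVector count_b, int k) {
  std::vector<std::pair<uint64_t, double> > ta((size_t)kmer_a.size()),
      tb((size_t)kmer_b.size());
  for (R_xlen_t i = 0; i < kmer_a.size(); ++i)
    ta[i] = std::make_pair(pack_kmer(CHAR((SEXP)kmer_a[i]), k), count_a[i]);
  for (R_xlen_t i = 0; i < kmer_b.size(); ++i)
    tb[i] = std::make_pair(pack_kmer(CHAR((SEXP)kmer_b[i]), k), count_b[i]);
  std::sort(ta.begin(), ta.end());
  std::sort(tb.begin(), tb.end());
  std::vector<std::pair<uint64_t, double> > un;
  std::vector<double> ka, kb;
  size_t ia = 0, ib = 0;
  while (ia < ta.size() || ib < tb.size()) {
    if (ib >= tb.size() || (ia < ta.size() && ta[ia].first < tb[ib].first)) {
      un.push_back(ta[ia]); ka.push_back(ta[ia].second); kb.push_back(0.0);
      ++ia;
    } else if (ia >= ta.size() || tb[ib].first < ta[ia].first) {
      un.push_back(tb[ib]); ka.push_back(0.0); kb.push_back(tb[ib].second);
      ++ib;
    } else {
      un.push_back(ta[ia]); ka.push_back(ta[ia].second);
      kb.push_back(tb[ib].second);
      ++ia; ++ib;
    }
  }
  return List::create(_["kmer"] = pairs_to_strsxp(un, k),
                      _["K_A"] = NumericVector(ka.begin(), ka.end()),
                      _["K_B"] = NumericVector(kb.begin(), kb.end()));
}

// Canonical form (lexicographic min of k-mer and reverse complement) of
// each input sequence; NA for sequences with non-ACGT characters.
// [[Rcpp::export(name = ".cpp_canonicalize")]]
CharacterVector cpp_canonicalize(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP si = kmers[i];
    if (si == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *p = CHAR(si);
    const int k = LENGTH(si);
    if (k < 1 || k > 31) stop("k-mer length must be in [1, 31]");
    uint64_t fwd = 0, rev = 0;
    const int shift = 2 * (k - 1);
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      const int b = base2bits(p[j]);
      if (b < 0) { ok = false; break; }
      fwd = (fwd << 2) | uint64_t(b);
      rev = (rev >> 2) | (uint64_t(3 - b) << shift);
    }
    if (ok) {
      uint64_t key = std::min(fwd, rev);
      char buf[32];
      for (int j = k - 1; j >= 0; --j) { buf[j] = BITS2BASE[key & 3u]; key >>= 2; }
      out[i] = std::string(buf, k);
    } else out[i] = NA_STRING;
  }
  return out;
}

// Which reads contain at least one k-mer of the significant set
// (canonical match, so a read matching via its reverse complement counts).
// [[Rcpp::export(name = ".cpp_select_reads")]]
LogicalVector cpp_select_reads(CharacterVector reads, CharacterVector sig,
                               int k, bool canonical) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  FlatMap set((size_t)sig.size() + 64);
  for (R_xlen_t i = 0; i < sig.size(); ++i) {
    SEXP si = sig[i];
    if ((int)LENGTH(si) != k)
      stop("significant k-mer %d does not have length k", (int)(i + 1));
    const char *p = CHAR(si);
    bool ok = true;
    uint64_t key = 0;
    for (int j = 0; j < k; ++j) {
      const int b = base2bits(p[j]);
      if (b < 0) { ok = false; break; }
      key = (key << 2) | uint64_t(b);
    }
    if (ok) set.add(key, 1.0);
  }
  LogicalVector hit(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP sr = reads[r];
    const char *p = CHAR(sr);
    const R_xlen_t len = LENGTH(sr);
    bool found = false;
    if (len >= k) {
      for_each_kmer(p, len, k, canonical, [&](uint64_t key) {
        if (!found && set.contains(key)) found = true;
      });
    }
    hit[r] = found;
  }
  return hit;
}

// Read extraction for the simulator: slice plus-strand reads out of the
// homolog sequence and minus-strand reads out of its reverse complement,
// then apply presampled substitution errors at 1-based positions of the
// concatenated read string (shift in 1..3 rotates the base, so the
// replacement never equals the original).
// [[Rcpp::export(name = ".cpp_extract_reads")]]
SEXP cpp_extract_reads(std::string seq, std::string rc,
                       IntegerVector starts, LogicalVector minus,
                       int read_len, IntegerVector err_pos,
                       IntegerVector err_shift) {
  const size_t L = seq.size();
  const R_xlen_t n = starts.size();
  std::string big(n * (size_t)read_len, 'N');
  for (R_xlen_t i = 0; i < n; ++i) {
    const size_t s0 = (size_t)starts[i] - 1; // 1-based in
    const char *src;
    if (minus[i]) {
      // read spans [s0, s0 + read_len) on the forward strand; its reverse
      // complement starts at L - (s0 + read_len) in rc
      src = rc.data() + (L - s0 - read_len);
    } else {
      src = seq.data() + s0;
    }
    std::memcpy(&big[(size_t)i * read_len], src, read_len);
  }
  for (R_xlen_t e = 0; e < err_pos.size(); ++e) {
    const size_t p = (size_t)err_pos[e] - 1;
    const int b = base2bits(big[p]);
    if (b < 0) continue;
    big[p] = BITS2BASE[(b + err_shift[e]) & 3];
  }
  SEXP out = PROTECT(Rf_allocVector(STRSXP, n));
  for (R_xlen_t i = 0; i < n; ++i)
    SET_STRING_ELT(out, i,
                   Rf_mkCharLen(big.data() + (size_t)i * read_len, read_len));
  UNPROTECT(1);
  return out;
}
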