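// Bit-pattern bicluster enumeration kernels.
//
// Rows of the binary matrix are packed into unsigned words (32- or
// 64-bit, template parameter T).  Seeding ANDs every unordered row pair,
// keeps patterns with >= mnc set bits, and deduplicates them in a flat
// open-addressing hash keyed by the full pattern word sequence.  With
// multiple workers the membership-test-plus-insert is serialized by one
// mutex (pattern computation and popcount happen outside it).
// Completion intersects the column-support bitsets of each pattern's set
// columns, which yields exactly the rows r with pattern AND r == pattern;
// a direct row-scan variant is exported separately for cross-checking.
//
// No R API calls happen inside worker threads.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <memory>
#include <thread>
#include <mutex>
#include <algorithm>

using namespace Rcpp;

template <typename T> struct WordOps;
template <> struct WordOps<uint64_t> {
  static inline int popcount(uint64_t x) { return __builtin_popcountll(x); }
  static inline int ctz(uint64_t x) { return __builtin_ctzll(x); }
};
template <> struct WordOps<uint32_t> {
  static inline int popcount(uint32_t x) { return __builtin_popcount(x); }
  static inline int ctz(uint32_t x) { return __builtin_ctz(x); }
};

// Ascending lexicographic order on the unpacked column-bit sequence
// (column 0 first, '0' < '1'); with LSB-first packing the first
// differing column is the lowest differing bit of the first differing
// word.
template <typename T>
static inline bool pattern_less(const T* a, const T* b, int nwords) {
  for (int j = 0; j < nwords; ++j) {
    if (a[j] != b[j]) {
      int bit = WordOps<T>::ctz(a[j] ^ b[j]);
      return ((a[j] >> bit) & (T)1) == 0;
    }
  }
  return false;
}

// Static block partition of [0, total): the first (total mod workers)
// blocks are one item larger.
static void partition_blocks(int64_t total, int workers,
                             std::vector<int64_t>& starts,
                             std::vector<int64_t>& ends) {
  starts.resize(workers);
  ends.resize(workers);
  int64_t base = total / workers, rem = total % workers, pos = 0;
  for (int w = 0; w < workers; ++w) {
    int64_t len = base + (w < rem ? 1 : 0);
    starts[w] = pos;
    ends[w] = pos + len;
    pos += len;
  }
}

// Flat hash set of patterns with chunked arena storage.  Entry layout:
// nwords pattern words followed by the packed seeding row pair.  Index
// arithmetic uses a power-of-two chunk size so lookups avoid division.
template <typename T>
class PatternStore {
public:
  static const int CHUNK_SHIFT = 16;
  static const uint32_t CHUNK_MASK = (1u << CHUNK_SHIFT) - 1u;
  static int pair_words() { return sizeof(T) == 8 ? 1 : 2; }

  explicit PatternStore(int nwords)
      : nwords_(nwords), entry_words_(nwords + pair_words()), count_(0) {
    table_.assign(1u << 16, 0u);
    mask_ = table_.size() - 1;
  }

  uint64_t count() const { return count_; }
  int nwords() const { return nwords_; }

  const T* entry(uint32_t idx) const {
    return chunks_[idx >> CHUNK_SHIFT].get() +
           (size_t)(idx & CHUNK_MASK) * entry_words_;
  }

  void seed_pair(uint32_t idx, uint32_t& i, uint32_t& k) const {
    const T* e = entry(idx) + nwords_;
    if (sizeof(T) == 8) {
      uint64_t p = (uint64_t)e[0];
      i = (uint32_t)(p >> 32);
      k = (uint32_t)(p & 0xFFFFFFFFu);
    } else {
      i = (uint32_t)e[0];
      k = (uint32_t)e[1];
    }
  }

  // Membership test plus insert as one step (callers serialize when
  // running multi-threaded).  Returns true when the pattern was new.
  bool insert(const T* pat, uint32_t i, uint32_t k) {
    uint64_t h = hash(pat);
    size_t slot = h & mask_;
    for (;;) {
      uint32_t e = table_[slot];
      if (e == 0u) {
        uint32_t idx = append(pat, i, k);
        table_[slot] = idx + 1u;
        ++count_;
        if (2 * count_ >= (uint64_t)table_.size()) grow();
        return true;
      }
      if (std::memcmp(entry(e - 1u), pat, sizeof(T) * nwords_) == 0)
        return false;
      slot = (slot + 1) & mask_;
    }
  }

private:
  uint64_t hash(const T* p) const {
    uint64_t h = 0x9E3779B97F4A7C15ULL;
    for (int j = 0; j < nwords_; ++j) {
      h ^= (uint64_t)p[j];
      h *= 0xBF58476D1CE4E5B9ULL;
      h ^= h >> 31;
    }
    return h;
  }

  uint32_t append(const T* pat, uint32_t i, uint32_t k) {
    uint32_t idx = (uint32_t)count_;
    if ((idx >> CHUNK_SHIFT) >= chunks_.size()) {
      chunks_.emplace_back(new T[(size_t)(CHUNK_MASK + 1u) * entry_words_]);
    }
    T* dst = chunks_[idx >> CHUNK_SHIFT].get() +
             (size_t)(idx & CHUNK_MASK) * entry_words_;
    std::memcpy(dst, pat, sizeof(T) * nwords_);
    if (sizeof(T) == 8) {
      dst[nwords_] = (T)(((uint64_t)i << 32) | (uint64_t)k);
    } else {
      dst[nwords_] = (T)i;
      dst[nwords_ + 1] = (T)k;
    }
    return idx;
  }

  void grow() {
    std::vector<uint32_t> nt(table_.size() * 2, 0u);
    size_t nmask = nt.size() - 1;
    for (uint64_t idx = 0; idx < count_; ++idx) {
      size_t slot = hash(entry((uint32_t)idx)) & nmask;
      while (nt[slot] != 0u) slot = (slot + 1) & nmask;
      nt[slot] = (uint32_t)idx + 1u;
    }
    table_.swap(nt);
    mask_ = nmask;
  }

  int nwords_;
  int entry_words_;
  uint64_t count_;
  std::vector<uint32_t> table_;
  size_t mask_;
  std::vector<std::unique_ptr<T[]>> chunks_;
};

// ---- encoding helpers -------------------------------------------------

template <typename T>
static void pack_rows_from_bits(const int* bits, int m, int n,
                                std::vector<T>& rows, int& nwords) {
  const int W = sizeof(T) * 8;
  nwords = (n + W - 1) / W;
  rows.assign((size_t)m * nwords, (T)0);
  for (int j = 0; j < n; ++j) {
    const int* col = bits + (size_t)j * m;  // R matrices are column-major
    const int w = j / W;
    const T bitmask = (T)1 << (j % W);
    for (int i = 0; i < m; ++i) {
      if (col[i]) rows[(size_t)i * nwords + w] |= bitmask;
    }
  }
}

template <typename T>
static void rows_from_bytes(const Rbyte* bytes, int m, int nbytes,
                            std::vector<T>& rows, int nwords) {
  rows.assign((size_t)m * nwords, (T)0);
  for (int i = 0; i < m; ++i) {
    for (int b = 0; b < nbytes; ++b) {
      Rbyte v = bytes[(size_t)b * m + i];  // column-major raw matrix
      if (v) {
        rows[(size_t)i * nwords + b / (int)sizeof(T)] |=
            (T)v << (8 * (b % (int)sizeof(T)));
      }
    }
  }
}

template <typename T>
static void pattern_from_bytes(const Rbyte* bytes, int nbytes,
                               std::vector<T>& pat, int nwords) {
  pat.assign(nwords, (T)0);
  for (int b = 0; b < nbytes; ++b) {
    if (bytes[b]) pat[b / (int)sizeof(T)] |= (T)bytes[b] << (8 * (b % (int)sizeof(T)));
  }
}

template <typename T>
static void pattern_to_bytes(const T* pat, int nwords, Rbyte* out) {
  for (int j = 0; j < nwords; ++j) {
    for (unsigned s = 0; s < sizeof(T); ++s) {
      out[j * sizeof(T) + s] = (Rbyte)((pat[j] >> (8 * s)) & (T)0xFF);
    }
  }
}

// ---- seeding ----------------------------------------------------------

template <typename T>
static void seed_worker(const std::vector<T>& rows, int m, int nwords,
                        int mnc, const std::vector<int>& order,
                        int64_t a_begin, int64_t a_end,
                        PatternStore<T>* store, std::mutex* mtx) {
  std::vector<T> p(nwords);
  for (int64_t a = a_begin; a < a_end; ++a) {
    const T* ra = &rows[(size_t)order[a] * nwords];
    for (int b = (int)a + 1; b < m; ++b) {
      const T* rb = &rows[(size_t)order[b] * nwords];
      int num1 = 0;
      for (int j = 0; j < nwords; ++j) {
        p[j] = ra[j] & rb[j];
        num1 += WordOps<T>::popcount(p[j]);
      }
      if (num1 >= mnc) {
        uint32_t i = (uint32_t)order[a], k = (uint32_t)order[b];
        if (i > k) std::swap(i, k);
        if (mtx) {
          std::lock_guard<std::mutex> g(*mtx);
          store->insert(p.data(), i, k);
        } else {
          store->insert(p.data(), i, k);
        }
      }
    }
  }
}

template <typename T>
static void seed_all(const std::vector<T>& rows, int m, int nwords, int mnc,
                     const std::vector<int>& order, int workers,
                     PatternStore<T>& store) {
  if (workers <= 1) {
    seed_worker<T>(rows, m, nwords, mnc, order, 0, m - 1, &store, nullptr);
    return;
  }
  std::mutex mtx;
  std::vector<int64_t> s, e;
  partition_blocks(m - 1, workers, s, e);
  std::vector<std::thread> threads;
  for (int w = 0; w < workers; ++w) {
    threads.emplace_back(seed_worker<T>, std::cref(rows), m, nwords, mnc,
                         std::cref(order), s[w], e[w], &store, &mtx);
  }
  for (auto& t : threads) t.join();
}

// ---- completion -------------------------------------------------------

template <typename T>
struct Survivor {
  std::vector<T> pattern;
  std::vector<int> rows;  // 0-based
  std::vector<int> cols;  // 0-based
};

// Column-support bitsets: colbits[j] is the set of rows with a one in
// column j, packed over mwords words.
template <typename T>
static void build_colbits(const std::vector<T>& rows, int m, int nwords,
                          std::vector<T>& colbits, int& mwords) {
  const int W = sizeof(T) * 8;
  mwords = (m + W - 1) / W;
  colbits.assign((size_t)nwords * W * mwords, (T)0);
  for (int i = 0; i < m; ++i) {
    const T* ri = &rows[(size_t)i * nwords];
    const T rowbit = (T)1 << (i % W);
    const size_t rowword = i / W;
    for (int w = 0; w < nwords; ++w) {
      T word = ri[w];
      while (word) {
        int b = WordOps<T>::ctz(word);
        size_t col = (size_t)w * W + b;
        colbits[col * mwords + rowword] |= rowbit;
        word &= word - 1;
      }
    }
  }
}

template <typename T>
static void complete_worker(const PatternStore<T>* store,
                            const std::vector<T>* colbits, int mwords,
                            int m, int mnr, int64_t begin, int64_t end,
                            std::vector<Survivor<T>>* out) {
  const int W = sizeof(T) * 8;
  const int nwords = store->nwords();
  std::vector<T> acc(mwords);
  std::vector<int> cols;
  for (int64_t idx = begin; idx < end; ++idx) {
    const T* pat = store->entry((uint32_t)idx);
    cols.clear();
    for (int w = 0; w < nwords; ++w) {
      T word = pat[w];
      while (word) {
        int b = WordOps<T>::ctz(word);
        cols.push_back(w * W + b);
        word &= word - 1;
      }
    }
    const T* first = &(*colbits)[(size_t)cols[0] * mwords];
    std::memcpy(acc.data(), first, sizeof(T) * mwords);
    for (size_t c = 1; c < cols.size(); ++c) {
      const T* cb = &(*colbits)[(size_t)cols[c] * mwords];
      for (int w = 0; w < mwords; ++w) acc[w] &= cb[w];
    }
    int nr = 0;
    for (int w = 0; w < mwords; ++w) nr += WordOps<T>::popcount(acc[w]);
    if (nr >= mnr) {
      Survivor<T> s;
      s.pattern.assign(pat, pat + nwords);
      s.cols = cols;
      s.rows.reserve(nr);
      for (int w = 0; w < mwords; ++w) {
        T word = acc[w];
        while (word) {
          int b = WordOps<T>::ctz(word);
          s.rows.push_back(w * W + b);
          word &= word - 1;
        }
      }
      out->push_back(std::move(s));
    }
  }
}

template <typename T>
static std::vector<Survivor<T>> complete_all(const PatternStore<T>& store,
                                             const std::vector<T>& colbits,
                                             int mwords, int m, int mnr,
                                             int workers) {
  const int64_t total = (int64_t)store.count();
  std::vector<int64_t> s, e;
  partition_blocks(total, workers, s, e);
  std::vector<std::vector<Survivor<T>>> parts(workers);
  if (workers <= 1) {
    complete_worker<T>(&store, &colbits, mwords, m, mnr, 0, total, &parts[0]);
  } else {
    std::vector<std::thread> threads;
    for (int w = 0; w < workers; ++w) {
      threads.emplace_back(complete_worker<T>, &store, &colbits, mwords, m,
                           mnr, s[w], e[w], &parts[w]);
    }
    for (auto& t : threads) t.join();
  }
  std::vector<Survivor<T>> all;
  for (auto& p : parts) {
    for (auto& sv : p) all.push_back(std::move(sv));
  }
  std::sort(all.begin(), all.end(),
            [&](const Survivor<T>& a, const Survivor<T>& b) {
              return pattern_less<T>(a.pattern.data(), b.pattern.data(),
                                     store.nwords());
            });
  return all;
}

// ---- full pipeline ----------------------------------------------------

template <typename T>
static List run_impl(const IntegerMatrix& bits, int mnr, int mnc,
                     int workers, const std::vector<int>& order) {
  const int m = bits.nrow(), n = bits.ncol();
  int nwords = 0;
  std::vector<T> rows;
  pack_rows_from_bits<T>(bits.begin(), m, n, rows, nwords);

  PatternStore<T> store(nwords);
  seed_all<T>(rows, m, nwords, mnc, order, workers, store);

  std::vector<T> colbits;
  int mwords = 0;
  build_colbits<T>(rows, m, nwords, colbits, mwords);
  std::vector<Survivor<T>> surv =
      complete_all<T>(store, colbits, mwords, m, mnr, workers);

  const R_xlen_t ns = (R_xlen_t)surv.size();
  List rows_out(ns), cols_out(ns);
  for (R_xlen_t i = 0; i < ns; ++i) {
    IntegerVector r(surv[i].rows.size()), c(surv[i].cols.size());
    for (R_xlen_t j = 0; j < r.size(); ++j) r[j] = surv[i].rows[j] + 1;
    for (R_xlen_t j = 0; j < c.size(); ++j) c[j] = surv[i].cols[j] + 1;
    rows_out[i] = r;
    cols_out[i] = c;
  }
  return List::create(_["rows"] = rows_out, _["cols"] = cols_out,
                      _["n_seeds"] = (double)store.count());
}

static std::vector<int> make_order(int m, Nullable<IntegerVector> order_) {
  std::vector<int> order(m);
  if (order_.isNotNull()) {
    IntegerVector ov(order_);
    if ((int)ov.size() != m) stop("enumeration order must have length m");
    std::vector<bool> seen(m, false);
    for (int i = 0; i < m; ++i) {
      int v = ov[i] - 1;  // 1-based from R
      if (v < 0 || v >= m || seen[v]) stop("enumeration order must be a permutation of 1..m");
      seen[v] = true;
      order[i] = v;
    }
  } else {
    for (int i = 0; i < m; ++i) order[i] = i;
  }
  return order;
}

// [[Rcpp::export]]
List cpp_run(IntegerMatrix bits, int mnr, int mnc, int word_width,
             int workers, Nullable<IntegerVector> enum_order) {
  if (bits.nrow() < 2) stop("need at least 2 rows");
  if (workers < 1) stop("workers must be >= 1");
  std::vector<int> order = make_order(bits.nrow(), enum_order);
  if (word_width == 64) return run_impl<uint64_t>(bits, mnr, mnc, workers, order);
  if (word_width == 32) return run_impl<uint32_t>(bits, mnr, mnc, workers, order);
  stop("word_width must be 32 or 64");
}

// ---- exported building blocks (seed set, pair pattern, row scan) ------

template <typename T>
static List seed_impl(const RawMatrix& rowbytes, int n, int mnc, int workers,
                      const std::vector<int>& order) {
  const int W = sizeof(T) * 8;
  const int m = rowbytes.nrow();
  const int nwords = (n + W - 1) / W;
  if ((int)rowbytes.ncol() != nwords * (int)sizeof(T))
    stop("encoded row byte width does not match word width");
  std::vector<T> rows;
  rows_from_bytes<T>(rowbytes.begin(), m, rowbytes.ncol(), rows, nwords);

  PatternStore<T> store(nwords);
  seed_all<T>(rows, m, nwords, mnc, order, workers, store);

  const uint64_t ns = store.count();
  std::vector<uint32_t> idx(ns);
  for (uint64_t i = 0; i < ns; ++i) idx[i] = (uint32_t)i;
  std::sort(idx.begin(), idx.end(), [&](uint32_t a, uint32_t b) {
    return pattern_less<T>(store.entry(a), store.entry(b), nwords);
  });

  RawMatrix patterns((int)ns, nwords * (int)sizeof(T));
  IntegerMatrix pairs((int)ns, 2);
  IntegerVector ones((int)ns);
  std::vector<Rbyte> buf(nwords * sizeof(T));
  for (uint64_t i = 0; i < ns; ++i) {
    const T* pat = store.entry(idx[i]);
    pattern_to_bytes<T>(pat, nwords, buf.data());
    for (int b = 0; b < (int)buf.size(); ++b)
      patterns[(size_t)b * ns + i] = buf[b];
    uint32_t ri, rk;
    store.seed_pair(idx[i], ri, rk);
    pairs[i] = (int)ri + 1;
    pairs[ns + i] = (int)rk + 1;
    int cnt = 0;
    for (int j = 0; j < nwords; ++j) cnt += WordOps<T>::popcount(pat[j]);
    ones[i] = cnt;
  }
  return List::create(_["patterns"] = patterns, _["seed_rows"] = pairs,
                      _["ones"] = ones);
}

// [[Rcpp::export]]
List cpp_seed(RawMatrix rowbytes, int n, int word_width, int mnc,
              int workers, Nullable<IntegerVector> enum_order) {
  if (rowbytes.nrow() < 2) stop("need at least 2 rows");
  std::vector<int> order = make_order(rowbytes.nrow(), enum_order);
  if (word_width == 64) return seed_impl<uint64_t>(rowbytes, n, mnc, workers, order);
  if (word_width == 32) return seed_impl<uint32_t>(rowbytes, n, mnc, workers, order);
  stop("word_width must be 32 or 64");
}

template <typename T>
static List pair_impl(const RawMatrix& rowbytes, int n, int i, int k) {
  const int W = sizeof(T) * 8;
  const int m = rowbytes.nrow();
  const int nwords = (n + W - 1) / W;
  std::vector<T> rows;
  rows_from_bytes<T>(rowbytes.begin(), m, rowbytes.ncol(), rows, nwords);
  std::vector<T> p(nwords);
  int ones = 0;
  for (int j = 0; j < nwords; ++j) {
    p[j] = rows[(size_t)i * nwords + j] & rows[(size_t)k * nwords + j];
    ones += WordOps<T>::popcount(p[j]);
  }
  RawVector out(nwords * (int)sizeof(T));
  pattern_to_bytes<T>(p.data(), nwords, (Rbyte*)out.begin());
  return List::create(_["bytes"] = out, _["ones"] = ones);
}

// [[Rcpp::export]]
List cpp_pair_pattern(RawMatrix rowbytes, int n, int word_width, int i, int k) {
  const int m = rowbytes.nrow();
  if (i < 0 || k < 0 || i >= m || k >= m || i == k)
    stop("row indices must be distinct and within 1..m");
  if (word_width == 64) return pair_impl<uint64_t>(rowbytes, n, i, k);
  if (word_width == 32) return pair_impl<uint32_t>(rowbytes, n, i, k);
  stop("word_width must be 32 or 64");
}

// Direct row-scan completion: every row r with pattern AND r == pattern.
template <typename T>
static IntegerVector rowscan_impl(const RawMatrix& rowbytes, int n,
                                  const RawVector& pattern) {
  const int W = sizeof(T) * 8;
  const int m = rowbytes.nrow();
  const int nwords = (n + W - 1) / W;
  std::vector<T> rows, pat;
  rows_from_bytes<T>(rowbytes.begin(), m, rowbytes.ncol(), rows, nwords);
  if ((int)pattern.size() != nwords * (int)sizeof(T))
    stop("pattern byte width does not match the encoded matrix");
  pattern_from_bytes<T>((const Rbyte*)pattern.begin(), pattern.size(), pat, nwords);
  std::vector<int> hits;
  for (int i = 0; i < m; ++i) {
    const T* ri = &rows[(size_t)i * nwords];
    bool ok = true;
    for (int j = 0; j < nwords; ++j) {
      if ((pat[j] & ri[j]) != pat[j]) { ok = false; break; }
    }
    if (ok) hits.push_back(i + 1);
  }
  return wrap(hits);
}

// [[Rcpp::export]]
IntegerVector cpp_complete_rowscan(RawMatrix rowbytes, int n, int word_width,
                                   RawVector pattern) {
  if (word_width == 64) return rowscan_impl<uint64_t>(rowbytes, n, pattern);
  if (word_width == 32) return rowscan_impl<uint32_t>(rowbytes, n, pattern);
  stop("word_width must be 32 or 64");
}

// [[Rcpp::export]]
IntegerVector cpp_popcount(NumericVector x) {
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = __builtin_popcountll((uint64_t)x[i]);
  }
  return out;
}
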