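#pragma once

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <cstring>
#include <memory>
#include <random>
#include <string>
#include <unordered_map>
#include <vector>

namespace sc {

// ---------------------------------------------------------------------------
// alphabet helpers
// ---------------------------------------------------------------------------

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

inline char code_base(int i) { return "ACGT"[i]; }

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

inline std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Packed 2-bit key of the first 30 characters of a suffix (MSB first).
// Suffixes shorter than 30 are padded with the smallest code; key equality
// then implies nothing and callers fall back to a full comparison.  All
// pipeline suffixes have length >= 30, for which key equality is exactly
// "identical 30-character prefix".
inline uint64_t pack_key(const char* s, size_t avail) {
  uint64_t k = 0;
  const size_t m = avail < 30 ? avail : 30;
  for (size_t i = 0; i < m; ++i) k = (k << 2) | (uint64_t)base_code(s[i]);
  k <<= 2 * (30 - m);
  return k;
}

// Lexicographic comparison of two character ranges where running off the end
// of a segment sorts smallest ("$" sentinel semantics, no concatenation).
inline int suffix_cmp(const char* a, size_t la, const char* b, size_t lb) {
  const size_t m = la < lb ? la : lb;
  const int c = std::memcmp(a, b, m);
  if (c != 0) return c;
  if (la == lb) return 0;
  return la < lb ? -1 : 1;
}

// ---------------------------------------------------------------------------
// deterministic RNG (fixed algorithm; not tied to the stdlib's distribution
// implementations, so streams are reproducible across toolchains)
// ---------------------------------------------------------------------------

struct RNG {
  std::mt19937_64 eng;
  explicit RNG(uint64_t seed) : eng(seed) {}
  uint64_t u64() { return eng(); }
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  uint64_t below(uint64_t n) { return eng() % n; }
  bool bern(double p) { return unif() < p; }
};

// ---------------------------------------------------------------------------
// read segment corpus
// ---------------------------------------------------------------------------

constexpr uint8_t ORIG_TUMOUR = 0;
constexpr uint8_t ORIG_CONTROL = 1;

// Segments live in one concatenated text buffer so suffix comparisons are
// contiguous memory streams (suffixes never cross segment boundaries).
struct Corpus {
  std::string text;                 // concatenated A/C/G/T bases
  std::string phred;                // concatenated raw phred scores
  std::vector<uint64_t> start;      // n+1 segment start offsets
  std::vector<uint8_t> origin;      // ORIG_TUMOUR / ORIG_CONTROL
  // For auxiliary corpora every source segment is present in both
  // orientations; these map each member back to its originating segment.
  std::vector<int> orig_segment;    // 0-based index into the parent corpus
  std::vector<uint8_t> orientation; // 0 forward, 1 reverse complement

  Corpus() { start.push_back(0); }
  size_t n() const { return start.size() - 1; }
  const char* seq(size_t i) const { return text.data() + start[i]; }
  const char* qual(size_t i) const { return phred.data() + start[i]; }
  size_t len(size_t i) const { return start[i + 1] - start[i]; }
  std::string seq_str(size_t i) const {
    return std::string(seq(i), len(i));
  }
  void append(const char* s, const char* q, size_t l, uint8_t orig,
              int oseg, uint8_t orient) {
    text.append(s, l);
    phred.append(q, l);
    start.push_back(text.size());
    origin.push_back(orig);
    orig_segment.push_back(oseg);
    orientation.push_back(orient);
  }
};

using CorpusPtr = std::shared_ptr<Corpus>;

// Handle wrapped in an Rcpp::XPtr so shared ownership survives R-side gc.
struct CorpusHandle { CorpusPtr p; };

// ---------------------------------------------------------------------------
// generalised suffix array
// ---------------------------------------------------------------------------

struct GsaEntry {
  uint64_t key;   // packed first-30-char prefix
  uint32_t pos;   // absolute position of the suffix in corpus text
  uint32_t seg;
};

// allocator whose value-initialisation is a no-op: resize() of the
// (gigabyte-scale) entry vector skips the zeroing pass, halving the
// first-touch cost right before the scatter overwrites every element
template <typename T, typename A = std::allocator<T>>
struct no_init_alloc : public A {
  template <typename U>
  struct rebind {
    using other =
        no_init_alloc<U,
                      typename std::allocator_traits<A>::template rebind_alloc<U>>;
  };
  using A::A;
  template <typename U>
  void construct(U* p) noexcept {}
  template <typename U, typename... Args>
  void construct(U* p, Args&&... args) {
    ::new (static_cast<void*>(p)) U(std::forward<Args>(args)...);
  }
};

using GsaEntryVec = std::vector<GsaEntry, no_init_alloc<GsaEntry>>;

// Capped pool of entry buffers.  Suffix arrays of successive datasets and
// legs have near-identical sizes, and first-touch page faults on fresh
// multi-gigabyte allocations are expensive under sandboxed kernels, so
// freed buffers are kept (largest first, bounded total) for reuse.
struct EntryPool {
  static constexpr size_t CAP_BYTES = (size_t)22 << 27;  // ~2.75 GB
  std::vector<GsaEntryVec> bufs;
  size_t bytes = 0;

  static EntryPool& instance() {
    static EntryPool p;
    return p;
  }
  GsaEntryVec acquire() {
    if (bufs.empty()) return GsaEntryVec();
    // hand out the largest buffer
    size_t best = 0;
    for (size_t i = 1; i < bufs.size(); ++i)
      if (bufs[i].capacity() > bufs[best].capacity()) best = i;
    GsaEntryVec v = std::move(bufs[best]);
    bufs.erase(bufs.begin() + best);
    bytes -= v.capacity() * sizeof(GsaEntry);
    v.clear();
    return v;
  }
  void release(GsaEntryVec&& v) {
    if (v.capacity() == 0) return;
    bytes += v.capacity() * sizeof(GsaEntry);
    bufs.push_back(std::move(v));
    while (bytes > CAP_BYTES && !bufs.empty()) {
      // evict the smallest buffer
      size_t worst = 0;
      for (size_t i = 1; i < bufs.size(); ++i)
        if (bufs[i].capacity() < bufs[worst].capacity()) worst = i;
      bytes -= bufs[worst].capacity() * sizeof(GsaEntry);
      bufs.erase(bufs.begin() + worst);
    }
  }
};

struct GSA {
  CorpusPtr corp;
  int min_prefix = 30;
  bool includes_rc = false;
  bool key_sorted = false;  // ties broken by (seg, pos), not suffix order
  bool tumour_first = false;       // corpus lists all tumour segments first
  uint32_t ctrl_boundary = 0;      // first control segment index (if so)
  GsaEntryVec entries;
  ~GSA() { EntryPool::instance().release(std::move(entries)); }
  // section runs (CSR over entries); built on demand
  std::vector<uint64_t> run_start;  // size n_sections + 1
  // top-20-key-bit bucket index over runs, for O(1)-ish interval lookup
  std::vector<uint32_t> run_bucket;  // size 2^20 + 1
  bool runs_built = false;

  size_t n() const { return entries.size(); }

  uint16_t entry_off(size_t i) const {
    const GsaEntry& e = entries[i];
    return (uint16_t)(e.pos - corp->start[e.seg]);
  }
  uint32_t entry_len(size_t i) const {
    const GsaEntry& e = entries[i];
    return (uint32_t)(corp->start[e.seg + 1] - e.pos);
  }
  const char* suffix(size_t i, size_t* len) const {
    *len = entry_len(i);
    return corp->text.data() + entries[i].pos;
  }
};

struct GsaHandle { std::shared_ptr<GSA> p; };

// exact LCP between ranked suffixes i-1 and i
inline int gsa_lcp_exact(const GSA& g, size_t i) {
  size_t la, lb;
  const char* a = g.suffix(i - 1, &la);
  const char* b = g.suffix(i, &lb);
  const size_t m = la < lb ? la : lb;
  size_t k = 0;
  while (k < m && a[k] == b[k]) ++k;
  return (int)k;
}

// do ranked suffixes i-1 and i share a prefix of length >= min_prefix?
inline bool gsa_same_section(const GSA& g, size_t i) {
  const GsaEntry& a = g.entries[i - 1];
  const GsaEntry& b = g.entries[i];
  if (g.min_prefix == 30) return a.key == b.key;
  if (g.min_prefix < 30) {
    // compare exactly; short suffixes can never share >= min_prefix unless
    // both are long enough
    size_t la, lb;
    const char* pa = g.suffix(i - 1, &la);
    const char* pb = g.suffix(i, &lb);
    if ((int)la < g.min_prefix || (int)lb < g.min_prefix) return false;
    return std::memcmp(pa, pb, g.min_prefix) == 0;
  }
  if (a.key != b.key) return false;
  size_t la, lb;
  const char* pa = g.suffix(i - 1, &la);
  const char* pb = g.suffix(i, &lb);
  if ((int)la < g.min_prefix || (int)lb < g.min_prefix) return false;
  return std::memcmp(pa + 30, pb + 30, g.min_prefix - 30) == 0;
}

void gsa_build_runs(GSA& g);

// ---------------------------------------------------------------------------
// variant blocks
// ---------------------------------------------------------------------------

struct BlockSet {
  CorpusPtr aux;                   // oriented copies of the extracted reads
  std::vector<uint64_t> ptr;       // CSR, size n_blocks + 1
  std::vector<uint32_t> mem_seg;   // aux segment index per member
  std::vector<int32_t> mem_shift;  // alignment shift per member
  size_t n() const { return ptr.empty() ? 0 : ptr.size() - 1; }
};

struct BlockSetHandle { std::shared_ptr<BlockSet> p; };

// ---------------------------------------------------------------------------
// reference index (suffix array over the reference, per chromosome)
// ---------------------------------------------------------------------------

struct RefEntry {
  uint64_t key;
  uint32_t chrom;
  uint32_t pos;
};

struct RefIndex {
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<RefEntry> entries;  // all positions with >= 30 bases remaining
};

struct RefIndexHandle { std::shared_ptr<RefIndex> p; };

// exact full-length gapless occurrence check (single strand)
bool ref_exact_one_strand(const RefIndex& ri, const std::string& s);
// (chrom, pos) occurrences of one exact 30-mer
void ref_key_candidates(const RefIndex& ri, const char* pat30,
                        std::vector<std::pair<uint32_t, uint32_t>>& out);
// candidate leftmost positions of s (gapless, any mismatches counted later)
void ref_seed_candidates(const RefIndex& ri, const std::string& s, int step,
                         std::vector<std::pair<uint32_t, int64_t>>& out);

// ---------------------------------------------------------------------------
// consensus
// ---------------------------------------------------------------------------

struct AlnView {
  const char* seq;
  const char* phred;  // raw scores
  int len;
  int shift;          // column of (oriented) seq[0] in the alignment frame
  bool rc = false;    // walk the stored bytes reverse-complemented
};

struct Consensus {
  std::string s;
  std::vector<uint8_t> support;            // phred-filtered count > 0 at s[j]
  int start = 0;                           // frame column of s[0]
  std::vector<std::array<int, 4>> counts;  // phred >= p
  std::vector<std::array<int, 4>> any;     // all phreds
};

void consensus_build(const std::vector<AlnView>& views, int p, Consensus& out);
void consensus_pick(const std::vector<std::array<int, 4>>& counts,
                    const std::vector<std::array<int, 4>>& any,
                    std::string& s, std::vector<uint8_t>& support);

// ---------------------------------------------------------------------------
// control recruitment
// ---------------------------------------------------------------------------

struct RecruitHit {
  uint32_t seg;
  int32_t shift;
  uint8_t rc;
  int votes;
};

struct RecruitState {
  uint32_t epoch;
  int32_t shift;
  int32_t votes;
  uint8_t rc, multi;
};

struct RecruitScratch {
  std::vector<RecruitState> state;   // per corpus segment
  std::vector<uint32_t> touched;
  // rare multi-placement overflow: (seg, shift, rc) -> votes, linear scan
  std::vector<std::pair<uint64_t, int>> extra;
  uint32_t cur = 0;
  void init(size_t n) {
    if (state.size() < n) state.assign(n, RecruitState{0, 0, 0, 0, 0});
  }
};

void recruit_control_core(const GSA& g, const std::string& T,
                          RecruitScratch& rs, std::vector<RecruitHit>& hits);

// memoised per-consensus outcome of the pair construction / filter /
// calling cascade, keyed by min(T, revcomp(T)); everything downstream of a
// block's tumour consensus depends only on that string (plus shared
// structures), and reverse-complement mirror blocks give identical calls
struct PairOutcome {
  // 0 no_control, 1 no_overlap, 2 indel, 3 multilocus, 4 unmapped,
  // 5 kept without calls, 6 kept with calls
  uint8_t status = 0;
  long mask_events = 0;
  std::vector<int> call_chrom;
  std::vector<double> call_pos;
  std::vector<char> call_ref, call_alt;
};

struct PairCache {
  std::unordered_map<std::string, PairOutcome> map;
};
struct PairCacheHandle { std::shared_ptr<PairCache> p; };

// filters (definitions in filters.cpp)
bool indel_gapless_optimal(const std::string& T, const std::string& C,
                           int match, int mismatch, int gap, int* opt_score,
                           int* gapless_score, int* gapless_offset);
int masking_events_core(const std::vector<std::array<int, 4>>& fc, double e,
                        size_t j);

}  // namespace sc
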