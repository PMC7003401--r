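#include "sc_common.h"

using namespace Rcpp;
using namespace sc;

namespace sc {

// candidate leftmost placements (chrom, m) of s against the reference,
// seeded by exact 30-mers of s at positions q = 0, step, 2*step, ...
void ref_seed_candidates(const RefIndex& ri, const std::string& s, int step,
                         std::vector<std::pair<uint32_t, int64_t>>& out) {
  out.clear();
  const int n = (int)s.size();
  if (n < 30) {
    // short query: plain substring scan (rare path, used by emfilter on
    // sub-30 reads which the pipeline never produces)
    for (uint32_t c = 0; c < ri.seqs.size(); ++c) {
      size_t pos = ri.seqs[c].find(s);
      while (pos != std::string::npos) {
        out.push_back({c, (int64_t)pos});
        pos = ri.seqs[c].find(s, pos + 1);
      }
    }
    return;
  }
  for (int q = 0; q + 30 <= n; q += step) {
    const uint64_t key = pack_key(s.data() + q, 30);
    size_t a = 0, b = ri.entries.size();
    while (a < b) {
      const size_t mid = (a + b) / 2;
      if (ri.entries[mid].key < key) a = mid + 1; else b = mid;
    }
    for (size_t i = a; i < ri.entries.size() && ri.entries[i].key == key;
         ++i) {
      const int64_t m = (int64_t)ri.entries[i].pos - q;
      const uint32_t c = ri.entries[i].chrom;
      if (m < 0 || m + n > (int64_t)ri.seqs[c].size()) continue;
      out.push_back({c, m});
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// (chrom, pos) occurrences of one exact 30-mer
void ref_key_candidates(const RefIndex& ri, const char* pat30,
                        std::vector<std::pair<uint32_t, uint32_t>>& out) {
  out.clear();
  const uint64_t key = pack_key(pat30, 30);
  size_t a = 0, b = ri.entries.size();
  while (a < b) {
    const size_t mid = (a + b) / 2;
    if (ri.entries[mid].key < key) a = mid + 1; else b = mid;
  }
  for (size_t i = a; i < ri.entries.size() && ri.entries[i].key == key; ++i)
    out.push_back({ri.entries[i].chrom, ri.entries[i].pos});
}

bool ref_exact_one_strand(const RefIndex& ri, const std::string& s) {
  std::vector<std::pair<uint32_t, int64_t>> cand;
  if ((int)s.size() >= 30) {
    // a full-length exact match must in particular match at its first 30-mer
    const uint64_t key = pack_key(s.data(), 30);
    size_t a = 0, b = ri.entries.size();
    while (a < b) {
      const size_t mid = (a + b) / 2;
      if (ri.entries[mid].key < key) a = mid + 1; else b = mid;
    }
    for (size_t i = a; i < ri.entries.size() && ri.entries[i].key == key;
         ++i) {
      const uint32_t c = ri.entries[i].chrom;
      const int64_t m = (int64_t)ri.entries[i].pos;
      if (m + (int64_t)s.size() > (int64_t)ri.seqs[c].size()) continue;
      if (std::memcmp(ri.seqs[c].data() + m, s.data(), s.size()) == 0)
        return true;
    }
    return false;
  }
  ref_seed_candidates(ri, s, 1, cand);
  return !cand.empty();
}

}  // namespace sc

// [[Rcpp::export(name = ".ref_index_cpp")]]
SEXP ref_index_cpp(CharacterVector names, CharacterVector seqs) {
  auto ri = std::make_shared<RefIndex>();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (auto& ch : s) ch = (char)std::toupper(ch);
    for (char ch : s)
      if (base_code(ch) < 0)
        stop("reference sequence '%s' contains non-ACGT characters",
             as<std::string>(names[i]).c_str());
    ri->names.push_back(as<std::string>(names[i]));
    ri->seqs.push_back(std::move(s));
  }
  size_t total = 0;
  for (const auto& s : ri->seqs)
    if (s.size() >= 30) total += s.size() - 29;
  ri->entries.reserve(total);
  for (uint32_t c = 0; c < ri->seqs.size(); ++c) {
    const std::string& s = ri->seqs[c];
    if (s.size() < 30) continue;
    for (uint32_t p = 0; p + 30 <= s.size(); ++p)
      ri->entries.push_back({pack_key(s.data() + p, s.size() - p), c, p});
  }
  const RefIndex& R = *ri;
  std::sort(ri->entries.begin(), ri->entries.end(),
            [&R](const RefEntry& a, const RefEntry& b) {
              if (a.key != b.key) return a.key < b.key;
              const std::string& sa = R.seqs[a.chrom];
              const std::string& sb = R.seqs[b.chrom];
              const int cmp = suffix_cmp(sa.data() + a.pos + 30,
                                         sa.size() - a.pos - 30,
                                         sb.data() + b.pos + 30,
                                         sb.size() - b.pos - 30);
              if (cmp != 0) return cmp < 0;
              if (a.chrom != b.chrom) return a.chrom < b.chrom;
              return a.pos < b.pos;
            });
  return XPtr<RefIndexHandle>(new RefIndexHandle{ri}, true);
}

// [[Rcpp::export(name = ".ref_names_cpp")]]
CharacterVector ref_names_cpp(SEXP ref) {
  XPtr<RefIndexHandle> xp(ref);
  return wrap(xp->p->names);
}

// [[Rcpp::export(name = ".ref_lengths_cpp")]]
NumericVector ref_lengths_cpp(SEXP ref) {
  XPtr<RefIndexHandle> xp(ref);
  NumericVector out(xp->p->seqs.size());
  for (size_t i = 0; i < xp->p->seqs.size(); ++i)
    out[i] = (double)xp->p->seqs[i].size();
  return out;
}

// Does s occur exactly (full length, gapless) on either reference strand?
// [[Rcpp::export(name = ".ref_has_exact_cpp")]]
bool ref_has_exact_cpp(std::string s, SEXP ref) {
  XPtr<RefIndexHandle> xp(ref);
  const RefIndex& ri = *xp->p;
  for (char c : s)
    if (base_code(c) < 0) return false;  // N-containing: cannot match
  if (ref_exact_one_strand(ri, s)) return true;
  return ref_exact_one_strand(ri, revcomp(s));
}

// keep[i] = TRUE iff read i is NOT an exact full-length match to the
// reference on either strand (the emfilter predicate)
// [[Rcpp::export(name = ".emfilter_cpp")]]
LogicalVector emfilter_cpp(CharacterVector seqs, SEXP ref) {
  XPtr<RefIndexHandle> xp(ref);
  const RefIndex& ri = *xp->p;
  LogicalVector keep(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    bool clean = true;
    for (char c : s)
      if (base_code(c) < 0) {
        clean = false;
        break;
      }
    bool exact = false;
    if (clean) {
      exact = ref_exact_one_strand(ri, s) ||
              ref_exact_one_strand(ri, revcomp(s));
    }
    keep[i] = !exact;
  }
  return keep;
}

// Gapless seed-and-extend mapping of a consensus to the reference: every
// 30-mer on both strands seeds a candidate leftmost coordinate; the candidate
// with the fewest mismatches wins if unique and within max_mm.
// [[Rcpp::export(name = ".map_control_cpp")]]
List map_control_cpp(std::string C, SEXP ref, int max_mm) {
  XPtr<RefIndexHandle> xp(ref);
  const RefIndex& ri = *xp->p;
  const int n = (int)C.size();
  std::vector<std::pair<uint32_t, int64_t>> cand_p, cand_m;
  ref_seed_candidates(ri, C, 1, cand_p);
  const std::string Crc = revcomp(C);
  ref_seed_candidates(ri, Crc, 1, cand_m);

  int best_mm = max_mm + 1;
  int n_best = 0;
  uint32_t bc = 0;
  int64_t bm = 0;
  int bstrand = 0;
  auto consider = [&](const std::string& q, uint32_t c, int64_t m,
                      int strand) {
    const char* r = ri.seqs[c].data() + m;
    int mm = 0;
    for (int i = 0; i < n; ++i) {
      if (q[i] != r[i] && ++mm > best_mm) break;
    }
    if (mm < best_mm) {
      best_mm = mm;
      n_best = 1;
      bc = c;
      bm = m;
      bstrand = strand;
    } else if (mm == best_mm) {
      ++n_best;
    }
  };
  for (const auto& cm : cand_p) consider(C, cm.first, cm.second, 0);
  for (const auto& cm : cand_m) consider(Crc, cm.first, cm.second, 1);

  const bool mapped = best_mm <= max_mm && n_best == 1;
  return List::create(_["mapped"] = mapped, _["chrom"] = (int)bc + 1,
                      _["m"] = (double)bm,
                      _["strand"] = bstrand == 0 ? "+" : "-",
                      _["mismatches"] = best_mm <= max_mm ? best_mm : NA_INTEGER,
                      _["unique"] = n_best == 1, _["n_best"] = n_best);
}
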