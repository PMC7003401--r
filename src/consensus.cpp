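#include "sc_common.h"

using namespace Rcpp;
using namespace sc;

namespace sc {

// Phred-filtered frequency matrices over a gapless alignment of reads, and
// the consensus pick with the tie cascade:
//   argmax phred-filtered count -> among ties, argmax any-phred count ->
//   among remaining ties, lexicographically smallest base.
// Columns whose phred-filtered counts are all zero fall back to the any-phred
// tally entirely; such columns carry no phred support.
void consensus_build(const std::vector<AlnView>& views, int p, Consensus& out) {
  int lo = INT32_MAX, hi = INT32_MIN;
  for (const auto& v : views) {
    lo = std::min(lo, v.shift);
    hi = std::max(hi, v.shift + v.len);
  }
  if (views.empty() || hi <= lo) {
    out = Consensus();
    return;
  }
  const int W = hi - lo;
  // single packed tally per (column, base): any-phred count in the high
  // half, phred-filtered count in the low half (halves the memory traffic
  // of the innermost loop; counts stay < 2^16 for any realistic depth)
  std::vector<std::array<uint32_t, 4>> packed(W, {0, 0, 0, 0});
  for (const auto& v : views) {
    const int base = v.shift - lo;
    if (!v.rc) {
      for (int j = 0; j < v.len; ++j) {
        const int b = base_code(v.seq[j]);
        packed[base + j][b] +=
            0x10000u + (uint32_t)((int)v.phred[j] >= p);
      }
    } else {
      // walk the stored bytes back-to-front, complementing codes
      for (int j = 0; j < v.len; ++j) {
        const int b = 3 - base_code(v.seq[v.len - 1 - j]);
        packed[base + j][b] +=
            0x10000u + (uint32_t)((int)v.phred[v.len - 1 - j] >= p);
      }
    }
  }
  out.counts.assign(W, {0, 0, 0, 0});
  out.any.assign(W, {0, 0, 0, 0});
  for (int j = 0; j < W; ++j)
    for (int b = 0; b < 4; ++b) {
      out.any[j][b] = (int)(packed[j][b] >> 16);
      out.counts[j][b] = (int)(packed[j][b] & 0xffffu);
    }
  // trim leading/trailing columns without any coverage (possible only when a
  // view is empty; interior columns of a connected alignment are covered)
  int first = 0, last = W;
  auto covered = [&](int j) {
    const auto& a = out.any[j];
    return a[0] + a[1] + a[2] + a[3] > 0;
  };
  while (first < last && !covered(first)) ++first;
  while (last > first && !covered(last - 1)) --last;
  if (first > 0 || last < W) {
    out.counts.erase(out.counts.begin() + last, out.counts.end());
    out.counts.erase(out.counts.begin(), out.counts.begin() + first);
    out.any.erase(out.any.begin() + last, out.any.end());
    out.any.erase(out.any.begin(), out.any.begin() + first);
  }
  out.start = lo + first;
  consensus_pick(out.counts, out.any, out.s, out.support);
}

void consensus_pick(const std::vector<std::array<int, 4>>& counts,
                    const std::vector<std::array<int, 4>>& any,
                    std::string& s, std::vector<uint8_t>& support) {
  const size_t W = counts.size();
  s.assign(W, 'N');
  support.assign(W, 0);
  for (size_t j = 0; j < W; ++j) {
    const auto& f = counts[j];
    const auto& a = any[j];
    int maxf = std::max(std::max(f[0], f[1]), std::max(f[2], f[3]));
    int best;
    if (maxf > 0) {
      int besta = -1;
      best = -1;
      for (int b = 0; b < 4; ++b)
        if (f[b] == maxf && a[b] > besta) {
          besta = a[b];
          best = b;  // first (lexicographically smallest) among final ties
        }
      support[j] = 1;
    } else {
      // all filtered counts zero: any-phred majority, lexicographic ties
      int maxa = std::max(std::max(a[0], a[1]), std::max(a[2], a[3]));
      if (maxa == 0) continue;  // uncovered column (kept as 'N', trimmed away)
      best = 0;
      for (int b = 0; b < 4; ++b)
        if (a[b] == maxa) {
          best = b;
          break;
        }
    }
    s[j] = code_base(best);
  }
}

}  // namespace sc

static std::vector<std::string> quals_to_raw(const CharacterVector& qual) {
  std::vector<std::string> out;
  out.reserve(qual.size());
  for (R_xlen_t i = 0; i < qual.size(); ++i) {
    const char* q = CHAR(STRING_ELT(qual, i));
    const size_t n = std::strlen(q);
    std::string r(n, '\0');
    for (size_t j = 0; j < n; ++j) r[j] = (char)(q[j] - 33);
    out.push_back(std::move(r));
  }
  return out;
}

static List consensus_to_list(const Consensus& cns) {
  const size_t W = cns.counts.size();
  IntegerMatrix counts(4, W), any(4, W);
  for (size_t j = 0; j < W; ++j)
    for (int b = 0; b < 4; ++b) {
      counts(b, j) = cns.counts[j][b];
      any(b, j) = cns.any[j][b];
    }
  counts.attr("dimnames") =
      List::create(CharacterVector::create("A", "C", "G", "T"), R_NilValue);
  any.attr("dimnames") =
      List::create(CharacterVector::create("A", "C", "G", "T"), R_NilValue);
  return List::create(_["consensus"] = cns.s,
                      _["support"] = LogicalVector(cns.support.begin(),
                                                   cns.support.end()),
                      _["start"] = cns.start, _["counts"] = counts,
                      _["any_phred_counts"] = any);
}

// [[Rcpp::export(name = ".consensus_views_cpp")]]
List consensus_views_cpp(CharacterVector seq, CharacterVector qual,
                         IntegerVector shift, int p) {
  const auto raw = quals_to_raw(qual);
  std::vector<AlnView> views;
  std::vector<std::string> seqs;
  seqs.reserve(seq.size());
  for (R_xlen_t i = 0; i < seq.size(); ++i)
    seqs.emplace_back(CHAR(STRING_ELT(seq, i)));
  for (R_xlen_t i = 0; i < seq.size(); ++i) {
    if (seqs[i].size() != raw[i].size())
      stop("phred string length differs from sequence length at row %d",
           (int)i + 1);
    for (char c : seqs[i])
      if (base_code(c) < 0)
        stop("alignment row %d contains a non-ACGT character", (int)i + 1);
    views.push_back({seqs[i].data(), raw[i].data(), (int)seqs[i].size(),
                     shift[i]});
  }
  Consensus cns;
  consensus_build(views, p, cns);
  return consensus_to_list(cns);
}

// [[Rcpp::export(name = ".consensus_from_f_cpp")]]
List consensus_from_f_cpp(IntegerMatrix counts, IntegerMatrix any) {
  if (counts.nrow() != 4 || any.nrow() != 4 || counts.ncol() != any.ncol())
    stop("frequency matrices must be 4 x W with matching widths");
  const size_t W = counts.ncol();
  std::vector<std::array<int, 4>> f(W), a(W);
  for (size_t j = 0; j < W; ++j)
    for (int b = 0; b < 4; ++b) {
      f[j][b] = counts(b, j);
      a[j][b] = any(b, j);
    }
  std::string s;
  std::vector<uint8_t> support;
  consensus_pick(f, a, s, support);
  return List::create(_["consensus"] = s,
                      _["support"] = LogicalVector(support.begin(),
                                                   support.end()));
}

// ---------------------------------------------------------------------------
// control recruitment through the primary array
// ---------------------------------------------------------------------------

namespace sc {

// locate the GSA interval of entries whose first 30 characters equal pat
static void gsa_interval30(const GSA& g, const char* pat, uint64_t* lo,
                           uint64_t* hi) {
  const size_t n = g.n();
  if (g.min_prefix == 30 && g.runs_built) {
    // sections are exactly the distinct 30-mer prefixes: bisect the few
    // runs sharing the key's top 20 bits
    const uint64_t key = pack_key(pat, 30);
    const size_t nr = g.run_start.size() - 1;
    size_t a = g.run_bucket[key >> 40], b = g.run_bucket[(key >> 40) + 1];
    while (a < b) {
      const size_t mid = (a + b) / 2;
      if (g.entries[g.run_start[mid]].key < key)
        a = mid + 1;
      else
        b = mid;
    }
    if (a < nr && g.entries[g.run_start[a]].key == key) {
      *lo = g.run_start[a];
      *hi = g.run_start[a + 1];
    } else {
      *lo = *hi = 0;
    }
    return;
  }
  // general path: direct binary search with 30-char-bounded comparisons;
  // suffixes shorter than 30 compare smaller than any full pattern
  auto cmp_lt = [&](size_t i) {  // suffix(i) < pat (first 30 chars)
    size_t len;
    const char* s = g.suffix(i, &len);
    const size_t m = len < 30 ? len : 30;
    const int c = std::memcmp(s, pat, m);
    if (c != 0) return c < 0;
    return len < 30;
  };
  auto cmp_le = [&](size_t i) {  // suffix(i) <= pat on first 30 chars
    size_t len;
    const char* s = g.suffix(i, &len);
    const size_t m = len < 30 ? len : 30;
    const int c = std::memcmp(s, pat, m);
    if (c != 0) return c < 0;
    return true;  // equal prefix or shorter suffix
  };
  size_t a = 0, b = n;
  while (a < b) {
    const size_t mid = (a + b) / 2;
    if (cmp_lt(mid)) a = mid + 1; else b = mid;
  }
  *lo = a;
  b = n;
  while (a < b) {
    const size_t mid = (a + b) / 2;
    if (cmp_le(mid)) a = mid + 1; else b = mid;
  }
  *hi = a;
}

static void recruit_add(RecruitScratch& rs, uint32_t seg, int32_t shift,
                        uint8_t rc) {
  RecruitState& s = rs.state[seg];
  if (s.epoch != rs.cur) {
    s = {rs.cur, shift, 1, rc, 0};
    rs.touched.push_back(seg);
  } else if (s.shift == shift && s.rc == rc) {
    s.votes++;
  } else {
    s.multi = 1;
    // 22-bit biased shift + orientation bit below the segment id
    const uint64_t x = (uint64_t)(uint32_t)(shift + (1 << 21)) & 0x3fffffull;
    const uint64_t key = ((uint64_t)seg << 23) | (x << 1) | rc;
    for (auto& kv : rs.extra)
      if (kv.first == key) {
        kv.second++;
        return;
      }
    rs.extra.push_back({key, 1});
  }
}

// All control reads sharing a 30-character exact match with T (or with its
// reverse complement); shift places read position 0 in T's frame.  A read
// matching at several placements keeps the placement with the most matching
// 30-mers; exact ties are dropped as unresolved.
void recruit_control_core(const GSA& g, const std::string& T,
                          RecruitScratch& rs, std::vector<RecruitHit>& hits) {
  hits.clear();
  if ((int)T.size() < 30) return;
  rs.init(g.corp->n());
  rs.cur++;
  rs.touched.clear();
  rs.extra.clear();
  const int Tn = (int)T.size();
  // with a tumour-first corpus and (seg, pos) tie-breaks, the control
  // entries of a section form its tail: bisect to skip the tumour block
  const bool skip_tum = g.key_sorted && g.tumour_first;
  auto first_control = [&](uint64_t lo, uint64_t hi) {
    if (!skip_tum) return lo;
    while (lo < hi) {
      const uint64_t mid = (lo + hi) / 2;
      if (g.entries[mid].seg < g.ctrl_boundary) lo = mid + 1; else hi = mid;
    }
    return lo;
  };
  for (int q = 0; q + 30 <= Tn; ++q) {
    uint64_t lo, hi;
    gsa_interval30(g, T.data() + q, &lo, &hi);
    for (uint64_t i = first_control(lo, hi); i < hi; ++i) {
      const GsaEntry& e = g.entries[i];
      if (!skip_tum && g.corp->origin[e.seg] != ORIG_CONTROL) continue;
      recruit_add(rs, e.seg, q - (int)(e.pos - g.corp->start[e.seg]), 0);
    }
  }
  const std::string Trc = revcomp(T);
  for (int q = 0; q + 30 <= Tn; ++q) {
    uint64_t lo, hi;
    gsa_interval30(g, Trc.data() + q, &lo, &hi);
    for (uint64_t i = first_control(lo, hi); i < hi; ++i) {
      const GsaEntry& e = g.entries[i];
      if (!skip_tum && g.corp->origin[e.seg] != ORIG_CONTROL) continue;
      // read matches revcomp(T) at q; after reverse complementing the read it
      // sits at this shift in T's own frame
      const int len = (int)g.corp->len(e.seg);
      const int shift = Tn - q - len + (int)(e.pos - g.corp->start[e.seg]);
      recruit_add(rs, e.seg, shift, 1);
    }
  }
  for (uint32_t seg : rs.touched) {
    const RecruitState& s = rs.state[seg];
    if (!s.multi) {
      hits.push_back({seg, s.shift, s.rc, s.votes});
      continue;
    }
    // competing placements: strict vote maximum wins, ties drop the read
    int best_votes = s.votes;
    int32_t best_shift = s.shift;
    uint8_t best_rc = s.rc;
    bool tie = false;
    for (const auto& kv : rs.extra) {
      if ((uint32_t)(kv.first >> 23) != seg) continue;
      const int v = kv.second;
      const int32_t sh = (int32_t)((kv.first >> 1) & 0x3fffffull) - (1 << 21);
      const uint8_t rc = kv.first & 1;
      if (v > best_votes) {
        best_votes = v;
        best_shift = sh;
        best_rc = rc;
        tie = false;
      } else if (v == best_votes) {
        tie = true;
      }
    }
    if (!tie) hits.push_back({seg, best_shift, best_rc, best_votes});
  }
  std::sort(hits.begin(), hits.end(),
            [](const RecruitHit& a, const RecruitHit& b) {
              return a.seg < b.seg;
            });
}

}  // namespace sc

// [[Rcpp::export(name = ".recruit_control_cpp")]]
DataFrame recruit_control_cpp(std::string T, SEXP gsa) {
  XPtr<GsaHandle> xp(gsa);
  GSA& g = *xp->p;
  gsa_build_runs(g);
  RecruitScratch rs;
  std::vector<RecruitHit> hits;
  recruit_control_core(g, T, rs, hits);
  const size_t n = hits.size();
  IntegerVector seg(n), shift(n), votes(n);
  LogicalVector rc(n);
  for (size_t i = 0; i < n; ++i) {
    seg[i] = (int)hits[i].seg + 1;
    shift[i] = hits[i].shift;
    rc[i] = hits[i].rc != 0;
    votes[i] = hits[i].votes;
  }
  return DataFrame::create(_["segment"] = seg, _["shift"] = shift,
                           _["revcomp"] = rc, _["votes"] = votes,
                           _["stringsAsFactors"] = false);
}
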