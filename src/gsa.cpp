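#include "sc_common.h"

using namespace Rcpp;
using namespace sc;

namespace sc {

// Maximal runs of consecutive entries whose adjacent pairs share a prefix of
// length >= min_prefix.  With min_prefix = 30 a run is exactly the set of
// suffixes sharing one 30-character prefix, so runs double as the section
// lookup table used by control recruitment.
void gsa_build_runs(GSA& g) {
  if (g.runs_built) return;
  g.run_start.clear();
  const size_t n = g.n();
  g.run_start.push_back(0);
  if (n > 0) {
    for (size_t i = 1; i < n; ++i)
      if (!gsa_same_section(g, i)) g.run_start.push_back(i);
    g.run_start.push_back(n);
  }
  // bucket the runs by their key's top 20 bits so interval lookups bisect
  // only a handful of runs
  const size_t nr = g.run_start.size() - 1;
  g.run_bucket.assign((1u << 20) + 1, 0);
  for (size_t r = 0; r < nr; ++r)
    g.run_bucket[(g.entries[g.run_start[r]].key >> 40) + 1]++;
  for (size_t b = 1; b < g.run_bucket.size(); ++b)
    g.run_bucket[b] += g.run_bucket[b - 1];
  g.runs_built = true;
}

}  // namespace sc

static std::shared_ptr<GSA> gsa_build_core(CorpusPtr corp, bool includes_rc,
                                           int min_prefix, bool full_order) {
  auto g = std::make_shared<GSA>();
  g->corp = corp;
  g->min_prefix = min_prefix;
  g->includes_rc = includes_rc;
  g->entries = EntryPool::instance().acquire();

  if (corp->text.size() > UINT32_MAX)
    Rcpp::stop("corpus exceeds the 4 Gb indexing limit");
  const bool dbg0 = std::getenv("SARCALL_TIME") != nullptr;
  clock_t tg = clock();
  size_t total = 0;
  for (size_t si = 0; si < corp->n(); ++si)
    if ((int)corp->len(si) >= min_prefix)
      total += corp->len(si) - min_prefix + 1;
  const char* text = corp->text.data();
  constexpr uint64_t MASK60 = (1ull << 60) - 1;
  // enumerate every suffix of length >= min_prefix with its rolling
  // 30-char key (shifting in zeros at the segment end reproduces
  // pack_key's short-suffix padding)
  const auto for_each_suffix = [&](auto&& emit) {
    for (size_t si = 0; si < corp->n(); ++si) {
      const size_t L = corp->len(si);
      if ((int)L < min_prefix) continue;
      const uint64_t base = corp->start[si];
      const size_t no = L - min_prefix + 1;
      if (L >= 30) {
        uint64_t key = pack_key(text + base, 30);
        for (size_t o = 0; o < no; ++o) {
          emit(key, (uint32_t)(base + o), (uint32_t)si);
          if (o + 30 < L)
            key = ((key << 2) & MASK60) |
                  (uint64_t)base_code(text[base + o + 30]);
          else
            key = (key << 2) & MASK60;
        }
      } else {
        for (size_t o = 0; o < no; ++o)
          emit(pack_key(text + base + o, L - o), (uint32_t)(base + o),
               (uint32_t)si);
      }
    }
  };

  if (!full_order && min_prefix != 30)
    Rcpp::stop("key-only ordering requires min_prefix = 30");
  const bool dbg = dbg0;
  clock_t t0 = clock();
  if (dbg)
    Rprintf("[gsa] generate %.1fs\n", (double)(t0 - tg) / CLOCKS_PER_SEC);
  auto tick = [&](const char* what) {
    if (!dbg) return;
    Rprintf("[gsa] %s %.1fs\n", what,
            (double)(clock() - t0) / CLOCKS_PER_SEC);
    t0 = clock();
  };
  const std::vector<uint64_t>& sstart = corp->start;
  // Exact lexicographic comparator (public contract): packed 30-char key,
  // then the suffix remainder, then a stable (segment, offset) tie-break.
  const auto cmp_full = [text, &sstart](const GsaEntry& a, const GsaEntry& b) {
    if (a.key != b.key) return a.key < b.key;
    const size_t la = sstart[a.seg + 1] - a.pos;
    const size_t lb = sstart[b.seg + 1] - b.pos;
    const size_t skip = (la < 30 || lb < 30) ? 0 : 30;
    const int c = suffix_cmp(text + a.pos + skip, la - skip,
                             text + b.pos + skip, lb - skip);
    if (c != 0) return c < 0;
    if (a.seg != b.seg) return a.seg < b.seg;
    return a.pos < b.pos;
  };
  // Key-only comparator: groups suffixes into the same 30-prefix sections
  // without ordering inside a section.  Everything the calling pipeline
  // consumes (sections, counts, member sets, interval lookups) is invariant
  // under within-section order, so this avoids all text accesses.
  const auto cmp_key = [](const GsaEntry& a, const GsaEntry& b) {
    if (a.key != b.key) return a.key < b.key;
    if (a.seg != b.seg) return a.seg < b.seg;
    return a.pos < b.pos;
  };
  const size_t n = total;
  const auto run_sort = [&](auto comparator) {
    if (n < (1u << 21)) {
      g->entries.reserve(n);
      for_each_suffix([&](uint64_t k, uint32_t pos, uint32_t seg) {
        g->entries.push_back({k, pos, seg});
      });
      std::sort(g->entries.begin(), g->entries.end(), comparator);
      return;
    }
    // Bucket by key bits 44..59 (the top 8 packed characters): histogram
    // pass, then a second enumeration scattering each entry straight into
    // its bucket through per-bucket cache-line write buffers; finally an
    // ordinary sort inside each bucket (buckets are small enough that any
    // deep comparisons stay cache-local).
    constexpr size_t NB = 65536;
    std::vector<uint64_t> cnt(NB + 1, 0);
    for_each_suffix([&](uint64_t k, uint32_t, uint32_t) {
      cnt[(k >> 44) + 1]++;
    });
    for (size_t i = 1; i <= NB; ++i) cnt[i] += cnt[i - 1];
    tick("histogram");
    g->entries.resize(n);
    GsaEntry* out = g->entries.data();
    constexpr size_t BUF = 4;  // 4 x 16 B = one cache line per bucket
    std::vector<GsaEntry> buf(NB * BUF);
    std::vector<uint8_t> nbuf(NB, 0);
    std::vector<uint64_t> cur(cnt.begin(), cnt.end() - 1);
    for_each_suffix([&](uint64_t k, uint32_t pos, uint32_t seg) {
      const size_t b = k >> 44;
      buf[b * BUF + nbuf[b]] = {k, pos, seg};
      if (++nbuf[b] == BUF) {
        std::memcpy(out + cur[b], &buf[b * BUF], BUF * sizeof(GsaEntry));
        cur[b] += BUF;
        nbuf[b] = 0;
      }
    });
    for (size_t b = 0; b < NB; ++b)
      for (size_t j = 0; j < nbuf[b]; ++j) out[cur[b]++] = buf[b * BUF + j];
    tick("scatter");
    for (size_t b = 0; b < NB; ++b)
      if (cnt[b + 1] > cnt[b] + 1)
        std::sort(g->entries.begin() + cnt[b],
                  g->entries.begin() + cnt[b + 1], comparator);
    tick("bucket sorts");
  };
  if (full_order)
    run_sort(cmp_full);
  else
    run_sort(cmp_key);
  g->key_sorted = !full_order;
  // tumour-first corpus layout enables skipping tumour entries during
  // recruitment interval scans (entries within a section tie-break by seg)
  g->tumour_first = true;
  g->ctrl_boundary = (uint32_t)corp->n();
  for (size_t i = 0; i < corp->n(); ++i) {
    if (corp->origin[i] == ORIG_CONTROL) {
      g->ctrl_boundary = std::min(g->ctrl_boundary, (uint32_t)i);
    } else if ((uint32_t)i >= g->ctrl_boundary) {
      g->tumour_first = false;
      break;
    }
  }
  return g;
}

// [[Rcpp::export(name = ".gsa_build_cpp")]]
SEXP gsa_build_cpp(SEXP corpus, bool include_revcomp, int min_prefix,
                   bool full_order) {
  XPtr<CorpusHandle> cxp(corpus);
  CorpusPtr corp = cxp->p;
  if (include_revcomp) {
    // materialise an oriented corpus: every segment in both orientations
    auto aux = std::make_shared<Corpus>();
    const size_t n = corp->n();
    aux->text.reserve(2 * corp->text.size());
    aux->phred.reserve(2 * corp->text.size());
    std::string rc, rq;
    for (size_t i = 0; i < n; ++i) {
      const size_t l = corp->len(i);
      aux->append(corp->seq(i), corp->qual(i), l, corp->origin[i],
                  corp->orig_segment[i], corp->orientation[i]);
      rc.assign(corp->seq(i), l);
      std::reverse(rc.begin(), rc.end());
      for (auto& c : rc) c = comp_base(c);
      rq.assign(corp->qual(i), l);
      std::reverse(rq.begin(), rq.end());
      aux->append(rc.data(), rq.data(), l, corp->origin[i],
                  corp->orig_segment[i], 1 - corp->orientation[i]);
    }
    corp = aux;
  }
  auto g = gsa_build_core(corp, include_revcomp, min_prefix, full_order);
  XPtr<GsaHandle> xp(new GsaHandle{g}, true);
  return xp;
}

// [[Rcpp::export(name = ".gsa_subset_corpus_cpp")]]
SEXP gsa_subset_corpus_cpp(SEXP corpus, IntegerVector keep0) {
  XPtr<CorpusHandle> cxp(corpus);
  const Corpus& c = *cxp->p;
  auto sub = std::make_shared<Corpus>();
  for (int k : keep0)
    sub->append(c.seq(k), c.qual(k), c.len(k), c.origin[k],
                c.orig_segment[k], c.orientation[k]);
  return XPtr<CorpusHandle>(new CorpusHandle{sub}, true);
}

// Drop a GSA eagerly (instead of waiting for garbage collection) so its
// entry buffer returns to the reuse pool while it is still hot.
// [[Rcpp::export(name = ".gsa_release_cpp")]]
void gsa_release_cpp(SEXP gsa) {
  XPtr<GsaHandle> xp(gsa);
  xp->p.reset();
}

// [[Rcpp::export(name = ".gsa_size_cpp")]]
double gsa_size_cpp(SEXP gsa) {
  XPtr<GsaHandle> xp(gsa);
  return (double)xp->p->n();
}

// Full entry table with exact adjacent LCP values; intended for small arrays
// (tests, debugging dumps).
// [[Rcpp::export(name = ".gsa_entries_cpp")]]
DataFrame gsa_entries_cpp(SEXP gsa) {
  XPtr<GsaHandle> xp(gsa);
  const GSA& g = *xp->p;
  const size_t n = g.n();
  IntegerVector seg(n), off(n), lcp(n), orient(n), oseg(n);
  CharacterVector origin(n);
  for (size_t i = 0; i < n; ++i) {
    seg[i] = (int)g.entries[i].seg + 1;
    off[i] = (int)g.entry_off(i);
    lcp[i] = i == 0 ? NA_INTEGER : gsa_lcp_exact(g, i);
    origin[i] = g.corp->origin[g.entries[i].seg] == ORIG_TUMOUR ? "tumour"
                                                                : "control";
    orient[i] = (int)g.corp->orientation[g.entries[i].seg];
    oseg[i] = g.corp->orig_segment[g.entries[i].seg] + 1;
  }
  return DataFrame::create(
      _["rank"] = seq_len(n), _["segment"] = seg, _["offset"] = off,
      _["origin"] = origin, _["lcp"] = lcp, _["orientation"] = orient,
      _["source_segment"] = oseg, _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".gsa_sections_cpp")]]
DataFrame gsa_sections_cpp(SEXP gsa, bool prefix_len) {
  XPtr<GsaHandle> xp(gsa);
  GSA& g = *xp->p;
  gsa_build_runs(g);
  const size_t ns = g.run_start.size() - 1;
  NumericVector lo(ns), hi(ns);
  IntegerVector tum(ns), ctl(ns), plen(ns);
  for (size_t r = 0; r < ns; ++r) {
    const uint64_t a = g.run_start[r], b = g.run_start[r + 1];
    lo[r] = (double)a;
    hi[r] = (double)b;
    int t = 0, c = 0;
    for (uint64_t i = a; i < b; ++i)
      (g.corp->origin[g.entries[i].seg] == ORIG_TUMOUR ? t : c)++;
    tum[r] = t;
    ctl[r] = c;
    if (prefix_len) {
      // shared prefix of the whole section = min adjacent LCP over the run;
      // singleton sections share their entire (single) suffix
      size_t len;
      g.suffix(a, &len);
      int pl = (int)len;
      for (uint64_t i = a + 1; i < b; ++i) pl = std::min(pl, gsa_lcp_exact(g, i));
      plen[r] = pl;
    } else {
      plen[r] = NA_INTEGER;
    }
  }
  return DataFrame::create(_["lo"] = lo, _["hi"] = hi,
                           _["tumour_suffixes"] = tum,
                           _["control_suffixes"] = ctl,
                           _["prefix_len"] = plen,
                           _["stringsAsFactors"] = false);
}

// Tumour segments (0-based, sorted, unique) contributing >= 1 suffix to >= 1
// enriched section.  Enrichment: tumour_suffixes >= pmss and
// control_suffixes <= e_cont * section size (tumour-exclusive up to the
// contamination allowance).
// [[Rcpp::export(name = ".gsa_extract_cpp")]]
IntegerVector gsa_extract_cpp(SEXP gsa, double e_cont, int pmss) {
  XPtr<GsaHandle> xp(gsa);
  GSA& g = *xp->p;
  gsa_build_runs(g);
  std::vector<uint8_t> keep(g.corp->n(), 0);
  const size_t ns = g.run_start.size() - 1;
  for (size_t r = 0; r < ns; ++r) {
    const uint64_t a = g.run_start[r], b = g.run_start[r + 1];
    int t = 0, c = 0;
    for (uint64_t i = a; i < b; ++i)
      (g.corp->origin[g.entries[i].seg] == ORIG_TUMOUR ? t : c)++;
    if (t >= pmss && (double)c <= e_cont * (double)(t + c)) {
      for (uint64_t i = a; i < b; ++i) {
        const GsaEntry& e = g.entries[i];
        if (g.corp->origin[e.seg] == ORIG_TUMOUR) keep[e.seg] = 1;
      }
    }
  }
  std::vector<int> out;
  for (size_t i = 0; i < keep.size(); ++i)
    if (keep[i]) out.push_back((int)i);
  return wrap(out);
}

// Same extraction from explicit entry intervals (0-based, half-open).
// [[Rcpp::export(name = ".gsa_extract_sections_cpp")]]
IntegerVector gsa_extract_sections_cpp(SEXP gsa, NumericVector lo,
                                       NumericVector hi) {
  XPtr<GsaHandle> xp(gsa);
  const GSA& g = *xp->p;
  std::vector<uint8_t> keep(g.corp->n(), 0);
  for (R_xlen_t r = 0; r < lo.size(); ++r) {
    for (uint64_t i = (uint64_t)lo[r]; i < (uint64_t)hi[r]; ++i) {
      const GsaEntry& e = g.entries[i];
      if (g.corp->origin[e.seg] == ORIG_TUMOUR) keep[e.seg] = 1;
    }
  }
  std::vector<int> out;
  for (size_t i = 0; i < keep.size(); ++i)
    if (keep[i]) out.push_back((int)i);
  return wrap(out);
}

// ---------------------------------------------------------------------------
// variant blocks from an auxiliary array
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".blocks_build_cpp")]]
SEXP blocks_build_cpp(SEXP aux_gsa, int amss) {
  XPtr<GsaHandle> xp(aux_gsa);
  GSA& g = *xp->p;
  gsa_build_runs(g);
  auto bs = std::make_shared<BlockSet>();
  bs->aux = g.corp;
  bs->ptr.push_back(0);
  const size_t ns = g.run_start.size() - 1;
  for (size_t r = 0; r < ns; ++r) {
    const uint64_t a = g.run_start[r], b = g.run_start[r + 1];
    if (b - a < (uint64_t)amss) continue;
    int anchor = 0;
    for (uint64_t i = a; i < b; ++i)
      anchor = std::max(anchor, (int)g.entry_off(i));
    for (uint64_t i = a; i < b; ++i) {
      bs->mem_seg.push_back(g.entries[i].seg);
      bs->mem_shift.push_back(anchor - (int)g.entry_off(i));
    }
    bs->ptr.push_back(bs->mem_seg.size());
  }
  return XPtr<BlockSetHandle>(new BlockSetHandle{bs}, true);
}

// [[Rcpp::export(name = ".blocks_size_cpp")]]
int blocks_size_cpp(SEXP blocks) {
  XPtr<BlockSetHandle> xp(blocks);
  return (int)xp->p->n();
}

// [[Rcpp::export(name = ".blocks_df_cpp")]]
DataFrame blocks_df_cpp(SEXP blocks) {
  XPtr<BlockSetHandle> xp(blocks);
  const BlockSet& bs = *xp->p;
  const size_t nm = bs.mem_seg.size();
  IntegerVector blk(nm), segid(nm), shift(nm), orient(nm);
  size_t r = 0;
  for (size_t b = 0; b < bs.n(); ++b) {
    for (uint64_t i = bs.ptr[b]; i < bs.ptr[b + 1]; ++i, ++r) {
      blk[r] = (int)b + 1;
      segid[r] = bs.aux->orig_segment[bs.mem_seg[i]] + 1;
      orient[r] = (int)bs.aux->orientation[bs.mem_seg[i]];
      shift[r] = bs.mem_shift[i];
    }
  }
  return DataFrame::create(_["block"] = blk, _["segment_id"] = segid,
                           _["orientation"] = orient, _["shift"] = shift,
                           _["stringsAsFactors"] = false);
}

// Deduplicate blocks whose member multisets of (source segment, orientation)
// are identical; the survivor is the block with the lexicographically
// smallest serialised member list (sorted (segment, orientation, shift)
// triples).  Survivors keep their original relative order.
// [[Rcpp::export(name = ".blocks_dedupe_cpp")]]
SEXP blocks_dedupe_cpp(SEXP blocks) {
  XPtr<BlockSetHandle> xp(blocks);
  const BlockSet& bs = *xp->p;
  const size_t nb = bs.n();

  typedef std::vector<std::array<int64_t, 3>> Ser;
  auto serialise = [&](size_t b, bool with_shift) {
    Ser v;
    for (uint64_t i = bs.ptr[b]; i < bs.ptr[b + 1]; ++i) {
      const uint32_t s = bs.mem_seg[i];
      v.push_back({(int64_t)bs.aux->orig_segment[s],
                   (int64_t)bs.aux->orientation[s],
                   with_shift ? (int64_t)bs.mem_shift[i] : 0});
    }
    std::sort(v.begin(), v.end());
    return v;
  };

  std::unordered_map<uint64_t, std::vector<size_t>> groups;
  std::vector<uint64_t> hashes(nb);
  for (size_t b = 0; b < nb; ++b) {
    Ser key = serialise(b, false);
    uint64_t h = 1469598103934665603ull;
    for (const auto& t : key) {
      const uint64_t x = ((uint64_t)t[0] << 1) | (uint64_t)t[1];
      h ^= x + 0x9e3779b97f4a7c15ull + (h << 6) + (h >> 2);
    }
    hashes[b] = h;
    groups[h].push_back(b);
  }

  std::vector<uint8_t> keep(nb, 0);
  for (auto& kv : groups) {
    auto& idx = kv.second;
    // split hash bucket into true identical-set groups
    std::vector<std::pair<Ser, std::vector<size_t>>> exact;
    for (size_t b : idx) {
      Ser key = serialise(b, false);
      bool found = false;
      for (auto& e : exact)
        if (e.first == key) {
          e.second.push_back(b);
          found = true;
          break;
        }
      if (!found) exact.push_back({std::move(key), {b}});
    }
    for (auto& e : exact) {
      size_t best = e.second[0];
      Ser bser = serialise(best, true);
      for (size_t j = 1; j < e.second.size(); ++j) {
        Ser cand = serialise(e.second[j], true);
        if (cand < bser) {
          best = e.second[j];
          bser = std::move(cand);
        }
      }
      keep[best] = 1;
    }
  }

  auto out = std::make_shared<BlockSet>();
  out->aux = bs.aux;
  out->ptr.push_back(0);
  for (size_t b = 0; b < nb; ++b) {
    if (!keep[b]) continue;
    for (uint64_t i = bs.ptr[b]; i < bs.ptr[b + 1]; ++i) {
      out->mem_seg.push_back(bs.mem_seg[i]);
      out->mem_shift.push_back(bs.mem_shift[i]);
    }
    out->ptr.push_back(out->mem_seg.size());
  }
  return XPtr<BlockSetHandle>(new BlockSetHandle{out}, true);
}
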