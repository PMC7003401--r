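#include "sc_common.h"

using namespace Rcpp;
using namespace sc;

// Does the reference contain a gapless placement of s at which every
// phred-supported column matches?  Unsupported (any-phred fallback) columns
// are ignored: they can never produce a call under the support rule, so a
// block passing this screen cannot yield a somatic SNV.  Seeded from the
// first run of 30 supported columns; returns false (do not screen) when no
// such run exists.
static bool ref_supported_match(const RefIndex& ri, const std::string& s,
                                const std::vector<uint8_t>& sup,
                                std::vector<std::pair<uint32_t, uint32_t>>&
                                    cand) {
  const int n = (int)s.size();
  int seed_q = -1, run = 0;
  for (int i = 0; i < n; ++i) {
    run = sup[i] ? run + 1 : 0;
    if (run >= 30) {
      seed_q = i - 29;
      break;
    }
  }
  if (seed_q < 0) return false;
  ref_key_candidates(ri, s.data() + seed_q, cand);
  for (const auto& cp : cand) {
    const int64_t m = (int64_t)cp.second - seed_q;
    const std::string& chr = ri.seqs[cp.first];
    if (m < 0 || m + n > (int64_t)chr.size()) continue;
    bool ok = true;
    for (int i = 0; i < n; ++i)
      if (sup[i] && chr[m + i] != s[i]) {
        ok = false;
        break;
      }
    if (ok) return true;
  }
  return false;
}

// [[Rcpp::export(name = ".pair_cache_new_cpp")]]
SEXP pair_cache_new_cpp() {
  return XPtr<PairCacheHandle>(
      new PairCacheHandle{std::make_shared<PairCache>()}, true);
}

// Run consensus-pair construction, filtering and SNV calling over a deduped
// block set.  Emits raw per-pair calls (merging happens on the R side) plus
// per-stage counters.
//
// ref_screen: consensus-level extension of the exact-match prefilter — a
// block whose phred-filtered tumour consensus matches the reference at
// every supported column (either strand) cannot yield a somatic call under
// the filter cascade, so recruitment/filtering are skipped for it.
//
// pair_cache: optional memo of pair outcomes keyed by the tumour consensus
// (plus its support and F^t indicator masks, canonicalised over
// orientation).  Everything downstream of the consensus depends only on
// that key and on structures shared between runs, and reverse-complement
// mirror blocks yield identical absolute calls, so outcomes can be reused
// across mirrors and across pMSS settings of one dataset.
// [[Rcpp::export(name = ".process_blocks_cpp")]]
List process_blocks_cpp(SEXP blocks, SEXP primary_gsa, SEXP refindex, int p,
                        double e, int mask_discard, bool ml_use_ft, int max_mm,
                        bool ref_screen, bool require_support, int indel_match,
                        int indel_mismatch, int indel_gap, SEXP pair_cache) {
  XPtr<BlockSetHandle> bxp(blocks);
  const BlockSet& bs = *bxp->p;
  XPtr<GsaHandle> gxp(primary_gsa);
  GSA& g = *gxp->p;
  gsa_build_runs(g);
  const bool have_ref = refindex != R_NilValue;
  std::shared_ptr<RefIndex> ri;
  if (have_ref) {
    XPtr<RefIndexHandle> rxp(refindex);
    ri = rxp->p;
  }
  if (ref_screen && !have_ref)
    stop("reference screening requested without a reference index");
  std::shared_ptr<PairCache> cache;
  if (pair_cache != R_NilValue) {
    XPtr<PairCacheHandle> cxp(pair_cache);
    cache = cxp->p;
  }

  RecruitScratch rs;
  std::vector<RecruitHit> hits;
  std::vector<AlnView> views;
  std::vector<std::pair<uint32_t, uint32_t>> screen_cand;
  Consensus consT, consC;

  // counters
  long n_blocks = (long)bs.n(), screened = 0, no_control = 0, no_overlap = 0,
       indel_discard = 0, ml_discard = 0, unmapped = 0, pairs_kept = 0,
       pairs_with_calls = 0, mask_events_total = 0, cache_hits = 0;

  std::vector<int> call_chrom, call_pair;
  std::vector<double> call_pos;
  std::vector<char> call_ref, call_alt;

  const bool dbg = std::getenv("SARCALL_TIME") != nullptr;
  double ph[6] = {0, 0, 0, 0, 0, 0};
  clock_t tp = clock();
  auto phase = [&](int i) {
    if (!dbg) return;
    const clock_t now = clock();
    ph[i] += (double)(now - tp) / CLOCKS_PER_SEC;
    tp = now;
  };

  // pair construction, filters and calling for one tumour consensus
  // (ftfire[j]: does F^t's column j fire the two-allele indicator?)
  auto process_one = [&](const std::string& T,
                         const std::vector<uint8_t>& ftfire) {
    PairOutcome oc;
    recruit_control_core(g, T, rs, hits);
    phase(2);
    if (hits.empty()) {
      oc.status = 0;
      return oc;
    }
    views.clear();
    for (const auto& h : hits)
      views.push_back({g.corp->seq(h.seg), g.corp->qual(h.seg),
                       (int)g.corp->len(h.seg), h.shift, h.rc != 0});
    consensus_build(views, p, consC);
    phase(3);
    const std::string& C = consC.s;
    const int c_start = consC.start;  // column of C[0] in T's frame

    const int ov_lo = std::max(0, c_start);
    const int ov_hi = std::min((int)T.size(), c_start + (int)C.size());
    if (ov_hi <= ov_lo) {
      oc.status = 1;
      return oc;
    }

    // indel filter (fast path: identical over the overlap => gapless optimum)
    bool mismatch_in_overlap = false;
    for (int j = ov_lo; j < ov_hi; ++j)
      if (T[j] != C[j - c_start]) {
        mismatch_in_overlap = true;
        break;
      }
    if (mismatch_in_overlap) {
      int opt, gl, off;
      if (!indel_gapless_optimal(T, C, indel_match, indel_mismatch,
                                 indel_gap, &opt, &gl, &off)) {
        oc.status = 2;
        return oc;
      }
    }

    // masking filter
    std::string maskedT = T;
    for (int j = ov_lo; j < ov_hi; ++j) {
      if (masking_events_core(consC.counts, e, j - c_start) > 1) {
        maskedT[j] = C[j - c_start];
        oc.mask_events++;
      }
    }

    // multi-locus filter: distinct pair-frame columns fired by F^c or F^t
    long ml_events = 0;
    const int lo = std::min(0, c_start);
    const int hi = std::max((int)T.size(), c_start + (int)C.size());
    for (int j = lo; j < hi; ++j) {
      bool fire = ml_use_ft && j >= 0 && j < (int)T.size() && ftfire[j];
      const int cj = j - c_start;
      if (!fire && cj >= 0 && cj < (int)C.size())
        fire = masking_events_core(consC.counts, e, cj) > 1;
      if (fire) ml_events++;
    }
    if (ml_events >= mask_discard) {
      oc.status = 3;
      return oc;
    }

    // candidate SNV columns after masking
    std::vector<int> mm_cols;
    for (int j = ov_lo; j < ov_hi; ++j) {
      if (maskedT[j] == C[j - c_start]) continue;
      if (require_support &&
          (!consT.support[j] || !consC.support[j - c_start]))
        continue;
      mm_cols.push_back(j);
    }
    phase(4);
    if (mm_cols.empty()) {
      oc.status = 5;
      return oc;
    }
    if (!have_ref) {
      oc.status = 6;  // detected, but no coordinates without a reference
      return oc;
    }

    // map the control consensus and convert columns to reference coordinates
    std::vector<std::pair<uint32_t, int64_t>> cand_p, cand_m;
    ref_seed_candidates(*ri, C, 1, cand_p);
    const std::string Crc = revcomp(C);
    ref_seed_candidates(*ri, Crc, 1, cand_m);
    int best_mm = max_mm + 1, n_best = 0, bstrand = 0;
    uint32_t bc = 0;
    int64_t bm = 0;
    const int cn = (int)C.size();
    auto consider = [&](const std::string& q, uint32_t c, int64_t m,
                        int strand) {
      const char* r = ri->seqs[c].data() + m;
      int mm = 0;
      for (int i = 0; i < cn; ++i)
        if (q[i] != r[i] && ++mm > best_mm) break;
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
    if (best_mm > max_mm || n_best != 1) {
      oc.status = 4;
      return oc;
    }

    oc.status = 6;
    for (int j : mm_cols) {
      const int i = j - c_start;  // index in C's frame
      if (bstrand == 0) {
        oc.call_pos.push_back((double)(bm + i));
        oc.call_ref.push_back(C[i]);
        oc.call_alt.push_back(maskedT[j]);
      } else {
        oc.call_pos.push_back((double)(bm + (cn - 1 - i)));
        oc.call_ref.push_back(comp_base(C[i]));
        oc.call_alt.push_back(comp_base(maskedT[j]));
      }
      oc.call_chrom.push_back((int)bc + 1);
    }
    phase(5);
    return oc;
  };

  auto apply_outcome = [&](const PairOutcome& oc, size_t b) {
    switch (oc.status) {
      case 0: no_control++; break;
      case 1: no_overlap++; break;
      case 2: indel_discard++; break;
      case 3: ml_discard++; break;
      case 4:
        pairs_kept++;
        unmapped++;
        pairs_with_calls++;
        mask_events_total += oc.mask_events;
        break;
      case 5:
        pairs_kept++;
        mask_events_total += oc.mask_events;
        break;
      case 6:
        pairs_kept++;
        pairs_with_calls++;
        mask_events_total += oc.mask_events;
        for (size_t i = 0; i < oc.call_pos.size(); ++i) {
          call_chrom.push_back(oc.call_chrom[i]);
          call_pos.push_back(oc.call_pos[i]);
          call_ref.push_back(oc.call_ref[i]);
          call_alt.push_back(oc.call_alt[i]);
          call_pair.push_back((int)b + 1);
        }
        break;
    }
  };

  for (size_t b = 0; b < bs.n(); ++b) {
    if ((b & 0x3ff) == 0) Rcpp::checkUserInterrupt();
    if (dbg) tp = clock();
    // tumour consensus from the block alignment
    views.clear();
    for (uint64_t i = bs.ptr[b]; i < bs.ptr[b + 1]; ++i) {
      const uint32_t s = bs.mem_seg[i];
      views.push_back({bs.aux->seq(s), bs.aux->qual(s),
                       (int)bs.aux->len(s), bs.mem_shift[i]});
    }
    consensus_build(views, p, consT);
    phase(0);
    const std::string& T = consT.s;
    const int Tn = (int)T.size();
    if (Tn < 30) {
      no_control++;  // cannot recruit: treated as having no control evidence
      continue;
    }
    const std::string Trc = revcomp(T);

    if (ref_screen) {
      bool hit = ref_supported_match(*ri, T, consT.support, screen_cand);
      if (!hit) {
        std::vector<uint8_t> sup_rc(consT.support.rbegin(),
                                    consT.support.rend());
        hit = ref_supported_match(*ri, Trc, sup_rc, screen_cand);
      }
      phase(1);
      if (hit) {
        screened++;
        continue;
      }
    }

    // F^t two-allele indicator per column (input to the multi-locus filter
    // and part of the memo key)
    std::vector<uint8_t> ftfire(Tn);
    for (int j = 0; j < Tn; ++j)
      ftfire[j] = masking_events_core(consT.counts, e, j) > 1;

    std::string key;
    if (cache) {
      // canonical over orientation: min of the forward and the mirrored
      // serialisation of (T, support mask, F^t indicator mask)
      std::string fwd, rev;
      fwd.reserve(3 * Tn);
      rev.reserve(3 * Tn);
      for (int j = 0; j < Tn; ++j) {
        fwd.push_back(T[j]);
        fwd.push_back((char)('0' + consT.support[j]));
        fwd.push_back((char)('0' + ftfire[j]));
      }
      for (int j = 0; j < Tn; ++j) {
        rev.push_back(Trc[j]);
        rev.push_back((char)('0' + consT.support[Tn - 1 - j]));
        rev.push_back((char)('0' + ftfire[Tn - 1 - j]));
      }
      key = fwd < rev ? std::move(fwd) : std::move(rev);
      auto it = cache->map.find(key);
      if (it != cache->map.end()) {
        cache_hits++;
        apply_outcome(it->second, b);
        continue;
      }
    }

    PairOutcome oc = process_one(T, ftfire);
    if (cache) cache->map.emplace(std::move(key), oc);
    apply_outcome(oc, b);
  }
  if (dbg)
    Rprintf("[blocks] consT %.1f screen %.1f recruit %.1f consC %.1f "
            "filters %.1f map+call %.1f | cache hits %ld\n",
            ph[0], ph[1], ph[2], ph[3], ph[4], ph[5], cache_hits);

  const size_t nc = call_pos.size();
  CharacterVector refv(nc), altv(nc);
  for (size_t i = 0; i < nc; ++i) {
    refv[i] = std::string(1, call_ref[i]);
    altv[i] = std::string(1, call_alt[i]);
  }
  DataFrame calls = DataFrame::create(
      _["chrom_idx"] = wrap(call_chrom), _["pos"] = wrap(call_pos),
      _["ref"] = refv, _["alt"] = altv, _["pair"] = wrap(call_pair),
      _["stringsAsFactors"] = false);
  List stats = List::create(
      _["blocks"] = (double)n_blocks, _["screened_reference"] = (double)screened,
      _["no_control"] = (double)no_control, _["no_overlap"] = (double)no_overlap,
      _["indel_discarded"] = (double)indel_discard,
      _["multi_locus_discarded"] = (double)ml_discard,
      _["unmapped"] = (double)unmapped, _["pairs_kept"] = (double)pairs_kept,
      _["pairs_with_calls"] = (double)pairs_with_calls,
      _["masking_events"] = (double)mask_events_total,
      _["cache_hits"] = (double)cache_hits);
  return List::create(_["calls"] = calls, _["stats"] = stats);
}
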