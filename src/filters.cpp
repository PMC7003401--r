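#include "sc_common.h"

using namespace Rcpp;
using namespace sc;

namespace sc {

// Overlap (free-end-gap) global alignment of T against C versus the best
// purely gapless superposition.  The pair passes the indel filter iff some
// gapless alignment attains the optimal overlap-alignment score, i.e. the
// optimum does not require an internal gap.
bool indel_gapless_optimal(const std::string& T, const std::string& C,
                           int match, int mismatch, int gap, int* opt_score,
                           int* gapless_score, int* gapless_offset) {
  const int n = (int)T.size(), m = (int)C.size();
  // best gapless score over all relative offsets d of T against C
  int best_g = 0, best_d = 0;  // empty overlap scores 0 (all end gaps, free)
  for (int d = -(m - 1); d <= n - 1; ++d) {
    // T[i] pairs with C[i - d]
    const int i0 = std::max(0, d), i1 = std::min(n, m + d);
    int s = 0;
    for (int i = i0; i < i1; ++i)
      s += (T[i] == C[i - d]) ? match : mismatch;
    if (s > best_g) {
      best_g = s;
      best_d = d;
    }
  }
  // free-end-gap DP
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int opt = 0;  // empty alignment feasible via end gaps
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;  // leading gaps in C are free
    for (int j = 1; j <= m; ++j) {
      const int diag = prev[j - 1] + (T[i - 1] == C[j - 1] ? match : mismatch);
      const int up = prev[j] + gap;
      const int left = cur[j - 1] + gap;
      cur[j] = std::max(diag, std::max(up, left));
    }
    opt = std::max(opt, cur[m]);  // trailing gaps in C are free
    std::swap(prev, cur);
  }
  for (int j = 0; j <= m; ++j) opt = std::max(opt, prev[j]);
  *opt_score = opt;
  *gapless_score = best_g;
  *gapless_offset = best_d;
  return opt <= best_g;
}

// number of bases in frequency-matrix column j whose ratio strictly exceeds e
int masking_events_core(const std::vector<std::array<int, 4>>& f, double e,
                        size_t j) {
  const auto& c = f[j];
  const double tot = c[0] + c[1] + c[2] + c[3];
  if (tot <= 0) return 0;
  int k = 0;
  for (int b = 0; b < 4; ++b)
    if ((double)c[b] / tot > e) ++k;
  return k;
}

}  // namespace sc

static std::vector<std::array<int, 4>> matrix_to_cols(
    const IntegerMatrix& m) {
  if (m.nrow() != 4) stop("frequency matrix must have 4 rows (A,C,G,T)");
  std::vector<std::array<int, 4>> out(m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int b = 0; b < 4; ++b) out[j][b] = m(b, j);
  return out;
}

// [[Rcpp::export(name = ".indel_filter_cpp")]]
List indel_filter_cpp(std::string T, std::string C, int match, int mismatch,
                      int gap) {
  int opt, gl, off;
  const bool keep = indel_gapless_optimal(T, C, match, mismatch, gap, &opt,
                                          &gl, &off);
  return List::create(_["keep"] = keep, _["opt_score"] = opt,
                      _["gapless_score"] = gl, _["gapless_offset"] = off);
}

// Mask T with C at columns where >= 2 bases of F^c carry ratio > e.
// c_start: column of C[0] (and of F^c column 1) in T's frame.
// [[Rcpp::export(name = ".masking_filter_cpp")]]
List masking_filter_cpp(std::string T, std::string C, int c_start,
                        IntegerMatrix fc, double e) {
  const auto cols = matrix_to_cols(fc);
  if ((int)cols.size() != (int)C.size())
    stop("F^c width must equal the control consensus length");
  std::string masked = T;
  std::vector<int> events;
  for (int j = 0; j < (int)T.size(); ++j) {
    const int cj = j - c_start;
    if (cj < 0 || cj >= (int)C.size()) continue;
    if (masking_events_core(cols, e, cj) > 1) {
      masked[j] = C[cj];
      events.push_back(j + 1);  // 1-based for the R side
    }
  }
  return List::create(_["masked"] = masked, _["events"] = wrap(events));
}

// Distinct pair-frame columns at which F^t (optionally) or F^c fire the
// masking indicator; columns are in T's frame, F^c shifted by c_start.
// [[Rcpp::export(name = ".multi_locus_events_cpp")]]
IntegerVector multi_locus_events_cpp(IntegerMatrix ft, IntegerMatrix fc,
                                     int c_start, double e, bool use_ft) {
  const auto tcols = matrix_to_cols(ft);
  const auto ccols = matrix_to_cols(fc);
  std::vector<int> ev;
  const int lo = std::min(0, c_start);
  const int hi = std::max((int)tcols.size(), c_start + (int)ccols.size());
  for (int j = lo; j < hi; ++j) {
    bool fire = false;
    if (use_ft && j >= 0 && j < (int)tcols.size())
      fire = masking_events_core(tcols, e, j) > 1;
    const int cj = j - c_start;
    if (!fire && cj >= 0 && cj < (int)ccols.size())
      fire = masking_events_core(ccols, e, cj) > 1;
    if (fire) ev.push_back(j + 1);
  }
  return wrap(ev);
}
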