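#include "sc_common.h"

using namespace Rcpp;
using namespace sc;

// Random reference with a target GC fraction.  All randomness in the
// simulator flows through a fixed Mersenne-Twister stream with hand-rolled
// draws, so output is byte-identical across platforms and toolchains.
// [[Rcpp::export(name = ".make_reference_cpp")]]
std::string make_reference_cpp(double length, double gc, double seed) {
  const size_t n = (size_t)length;
  RNG rng((uint64_t)seed);
  std::string s(n, 'A');
  for (size_t i = 0; i < n; ++i) {
    if (rng.bern(gc))
      s[i] = rng.bern(0.5) ? 'G' : 'C';
    else
      s[i] = rng.bern(0.5) ? 'A' : 'T';
  }
  return s;
}

// Single-end read sampling from one haplotype pool.
//
// Per read, in fixed draw order: start position, strand, one somatic
// haplotype draw (tumour only, probability = shared allele frequency of the
// overlapped somatic sites), per-overlapped-heterozygous-SNP allele draws,
// then per-base sequencing errors.  Errors substitute the base and receive
// phred_low unless the (usually zero) high-quality-error fraction fires.
// [[Rcpp::export(name = ".sim_reads_cpp")]]
List sim_reads_cpp(std::string ref, IntegerVector som_pos,
                   CharacterVector som_alt, NumericVector som_af,
                   IntegerVector germ_pos, CharacterVector germ_alt,
                   LogicalVector germ_het, double n_reads, int read_len,
                   double error_rate, int phred_high, int phred_low,
                   double hq_error_frac, bool somatic, double seed) {
  const int64_t L = (int64_t)ref.size();
  if (read_len > L) stop("read length exceeds reference length");
  const int64_t N = (int64_t)n_reads;
  RNG rng((uint64_t)seed);

  std::vector<int> spos(som_pos.begin(), som_pos.end());
  std::vector<int> gpos(germ_pos.begin(), germ_pos.end());
  std::vector<char> salt(spos.size()), galt(gpos.size());
  for (size_t i = 0; i < spos.size(); ++i)
    salt[i] = CHAR(STRING_ELT(som_alt, i))[0];
  for (size_t i = 0; i < gpos.size(); ++i)
    galt[i] = CHAR(STRING_ELT(germ_alt, i))[0];

  CharacterVector oseq(N), oqual(N);
  NumericVector ostart(N);
  IntegerVector ostrand(N);
  std::string buf(read_len, 'A'), qbuf(read_len, '!');
  const char qh = (char)(33 + phred_high), ql = (char)(33 + phred_low);

  for (int64_t r = 0; r < N; ++r) {
    const int64_t start = (int64_t)rng.below((uint64_t)(L - read_len + 1));
    const bool minus = rng.bern(0.5);
    std::memcpy(&buf[0], ref.data() + start, read_len);

    if (somatic && !spos.empty()) {
      // overlapped somatic sites; one haplotype draw per read (cluster
      // members share an allele frequency by construction)
      auto lo = std::lower_bound(spos.begin(), spos.end(), (int)start);
      auto hi = std::lower_bound(spos.begin(), spos.end(),
                                 (int)(start + read_len));
      if (lo != hi) {
        const size_t i0 = lo - spos.begin();
        if (rng.bern(som_af[i0])) {
          for (auto it = lo; it != hi; ++it)
            buf[*it - start] = salt[it - spos.begin()];
        }
      }
    }
    if (!gpos.empty()) {
      auto lo = std::lower_bound(gpos.begin(), gpos.end(), (int)start);
      auto hi = std::lower_bound(gpos.begin(), gpos.end(),
                                 (int)(start + read_len));
      for (auto it = lo; it != hi; ++it) {
        const size_t i = it - gpos.begin();
        if (!germ_het[i] || rng.bern(0.5)) buf[*it - start] = galt[i];
      }
    }
    for (int j = 0; j < read_len; ++j) {
      if (rng.bern(error_rate)) {
        const int b = base_code(buf[j]);
        buf[j] = code_base((b + 1 + (int)rng.below(3)) & 3);
        qbuf[j] = rng.bern(hq_error_frac) ? qh : ql;
      } else {
        qbuf[j] = qh;
      }
    }
    if (minus) {
      std::string rc = revcomp(buf);
      std::string rq(qbuf.rbegin(), qbuf.rend());
      oseq[r] = rc;
      oqual[r] = rq;
    } else {
      oseq[r] = buf;
      oqual[r] = qbuf;
    }
    ostart[r] = (double)start;
    ostrand[r] = minus ? 1 : 0;
  }
  return List::create(_["sequence"] = oseq, _["qual"] = oqual,
                      _["start"] = ostart, _["strand"] = ostrand);
}
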