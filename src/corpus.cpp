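#include "sc_common.h"

using namespace Rcpp;
using namespace sc;

// Convert ASCII (phred+33) quality strings to raw scores in place.
static std::string ascii_to_raw(const char* q, size_t n) {
  std::string out(n, '\0');
  for (size_t i = 0; i < n; ++i) out[i] = (char)(q[i] - 33);
  return out;
}

// [[Rcpp::export(name = ".corpus_build_cpp")]]
SEXP corpus_build_cpp(CharacterVector seq, CharacterVector qual,
                      IntegerVector origin) {
  auto corp = std::make_shared<Corpus>();
  const size_t n = seq.size();
  if ((size_t)qual.size() != n || (size_t)origin.size() != n)
    stop("sequence, quality and origin must have equal length");
  size_t total = 0;
  for (size_t i = 0; i < n; ++i) total += Rf_xlength(STRING_ELT(seq, i));
  corp->text.reserve(total);
  corp->phred.reserve(total);
  corp->start.reserve(n + 1);
  corp->origin.reserve(n);
  corp->orig_segment.reserve(n);
  corp->orientation.reserve(n);
  for (size_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seq, i));
    const char* q = CHAR(STRING_ELT(qual, i));
    const size_t ls = std::strlen(s);
    if (std::strlen(q) != ls)
      stop("phred string length differs from sequence length at segment %d",
           (int)i + 1);
    for (size_t j = 0; j < ls; ++j)
      if (base_code(s[j]) < 0)
        stop("segment %d contains a non-ACGT character", (int)i + 1);
    const std::string raw = ascii_to_raw(q, ls);
    corp->append(s, raw.data(), ls, (uint8_t)origin[i], (int)i, 0);
  }
  XPtr<CorpusHandle> xp(new CorpusHandle{corp}, true);
  return xp;
}

// Fused N-splitting + corpus construction for the pipeline: avoids
// materialising every segment as an R string.  Reads are split at non-ACGT
// characters; N-free pieces of length >= min_len are appended, tumour
// sample first.
// [[Rcpp::export(name = ".corpus_build_split_cpp")]]
List corpus_build_split_cpp(CharacterVector tseq, CharacterVector tqual,
                            CharacterVector cseq, CharacterVector cqual,
                            int min_len) {
  auto corp = std::make_shared<Corpus>();
  size_t total = 0;
  for (R_xlen_t i = 0; i < tseq.size(); ++i)
    total += Rf_xlength(STRING_ELT(tseq, i));
  for (R_xlen_t i = 0; i < cseq.size(); ++i)
    total += Rf_xlength(STRING_ELT(cseq, i));
  corp->text.reserve(total);
  corp->phred.reserve(total);
  std::string raw;
  int counts[2] = {0, 0};
  auto add_sample = [&](const CharacterVector& seq,
                        const CharacterVector& qual, uint8_t origin) {
    if (seq.size() != qual.size())
      stop("sequence and quality vectors differ in length");
    for (R_xlen_t i = 0; i < seq.size(); ++i) {
      const char* s = CHAR(STRING_ELT(seq, i));
      const char* q = CHAR(STRING_ELT(qual, i));
      const size_t ls = std::strlen(s);
      if (std::strlen(q) != ls)
        stop("phred string length differs from sequence length at read %d",
             (int)i + 1);
      size_t start = 0;
      for (size_t j = 0; j <= ls; ++j) {
        const bool brk = (j == ls) || (base_code(s[j]) < 0);
        if (brk) {
          if (j - start >= (size_t)min_len) {
            raw.assign(q + start, j - start);
            for (auto& c : raw) c = (char)(c - 33);
            corp->append(s + start, raw.data(), j - start, origin,
                         (int)corp->n(), 0);
            counts[origin]++;
          }
          start = j + 1;
        }
      }
    }
  };
  add_sample(tseq, tqual, ORIG_TUMOUR);
  add_sample(cseq, cqual, ORIG_CONTROL);
  return List::create(
      _["corpus"] = XPtr<CorpusHandle>(new CorpusHandle{corp}, true),
      _["tumour_segments"] = counts[0],
      _["control_segments"] = counts[1]);
}

// [[Rcpp::export(name = ".corpus_size_cpp")]]
int corpus_size_cpp(SEXP corpus) {
  XPtr<CorpusHandle> xp(corpus);
  return (int)xp->p->n();
}

// Split reads at 'N' characters, keeping maximal N-free substrings of length
// >= min_len with phred sliced in step.  Returns parallel vectors plus the
// 1-based source read index and the part number within the read.
// [[Rcpp::export(name = ".split_on_n_cpp")]]
List split_on_n_cpp(CharacterVector seq, CharacterVector qual, int min_len) {
  std::vector<std::string> oseq, oqual;
  std::vector<int> osrc, opart;
  for (R_xlen_t i = 0; i < seq.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seq, i));
    const char* q = CHAR(STRING_ELT(qual, i));
    const size_t ls = std::strlen(s);
    if (std::strlen(q) != ls)
      stop("phred string length differs from sequence length at read %d",
           (int)i + 1);
    size_t start = 0;
    int part = 0;
    for (size_t j = 0; j <= ls; ++j) {
      const bool brk = (j == ls) || (base_code(s[j]) < 0);
      if (brk) {
        if (j - start >= (size_t)min_len) {
          ++part;
          oseq.emplace_back(s + start, j - start);
          oqual.emplace_back(q + start, j - start);
          osrc.push_back((int)i + 1);
          opart.push_back(part);
        }
        start = j + 1;
      }
    }
  }
  return List::create(_["sequence"] = wrap(oseq), _["qual"] = wrap(oqual),
                      _["source"] = wrap(osrc), _["part"] = wrap(opart));
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seq) {
  CharacterVector out(seq.size());
  for (R_xlen_t i = 0; i < seq.size(); ++i) {
    std::string s = as<std::string>(seq[i]);
    out[i] = revcomp(s);
  }
  return out;
}
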