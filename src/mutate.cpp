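#include <Rcpp.h>
#include "sequtil.h"

using namespace Rcpp;

// Per-base substitution through R's RNG stream (reproducible via set.seed).
// Each A/C/G/T base is replaced, with probability `rate`, by one of the
// other three bases chosen uniformly; non-ACGT characters are untouched and
// consume no random draws.
// [[Rcpp::export]]
CharacterVector mutate_bases_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    buf = targetasm::to_upper(CHAR(STRING_ELT(seqs, i)));
    for (auto& c : buf) {
      if (!targetasm::is_acgt(c)) continue;
      if (unif_rand() >= rate) continue;
      int off = static_cast<int>(unif_rand() * 3.0);
      if (off > 2) off = 2;
      int b = 0;
      for (int j = 0; j < 4; ++j) {
        if (bases[j] == c) continue;
        if (b == off) {
          c = bases[j];
          break;
        }
        ++b;
      }
    }
    out[i] = buf;
  }
  return out;
}

// Uniform random A/C/G/T strings of the given lengths (R RNG stream).
// [[Rcpp::export]]
CharacterVector random_dna_cpp(IntegerVector lengths) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(lengths.size());
  std::string buf;
  for (R_xlen_t i = 0; i < lengths.size(); ++i) {
    buf.assign(lengths[i], 'A');
    for (int j = 0; j < lengths[i]; ++j) {
      int b = static_cast<int>(unif_rand() * 4.0);
      if (b > 3) b = 3;
      buf[j] = bases[b];
    }
    out[i] = buf;
  }
  return out;
}
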