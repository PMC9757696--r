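#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include "sequtil.h"

using namespace Rcpp;
using targetasm::last_bad_index;
using targetasm::revcomp;
using targetasm::to_upper;

// Count every N-free length-k window over the reads and their reverse
// complements (graph carries both orientations; counts pooled per distinct
// k-mer string). Returned sorted lexicographically for determinism.
// [[Rcpp::export]]
DataFrame dbg_count_kmers_cpp(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> counts;
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const std::string fwd = to_upper(CHAR(STRING_ELT(seqs, i)));
    const std::string rev = revcomp(fwd);
    for (const std::string* sp : {&fwd, &rev}) {
      const std::string& s = *sp;
      const long L = static_cast<long>(s.size());
      if (L < k) continue;
      const std::vector<long> lb = last_bad_index(s);
      for (long st = 0; st + k <= L; ++st) {
        if (lb[st + k - 1] >= st) continue;
        buf.assign(s, st, k);
        counts[buf] += 1;
      }
    }
  }
  std::vector<const std::string*> keys;
  keys.reserve(counts.size());
  for (const auto& kv : counts) keys.push_back(&kv.first);
  std::sort(keys.begin(), keys.end(),
            [](const std::string* a, const std::string* b) { return *a < *b; });
  CharacterVector kmer(keys.size());
  IntegerVector count(keys.size());
  for (std::size_t i = 0; i < keys.size(); ++i) {
    kmer[i] = *keys[i];
    count[i] = counts.at(*keys[i]);
  }
  return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                           _["stringsAsFactors"] = false);
}

// Greedy walk on the implicit de Bruijn graph under a visit-once constraint.
// Candidate successors (right) share a (k-1)-suffix/prefix overlap with the
// current node; each unvisited candidate is scored
//   W = count ^ (1 - pos_delta),
// pos_delta = |ref_pos[cand] - ref_pos[cur]| when both carry a reference
// position, else 1. Best weight wins; weight ties fall back to higher count,
// then to the lexicographically smaller k-mer, so the walk is deterministic.
// `seed` and `visited_init` are 1-based node indices; the returned path is
// 1-based and starts at the seed.
// [[Rcpp::export]]
IntegerVector dbg_extend_cpp(CharacterVector kmers, IntegerVector counts,
                             NumericVector ref_pos, int seed, bool forward,
                             IntegerVector visited_init) {
  const R_xlen_t n = kmers.size();
  std::unordered_map<std::string, int> node_of;
  node_of.reserve(n * 2);
  std::vector<std::string> keys(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    keys[i] = std::string(CHAR(STRING_ELT(kmers, i)));
    node_of[keys[i]] = static_cast<int>(i);
  }
  const int k = keys.empty() ? 0 : static_cast<int>(keys[0].size());

  std::vector<bool> visited(n, false);
  for (R_xlen_t i = 0; i < visited_init.size(); ++i)
    visited[visited_init[i] - 1] = true;

  int cur = seed - 1;
  visited[cur] = true;
  std::vector<int> path;
  path.push_back(cur);

  const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string cand;
  while (true) {
    const std::string& ck = keys[cur];
    const double cur_pos = ref_pos[cur];
    int best = -1;
    double best_w = -1.0;
    for (char b : bases) {
      if (forward) {
        cand.assign(ck, 1, k - 1);
        cand.push_back(b);
      } else {
        cand.assign(1, b);
        cand.append(ck, 0, k - 1);
      }
      auto it = node_of.find(cand);
      if (it == node_of.end() || visited[it->second]) continue;
      const int idx = it->second;
      double pos_delta = 1.0;
      if (!ISNAN(cur_pos) && !ISNAN(ref_pos[idx]))
        pos_delta = std::fabs(ref_pos[idx] - cur_pos);
      const double w = std::pow(static_cast<double>(counts[idx]),
                                1.0 - pos_delta);
      const bool better =
          best < 0 || w > best_w ||
          (w == best_w && (counts[idx] > counts[best] ||
                           (counts[idx] == counts[best] &&
                            keys[idx] < keys[best])));
      if (better) {
        best = idx;
        best_w = w;
      }
    }
    if (best < 0) break;
    visited[best] = true;
    path.push_back(best);
    cur = best;
  }
  IntegerVector out(path.size());
  for (std::size_t i = 0; i < path.size(); ++i) out[i] = path[i] + 1;
  return out;
}
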