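#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include "sequtil.h"

using namespace Rcpp;
using targetasm::last_bad_index;
using targetasm::revcomp;
using targetasm::to_upper;

// Reference k-mer hash table. One entry per (k-mer, gene): occurrence count
// and the running sum of fractional start positions start/(L-k) (0 when L==k),
// from which the mean fractional position is derived. Forward strand only:
// positional statistics stay in reference orientation.
struct KEntry {
  int gene;
  int count;
  double sum_frac;
};

struct KIndex {
  int k;
  std::vector<std::string> genes;
  std::unordered_map<std::string, std::vector<KEntry>> table;
};

// [[Rcpp::export]]
SEXP kmer_index_build_cpp(CharacterVector seqs, IntegerVector gene_of_seq,
                          CharacterVector gene_ids, int k) {
  KIndex* idx = new KIndex();
  idx->k = k;
  idx->genes.reserve(gene_ids.size());
  for (R_xlen_t g = 0; g < gene_ids.size(); ++g)
    idx->genes.push_back(std::string(gene_ids[g]));

  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const std::string s = to_upper(CHAR(STRING_ELT(seqs, i)));
    const long L = static_cast<long>(s.size());
    if (L < k) continue;
    const int gene = gene_of_seq[i]; // 0-based
    const std::vector<long> lb = last_bad_index(s);
    const long denom = L - k; // fractional position denominator; 0 when L==k
    for (long st = 0; st + k <= L; ++st) {
      if (lb[st + k - 1] >= st) continue; // window contains non-ACGT
      buf.assign(s, st, k);
      const double frac = denom == 0 ? 0.0 : static_cast<double>(st) / denom;
      auto& vec = idx->table[buf];
      bool found = false;
      for (auto& e : vec) {
        if (e.gene == gene) {
          e.count += 1;
          e.sum_frac += frac;
          found = true;
          break;
        }
      }
      if (!found) vec.push_back(KEntry{gene, 1, frac});
    }
  }
  XPtr<KIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int kmer_index_k_cpp(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  return xp->k;
}

// [[Rcpp::export]]
double kmer_index_size_cpp(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  return static_cast<double>(xp->table.size());
}

// Full (k-mer, gene) table, sorted by k-mer then gene index. Intended for
// small indices (inspection and testing); the pipeline queries in C++.
// [[Rcpp::export]]
DataFrame kmer_index_dump_cpp(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  std::vector<const std::string*> keys;
  keys.reserve(xp->table.size());
  for (const auto& kv : xp->table) keys.push_back(&kv.first);
  std::sort(keys.begin(), keys.end(),
            [](const std::string* a, const std::string* b) { return *a < *b; });
  std::vector<std::string> kmer;
  std::vector<std::string> gene;
  std::vector<int> count;
  std::vector<double> mean_frac;
  for (const auto* key : keys) {
    std::vector<KEntry> entries = xp->table.at(*key);
    std::sort(entries.begin(), entries.end(),
              [](const KEntry& a, const KEntry& b) { return a.gene < b.gene; });
    for (const auto& e : entries) {
      kmer.push_back(*key);
      gene.push_back(xp->genes[e.gene]);
      count.push_back(e.count);
      mean_frac.push_back(e.sum_frac / e.count);
    }
  }
  return DataFrame::create(_["kmer"] = kmer, _["gene_id"] = gene,
                           _["count"] = count, _["mean_frac_pos"] = mean_frac,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame kmer_index_lookup_cpp(SEXP xp_, CharacterVector kmers) {
  XPtr<KIndex> xp(xp_);
  std::vector<std::string> kmer;
  std::vector<std::string> gene;
  std::vector<int> count;
  std::vector<double> mean_frac;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const std::string q = to_upper(CHAR(STRING_ELT(kmers, i)));
    auto it = xp->table.find(q);
    if (it == xp->table.end()) continue;
    std::vector<KEntry> entries = it->second;
    std::sort(entries.begin(), entries.end(),
              [](const KEntry& a, const KEntry& b) { return a.gene < b.gene; });
    for (const auto& e : entries) {
      kmer.push_back(q);
      gene.push_back(xp->genes[e.gene]);
      count.push_back(e.count);
      mean_frac.push_back(e.sum_frac / e.count);
    }
  }
  return DataFrame::create(_["kmer"] = kmer, _["gene_id"] = gene,
                           _["count"] = count, _["mean_frac_pos"] = mean_frac,
                           _["stringsAsFactors"] = false);
}

// Mean fractional reference position of each query k-mer, pooled over all
// genes in the index (occurrence-weighted); NA when absent. Used to annotate
// assembly-graph nodes from a single-gene index.
// [[Rcpp::export]]
NumericVector kmer_index_meanpos_cpp(SEXP xp_, CharacterVector kmers) {
  XPtr<KIndex> xp(xp_);
  NumericVector out(kmers.size(), NA_REAL);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const std::string q = to_upper(CHAR(STRING_ELT(kmers, i)));
    auto it = xp->table.find(q);
    if (it == xp->table.end()) continue;
    double sum = 0.0;
    long n = 0;
    for (const auto& e : it->second) {
      sum += e.sum_frac;
      n += e.count;
    }
    out[i] = sum / n;
  }
  return out;
}

// Classify reads against the index: a gene matches when the number of stride-
// sampled k-mers of the read plus those of its reverse complement found in
// the hash table for that gene reaches min_hits. Exact matching only.
// Returns, per read, the 1-based indices of matching genes (ascending).
// [[Rcpp::export]]
List classify_reads_cpp(SEXP xp_, CharacterVector seqs, int step,
                        int min_hits) {
  XPtr<KIndex> xp(xp_);
  const int k = xp->k;
  const int G = static_cast<int>(xp->genes.size());
  std::vector<int> hits(G, 0);
  std::vector<int> touched;
  std::string buf;

  List out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const std::string fwd = to_upper(CHAR(STRING_ELT(seqs, i)));
    const std::string rev = revcomp(fwd);
    for (const std::string* sp : {&fwd, &rev}) {
      const std::string& s = *sp;
      const long L = static_cast<long>(s.size());
      if (L < k) continue;
      const std::vector<long> lb = last_bad_index(s);
      for (long st = 0; st + k <= L; st += step) {
        if (lb[st + k - 1] >= st) continue;
        buf.assign(s, st, k);
        auto it = xp->table.find(buf);
        if (it == xp->table.end()) continue;
        for (const auto& e : it->second) {
          if (hits[e.gene] == 0) touched.push_back(e.gene);
          hits[e.gene] += 1;
        }
      }
    }
    std::vector<int> matched;
    for (int g : touched) {
      if (hits[g] >= min_hits) matched.push_back(g + 1);
      hits[g] = 0;
    }
    touched.clear();
    std::sort(matched.begin(), matched.end());
    out[i] = IntegerVector(matched.begin(), matched.end());
  }
  return out;
}

// Stride-k-merization of one sequence; windows containing non-ACGT are
// dropped; empty result when the sequence is shorter than k.
// [[Rcpp::export]]
CharacterVector kmerize_cpp(std::string seq, int k, int step) {
  for (auto& c : seq) c = targetasm::upbase(c);
  const long L = static_cast<long>(seq.size());
  std::vector<std::string> out;
  if (L >= k) {
    const std::vector<long> lb = last_bad_index(seq);
    for (long st = 0; st + k <= L; st += step) {
      if (lb[st + k - 1] >= st) continue;
      out.push_back(seq.substr(st, k));
    }
  }
  return CharacterVector(out.begin(), out.end());
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(to_upper(CHAR(STRING_ELT(seqs, i))));
  return out;
}
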