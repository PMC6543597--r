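#include <Rcpp.h>
#include <unordered_map>
#include <string>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  out.names() = seqs.names();
  return out;
}

// Count k-mers over a set of reads. Canonical mode stores the
// lexicographic minimum of a motif and its reverse complement; motifs
// containing non-ACGT characters are skipped entirely.
// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector reads, int k, bool canonical) {
  std::unordered_map<std::string, double> counts;
  double total = 0.0;
  std::string kmer, rc;
  kmer.reserve(k); rc.reserve(k);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    int n = (int)s.size();
    if (n < k) continue;
    // prev_bad[j]: index of the most recent non-ACGT char at or before j
    std::vector<int> prev_bad(n);
    int lb = -1;
    for (int i = 0; i < n; ++i) { if (!valid_base(s[i])) lb = i; prev_bad[i] = lb; }
    for (int i = 0; i + k <= n; ++i) {
      if (prev_bad[i + k - 1] >= i) continue;
      kmer.assign(s, i, k);
      if (canonical) {
        rc = revcomp_str(kmer);
        if (rc < kmer) kmer = rc;
      }
      counts[kmer] += 1.0;
      total += 1.0;
    }
  }
  CharacterVector motifs(counts.size());
  NumericVector vals(counts.size());
  R_xlen_t i = 0;
  for (auto& kv : counts) { motifs[i] = kv.first; vals[i] = kv.second; ++i; }
  return List::create(_["motif"] = motifs, _["count"] = vals,
                      _["total_kmers"] = total);
}
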