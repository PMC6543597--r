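#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// identity(lag) = matches(s[i], s[i+lag]) / (L - lag); N never matches.
// [[Rcpp::export]]
NumericVector lag_identity_cpp(std::string s, int min_lag, int max_lag) {
  int L = (int)s.size();
  if (max_lag >= L) max_lag = L - 1;
  int nlag = max_lag - min_lag + 1;
  NumericVector out(nlag);
  CharacterVector nm(nlag);
  for (int lag = min_lag; lag <= max_lag; ++lag) {
    int m = 0;
    for (int i = 0; i + lag < L; ++i)
      if (s[i] == s[i + lag] && s[i] != 'N') ++m;
    out[lag - min_lag] = (double)m / (double)(L - lag);
  }
  return out;
}

// Self-dotplot match points: (i, j) with i < j (1-based starts) emitted
// when the window-length substrings at i and j agree at >= min_identity.
// [[Rcpp::export]]
DataFrame dotplot_cpp(std::string s, int window, double min_identity, int step) {
  int L = (int)s.size();
  std::vector<int> iv, jv;
  std::vector<double> idv;
  int need = (int)std::ceil(min_identity * window);
  for (int i = 0; i + window <= L; i += step) {
    for (int j = i + 1; j + window <= L; j += step) {
      int m = 0;
      for (int t = 0; t < window; ++t)
        if (s[i + t] == s[j + t] && s[i + t] != 'N') ++m;
      if (m >= need) {
        iv.push_back(i + 1); jv.push_back(j + 1);
        idv.push_back((double)m / window);
      }
    }
  }
  return DataFrame::create(_["i"] = iv, _["j"] = jv, _["identity"] = idv);
}

// Column-wise majority vote over reads placed at integer offsets
// (already strand-oriented). Ties break lexicographically (A<C<G<T);
// uncovered columns become N. Offsets are 0-based relative to the
// layout origin and must be >= 0.
// [[Rcpp::export]]
List consensus_vote_cpp(CharacterVector seqs, IntegerVector offsets) {
  int n = seqs.size();
  int span = 0;
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    int e = offsets[i] + (int)ss[i].size();
    if (e > span) span = e;
  }
  std::vector<int> tally(4 * (size_t)span, 0);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int i = 0; i < n; ++i) {
    int off = offsets[i];
    for (int t = 0; t < (int)ss[i].size(); ++t) {
      int b;
      switch (ss[i][t]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
      }
      if (b >= 0) tally[4 * (size_t)(off + t) + b]++;
    }
  }
  std::string cons(span, 'N');
  IntegerVector support(span);
  for (int x = 0; x < span; ++x) {
    int best = -1, bestc = 0, tot = 0;
    for (int b = 0; b < 4; ++b) {
      int c = tally[4 * (size_t)x + b];
      tot += c;
      if (c > bestc) { bestc = c; best = b; }
    }
    if (best >= 0) cons[x] = bases[best];
    support[x] = tot;
  }
  return List::create(_["consensus"] = cons, _["support"] = support);
}
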