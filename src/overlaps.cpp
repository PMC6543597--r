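#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

std::string revcomp_str(const std::string& s);

static inline int base2(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// Gap-free evaluation of an A-vs-B alignment at a fixed diagonal.
// d is the position of B's first base in A's coordinates; the overlap
// is the intersection of the two reads in that frame.
static void eval_diag(const std::string& A, const std::string& B, int d,
                      int& overlap, int& matches) {
  int s = std::max(0, d);
  int e = std::min((int)A.size(), (int)B.size() + d);
  overlap = e - s;
  matches = 0;
  if (overlap <= 0) { overlap = 0; return; }
  for (int x = s; x < e; ++x)
    if (A[x] == B[x - d] && base2(A[x]) >= 0) ++matches;
}

struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> idx; // seed -> (seq, pos)
};

static bool encode_seed(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int t = 0; t < k; ++t) {
    int b = base2(s[pos + t]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

static void build_index(const std::vector<std::string>& seqs, int k, int step,
                        SeedIndex& si) {
  si.k = k;
  for (int i = 0; i < (int)seqs.size(); ++i) {
    const std::string& s = seqs[i];
    for (int p = 0; p + k <= (int)s.size(); p += step) {
      uint64_t v;
      if (encode_seed(s, p, k, v)) si.idx[v].push_back({i, p});
    }
  }
}

// Read-overlap edges under the clustering edge criterion: an edge joins
// two reads when some (gap-free) overlap alignment, on either strand,
// spans >= min_overlap_frac of the shorter read at >= min_identity.
// Candidate diagonals come from shared seed_len-mers; up to
// max_diags best-supported diagonals are evaluated per pair/strand.
// [[Rcpp::export]]
DataFrame find_overlaps_cpp(CharacterVector reads,
                            double min_overlap_frac, double min_identity,
                            int seed_len, int index_step, int max_diags,
                            int max_seed_occ) {
  int n = reads.size();
  std::vector<std::string> fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(reads[i]);
    rev[i] = revcomp_str(fwd[i]);
  }
  SeedIndex si;
  build_index(fwd, seed_len, index_step, si);
  // downsample pathologically abundant seeds (high-copy satellites):
  for (auto& kv : si.idx) {
    if ((int)kv.second.size() > max_seed_occ) {
      std::vector<std::pair<int,int>> keep;
      double stride = (double)kv.second.size() / max_seed_occ;
      for (int t = 0; t < max_seed_occ; ++t)
        keep.push_back(kv.second[(size_t)(t * stride)]);
      kv.second = keep;
    }
  }

  // (pair, strand) -> diagonal support counts
  // key: a * n + b, strand in separate maps
  typedef std::unordered_map<int, int> DiagMap;
  std::unordered_map<uint64_t, DiagMap> cand[2]; // 0 = same, 1 = opposite

  for (int i = 0; i < n; ++i) {
    for (int frame = 0; frame < 2; ++frame) {
      const std::string& q = frame == 0 ? fwd[i] : rev[i];
      for (int p = 0; p + seed_len <= (int)q.size(); ++p) {
        uint64_t v;
        if (!encode_seed(q, p, seed_len, v)) continue;
        auto it = si.idx.find(v);
        if (it == si.idx.end()) continue;
        for (auto& hit : it->second) {
          int j = hit.first, qpos = hit.second;
          if (j == i) continue;
          int a = std::min(i, j), b = std::max(i, j);
          uint64_t key = (uint64_t)a * (uint64_t)n + (uint64_t)b;
          int d;
          if (frame == 0) {
            d = (i < j) ? (p - qpos) : (qpos - p);
            cand[0][key][d] += 1;
          } else {
            if (i < j) d = (int)fwd[i].size() - (int)fwd[j].size() - (p - qpos);
            else       d = qpos - p;
            cand[1][key][d] += 1;
          }
        }
      }
    }
  }

  std::vector<int> ea, eb, eov, ematch, eoff;
  std::vector<double> eid;
  std::vector<std::string> estrand;
  for (int strand = 0; strand < 2; ++strand) {
    for (auto& kv : cand[strand]) {
      int a = (int)(kv.first / (uint64_t)n);
      int b = (int)(kv.first % (uint64_t)n);
      // rank diagonals by seed support
      std::vector<std::pair<int,int>> diags(kv.second.begin(), kv.second.end());
      std::sort(diags.begin(), diags.end(),
                [](const std::pair<int,int>& x, const std::pair<int,int>& y) {
                  if (x.second != y.second) return x.second > y.second;
                  return x.first < y.first;
                });
      int la = (int)fwd[a].size(), lb = (int)fwd[b].size();
      int min_ov = (int)std::ceil(min_overlap_frac * std::min(la, lb));
      const std::string& B = strand == 0 ? fwd[b] : rev[b];
      int best_ov = 0, best_m = 0, best_d = 0;
      double best_id = -1.0;
      int tried = 0;
      for (auto& dg : diags) {
        if (tried++ >= max_diags) break;
        int ov, m;
        eval_diag(fwd[a], B, dg.first, ov, m);
        if (ov < min_ov) continue;
        double id = (double)m / ov;
        if (id > best_id || (id == best_id && ov > best_ov)) {
          best_id = id; best_ov = ov; best_m = m; best_d = dg.first;
        }
      }
      if (best_id >= min_identity && best_ov >= min_ov) {
        ea.push_back(a + 1); eb.push_back(b + 1);
        eov.push_back(best_ov); ematch.push_back(best_m);
        eid.push_back(best_id); eoff.push_back(best_d);
        estrand.push_back(strand == 0 ? "+" : "-");
      }
    }
  }
  return DataFrame::create(_["a"] = ea, _["b"] = eb, _["strand"] = estrand,
                           _["overlap"] = eov, _["matches"] = ematch,
                           _["identity"] = eid, _["offset"] = eoff,
                           _["stringsAsFactors"] = false);
}

// Map reads to a single reference fragment ("Map to Reference" role):
// a read counts as mapped when its best gap-free alignment to the
// fragment, on either strand, covers >= min_read_coverage of the read
// at >= min_identity. Returns per-read logical.
// [[Rcpp::export]]
LogicalVector map_reads_cpp(CharacterVector reads, std::string fragment,
                            double min_identity, double min_read_coverage,
                            int seed_len) {
  int n = reads.size();
  SeedIndex si;
  std::vector<std::string> frag(1, fragment);
  build_index(frag, seed_len, 1, si);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string f = as<std::string>(reads[i]);
    std::string r = revcomp_str(f);
    bool mapped = false;
    int need = (int)std::ceil(min_read_coverage * f.size());
    for (int frame = 0; frame < 2 && !mapped; ++frame) {
      const std::string& q = frame == 0 ? f : r;
      std::unordered_map<int, int> diags; // read-start offset in fragment coords
      for (int p = 0; p + seed_len <= (int)q.size(); ++p) {
        uint64_t v;
        if (!encode_seed(q, p, seed_len, v)) continue;
        auto it = si.idx.find(v);
        if (it == si.idx.end()) continue;
        for (auto& hit : it->second) diags[hit.second - p] += 1;
      }
      std::vector<std::pair<int,int>> dv(diags.begin(), diags.end());
      std::sort(dv.begin(), dv.end(),
                [](const std::pair<int,int>& x, const std::pair<int,int>& y) {
                  if (x.second != y.second) return x.second > y.second;
                  return x.first < y.first;
                });
      int tried = 0;
      for (auto& dg : dv) {
        if (tried++ >= 16) break;
        int ov, m;
        // fragment = A, read = B, offset of read start in fragment coords
        eval_diag(fragment, q, dg.first, ov, m);
        if (ov >= need && (double)m / ov >= min_identity) { mapped = true; break; }
      }
    }
    out[i] = mapped;
  }
  return out;
}
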