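// Maximal exact repeat finder (direct and inverted), REPuter-style semantics:
// every maximal repeated pair >= min_len, each unordered pair reported once,
// self-overlapping tandem copies allowed, N never matches anything.
//
// Anchoring: shared k-mers (k = min(min_len, 31)) are extended to maximal
// matches; per-(anti)diagonal bookkeeping avoids re-extending seeds that lie
// inside an already reported match.  Circular sequences are handled with
// modular extension from seed starts in [0, L).

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <set>
#include <tuple>
#include <cstdint>
using namespace Rcpp;

namespace {

inline int enc(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N and anything else: never matches
  }
}

struct Hit {
  int p1, p2, len, inv;
  bool operator<(const Hit& o) const {
    if (p1 != o.p1) return p1 < o.p1;
    if (p2 != o.p2) return p2 < o.p2;
    if (len != o.len) return len < o.len;
    return inv < o.inv;
  }
};

}  // namespace

// [[Rcpp::export]]
DataFrame find_repeats_cpp(std::string seq, int min_len, bool direct,
                           bool inverted, bool circular) {
  const int L = static_cast<int>(seq.size());
  std::set<Hit> hits;
  if (L >= min_len && min_len >= 2) {
    const int k = std::min(min_len, 31);
    std::vector<int8_t> code(L);
    for (int i = 0; i < L; ++i) code[i] = static_cast<int8_t>(enc(seq[i]));
    std::vector<int8_t> rc(L);
    for (int i = 0; i < L; ++i) {
      int8_t c = code[L - 1 - i];
      rc[i] = (c < 0) ? int8_t(-1) : int8_t(3 - c);
    }
    auto atS = [&](long long i) -> int {
      if (circular) { i %= L; if (i < 0) i += L; return code[i]; }
      return (i < 0 || i >= L) ? -2 : code[i];
    };
    auto atR = [&](long long i) -> int {
      if (circular) { i %= L; if (i < 0) i += L; return rc[i]; }
      return (i < 0 || i >= L) ? -2 : rc[i];
    };
    auto kmer_at = [&](const std::vector<int8_t>& v, int s, uint64_t& key) {
      key = 0;
      for (int t = 0; t < k; ++t) {
        int idx = circular ? (s + t) % L : s + t;
        int c = v[idx];
        if (c < 0) return false;
        key = (key << 2) | static_cast<uint64_t>(c);
      }
      return true;
    };

    const int maxStart = circular ? L - 1 : L - k;
    std::unordered_map<uint64_t, std::vector<int> > fwd;
    fwd.reserve(2 * L);
    for (int s = 0; s <= maxStart; ++s) {
      uint64_t key;
      if (kmer_at(code, s, key)) fwd[key].push_back(s);
    }

    auto modL = [&](long long x) -> int { x %= L; if (x < 0) x += L; return (int)x; };

    if (direct) {
      std::unordered_set<long long> done;
      for (auto& kv : fwd) {
        std::vector<int>& v = kv.second;
        const size_t m = v.size();
        if (m < 2) continue;
        for (size_t a = 0; a + 1 < m; ++a)
          for (size_t b = a + 1; b < m; ++b) {
            int i = v[a], j = v[b];
            long long diag = j - i;
            if (done.count(diag * L + i)) continue;
            // extend left
            int left = 0, right = 0;
            int len = k;
            while (len < L) {
              int ca = atS((long long)i - 1 - left), cb = atS((long long)j - 1 - left);
              if (ca < 0 || cb < 0 || ca != cb) break;
              ++left; ++len;
            }
            while (len < L) {
              int ca = atS((long long)i + k + right), cb = atS((long long)j + k + right);
              if (ca < 0 || cb < 0 || ca != cb) break;
              ++right; ++len;
            }
            int s1 = circular ? modL(i - left) : i - left;
            int s2 = circular ? modL(s1 + diag) : (int)(s1 + diag);
            for (int t = 0; t + k <= len; ++t) {
              int sp = circular ? modL(s1 + t) : s1 + t;
              done.insert(diag * L + sp);
            }
            if (len >= min_len) {
              Hit h;
              h.p1 = std::min(s1, s2);
              h.p2 = std::max(s1, s2);
              h.len = len;
              h.inv = 0;
              hits.insert(h);
            }
          }
      }
    }

    if (inverted) {
      std::unordered_map<uint64_t, std::vector<int> > rev;
      rev.reserve(2 * L);
      for (int s = 0; s <= maxStart; ++s) {
        uint64_t key;
        if (kmer_at(rc, s, key)) rev[key].push_back(s);
      }
      std::unordered_set<long long> done;
      for (auto& kv : rev) {
        auto it = fwd.find(kv.first);
        if (it == fwd.end()) continue;
        for (int pr : kv.second)
          for (int i : it->second) {
            long long anti = circular ? modL((long long)i + L - 1 - pr)
                                      : (long long)i + L - 1 - pr;
            if (done.count(anti * (2LL * L + 2) + i)) continue;
            int left = 0, right = 0, len = k;
            while (len < L) {
              int ca = atS((long long)i - 1 - left), cb = atR((long long)pr - 1 - left);
              if (ca < 0 || cb < 0 || ca != cb) break;
              ++left; ++len;
            }
            while (len < L) {
              int ca = atS((long long)i + k + right), cb = atR((long long)pr + k + right);
              if (ca < 0 || cb < 0 || ca != cb) break;
              ++right; ++len;
            }
            int s1 = circular ? modL(i - left) : i - left;
            int r1 = circular ? modL(pr - left) : pr - left;
            int q = circular ? modL((long long)L - r1 - len) : L - r1 - len;
            for (int t = 0; t + k <= len; ++t) {
              int sp = circular ? modL(s1 + t) : s1 + t;
              int sq = circular ? modL(q + t) : q + t;
              done.insert(anti * (2LL * L + 2) + sp);
              done.insert(anti * (2LL * L + 2) + sq);
            }
            if (len >= min_len) {
              Hit h;
              h.p1 = std::min(s1, q);
              h.p2 = std::max(s1, q);
              h.len = len;
              h.inv = 1;
              hits.insert(h);
            }
          }
      }
    }
  }

  const int nh = static_cast<int>(hits.size());
  IntegerVector p1(nh), p2(nh), len(nh);
  CharacterVector ori(nh);
  int idx = 0;
  for (const Hit& h : hits) {
    p1[idx] = h.p1 + 1;  // 1-based for R
    p2[idx] = h.p2 + 1;
    len[idx] = h.len;
    ori[idx] = h.inv ? "inverted" : "direct";
    ++idx;
  }
  return DataFrame::create(_["pos1"] = p1, _["pos2"] = p2,
                           _["length"] = len, _["orientation"] = ori,
                           _["stringsAsFactors"] = false);
}
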