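#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; 4 flags a non-ACGT character
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE2BASE[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// Enumerate canonical k-mers of a sequence with a rolling 2-bit encoding.
// Positions overlapping a non-ACGT base are skipped. f(pos_valid, canon)
template <typename F>
static void for_each_canonical(const std::string& s, int k, F f) {
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fwd = 0, rev = 0;
  int valid = 0; // run length of valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c > 3) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      f(i - k + 1, canon);
    }
  }
}

//' @noRd
// [[Rcpp::export]]
List cpp_kmer_graph(CharacterVector reads, int k, int min_count) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be odd and in [3, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const std::string s = as<std::string>(reads[r]);
    for_each_canonical(s, k, [&](int, uint64_t canon) { counts[canon]++; });
  }
  // survivors
  std::unordered_map<uint64_t, uint32_t> keep;
  for (auto& kv : counts)
    if ((int)kv.second >= min_count) keep.insert(kv);
  counts.clear();

  // edge pass: adjacent surviving canonical k-mers; unordered pair is
  // strand-symmetric (opposite strand reverses the pair)
  std::map<std::pair<uint64_t, uint64_t>, uint32_t> edges;
  std::vector<uint64_t> canon_at;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const std::string s = as<std::string>(reads[r]);
    const int n = (int)s.size();
    if (n < k + 1) continue;
    canon_at.assign(n, UINT64_MAX);
    for_each_canonical(s, k, [&](int pos, uint64_t canon) {
      if (keep.count(canon)) canon_at[pos] = canon;
    });
    for (int i = 0; i + 1 <= n - k; ++i) {
      uint64_t a = canon_at[i], b = canon_at[i + 1];
      if (a == UINT64_MAX || b == UINT64_MAX) continue;
      if (a <= b) edges[{a, b}]++; else edges[{b, a}]++;
    }
  }

  // nodes table (sorted by encoded value for determinism)
  std::vector<std::pair<uint64_t, uint32_t>> nodes(keep.begin(), keep.end());
  std::sort(nodes.begin(), nodes.end());
  CharacterVector node_kmer(nodes.size());
  IntegerVector node_count(nodes.size());
  for (size_t i = 0; i < nodes.size(); ++i) {
    node_kmer[i] = decode_kmer(nodes[i].first, k);
    node_count[i] = (int)nodes[i].second;
  }

  std::vector<std::pair<std::pair<uint64_t, uint64_t>, uint32_t>> ev;
  for (auto& kv : edges)
    if ((int)kv.second >= min_count) ev.push_back(kv);
  CharacterVector efrom(ev.size()), eto(ev.size());
  IntegerVector ew(ev.size());
  for (size_t i = 0; i < ev.size(); ++i) {
    efrom[i] = decode_kmer(ev[i].first.first, k);
    eto[i] = decode_kmer(ev[i].first.second, k);
    ew[i] = (int)ev[i].second;
  }

  return List::create(
    _["nodes"] = DataFrame::create(_["kmer"] = node_kmer, _["count"] = node_count,
                                   _["stringsAsFactors"] = false),
    _["edges"] = DataFrame::create(_["from"] = efrom, _["to"] = eto, _["weight"] = ew,
                                   _["stringsAsFactors"] = false));
}

//' Number of canonical k-mers shared between sequence `a` and any of `b`
//' (the simulator's background-vs-monomer collision screen).
//' @noRd
// [[Rcpp::export]]
int cpp_shared_kmer_count(std::string a, CharacterVector b, int k) {
  std::unordered_set<uint64_t> bk;
  for (R_xlen_t i = 0; i < b.size(); ++i) {
    const std::string s = as<std::string>(b[i]);
    for_each_canonical(s, k, [&](int, uint64_t canon) { bk.insert(canon); });
  }
  int shared = 0;
  std::unordered_set<uint64_t> seen;
  for_each_canonical(a, k, [&](int, uint64_t canon) {
    if (bk.count(canon) && seen.insert(canon).second) shared++;
  });
  return shared;
}
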