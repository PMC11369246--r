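#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// scores follow cross_match-ish simple scheme
static const int MATCH = 1, MISMATCH = -1, GAP = -2;

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// transition = purine<->purine (A/G) or pyrimidine<->pyrimidine (C/T)
static inline bool is_transition(char a, char b) {
  return (a == 'A' && b == 'G') || (a == 'G' && b == 'A') ||
         (a == 'C' && b == 'T') || (a == 'T' && b == 'C');
}

static inline int base2(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1;
  case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

static void seed_set(const std::string& s, int k,
                     std::unordered_set<uint64_t>& out) {
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0; int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base2(s[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) out.insert(h);
  }
}

static bool has_seed(const std::string& s, int k, int step,
                     const std::unordered_set<uint64_t>& set) {
  const int n = (int)s.size();
  if (n < k || set.empty()) return false;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  // recompute hash per sampled start (step small, k small: fine)
  for (int i = 0; i + k <= n; i += step) {
    uint64_t h = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base2(s[i + j]);
      if (c < 0) { ok = false; break; }
      h = ((h << 2) | (uint64_t)c) & mask;
    }
    if (ok && set.count(h)) return true;
  }
  return false;
}

struct AlnStats {
  int score = 0, matches = 0, mismatches = 0, ts = 0, tv = 0;
  int read_span = 0, columns = 0, ref_start = 0, ref_end = 0;
  bool ok = false;
};

// Smith-Waterman local alignment of read (rows) vs ref (cols) with traceback.
static AlnStats sw_align(const std::string& read, const std::string& ref) {
  const int n = (int)read.size(), m = (int)ref.size();
  AlnStats st;
  if (n == 0 || m == 0) return st;
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0); // 0 stop, 1 diag, 2 up(read gap in ref? read consumed), 3 left
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      int sub = (read[i - 1] == ref[j - 1] && is_acgt(read[i - 1])) ? MATCH : MISMATCH;
      int d = H[prow + j - 1] + sub;
      int u = H[prow + j] + GAP;      // gap in ref (read base unaligned column)
      int l = H[row + j - 1] + GAP;   // gap in read
      int v = d; uint8_t t = 1;
      if (u > v) { v = u; t = 2; }
      if (l > v) { v = l; t = 3; }
      if (v <= 0) { v = 0; t = 0; }
      H[row + j] = v; tb[row + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return st;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && tb[(size_t)i * (m + 1) + j] != 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    st.columns++;
    if (t == 1) {
      char a = read[i - 1], b = ref[j - 1];
      if (a == b && is_acgt(a)) st.matches++;
      else if (is_acgt(a) && is_acgt(b)) {
        st.mismatches++;
        if (is_transition(a, b)) st.ts++; else st.tv++;
      } else {
        st.mismatches++; // ambiguous column: counted in columns, not in ts/tv
      }
      --i; --j;
    } else if (t == 2) { --i; }
    else { --j; }
  }
  st.score = best;
  st.read_span = bi - i;
  st.ref_start = j + 1;  // 1-based on ref
  st.ref_end = bj;
  st.ok = true;
  return st;
}

// positional seed index of one reference strand: seed hash -> positions
typedef std::unordered_map<uint64_t, std::vector<int>> SeedIndex;

static void seed_index(const std::string& s, int k, SeedIndex& out) {
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0; int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base2(s[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) out[h].push_back(i - k + 1);
  }
}

// diagonals (ref_pos - read_pos) on which the read shares a sampled seed
// with the reference
static std::vector<int> seed_diagonals(const std::string& rd, int k, int step,
                                       const SeedIndex& idx) {
  std::vector<int> ds;
  const int n = (int)rd.size();
  if (n < k || idx.empty()) return ds;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int i = 0; i + k <= n; i += step) {
    uint64_t h = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base2(rd[i + j]);
      if (c < 0) { ok = false; break; }
      h = ((h << 2) | (uint64_t)c) & mask;
    }
    if (!ok) continue;
    auto it = idx.find(h);
    if (it == idx.end()) continue;
    for (int p : it->second) ds.push_back(p - i);
  }
  std::sort(ds.begin(), ds.end());
  ds.erase(std::unique(ds.begin(), ds.end()), ds.end());
  return ds;
}

struct DiagCluster { int dmin, dmax, support; };

static std::vector<DiagCluster> cluster_diagonals(const std::vector<int>& ds,
                                                  int merge_gap) {
  std::vector<DiagCluster> cl;
  for (int d : ds) {
    if (!cl.empty() && d - cl.back().dmax <= merge_gap) {
      cl.back().dmax = d; cl.back().support++;
    } else {
      cl.push_back({d, d, 1});
    }
  }
  std::sort(cl.begin(), cl.end(), [](const DiagCluster& a, const DiagCluster& b) {
    return a.support > b.support || (a.support == b.support && a.dmin < b.dmin);
  });
  return cl;
}

// seed-anchored alignment: SW restricted to a reference window around each
// seeded diagonal cluster (best of up to max_clusters windows)
static AlnStats anchored_align(const std::string& rd, const std::string& ref,
                               const std::vector<int>& ds, int pad,
                               int max_clusters) {
  AlnStats best;
  const int n = (int)rd.size(), m = (int)ref.size();
  std::vector<DiagCluster> cl = cluster_diagonals(ds, 2 * pad);
  int tried = 0;
  for (const DiagCluster& c : cl) {
    if (tried++ >= max_clusters) break;
    int lo = std::max(0, c.dmin - pad);
    int hi = std::min(m, c.dmax + n + pad);
    if (hi - lo < 1) continue;
    AlnStats st = sw_align(rd, ref.substr((size_t)lo, (size_t)(hi - lo)));
    if (!st.ok) continue;
    st.ref_start += lo; st.ref_end += lo;
    if (st.score > best.score ||
        (st.score == best.score && best.ok && st.ref_start < best.ref_start) ||
        !best.ok) {
      best = st;
    }
  }
  return best;
}

//' Best local hit of each read against a set of references (both strands).
//' refs are expected pre-tiled by the caller (monomer repeated so a full
//' read fits). seed_k = 0 disables the seed anchor and runs full-width
//' Smith-Waterman on both strands of every reference.
//' @noRd
// [[Rcpp::export]]
DataFrame cpp_best_hits(CharacterVector reads, CharacterVector refs,
                        double min_identity, double min_coverage,
                        int seed_k = 12, int seed_step = 3, int band_pad = 16) {
  const int nr = (int)refs.size();
  std::vector<std::string> ref_s(nr);
  std::vector<SeedIndex> idx(nr);
  for (int j = 0; j < nr; ++j) {
    ref_s[j] = as<std::string>(refs[j]);
    if (seed_k > 0) seed_index(ref_s[j], seed_k, idx[j]);
  }
  const R_xlen_t n = reads.size();
  IntegerVector hit(n, NA_INTEGER), masked_bp(n, 0), matches(n, 0),
      ts(n, 0), tv(n, 0), pairs(n, 0), ref_start(n, NA_INTEGER),
      ref_end(n, NA_INTEGER);
  NumericVector identity(n, NA_REAL), coverage(n, NA_REAL);
  IntegerVector strand(n, NA_INTEGER); // 1 fwd, -1 rev

  for (R_xlen_t r = 0; r < n; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const std::string rc = revcomp(rd);
    const int rl = (int)rd.size();
    double best_id = -1.0; int best_j = -1;
    AlnStats best_st; int best_strand = 1;
    for (int j = 0; j < nr; ++j) {
      for (int sdir = 0; sdir < 2; ++sdir) {
        const std::string& s = sdir == 0 ? rd : rc;
        AlnStats st;
        if (seed_k > 0) {
          std::vector<int> ds = seed_diagonals(s, seed_k, seed_step, idx[j]);
          if (ds.empty()) continue;
          st = anchored_align(s, ref_s[j], ds, band_pad, 3);
        } else {
          st = sw_align(s, ref_s[j]);
        }
        if (!st.ok || st.columns == 0) continue;
        double id = (double)st.matches / st.columns;
        double cov = (double)st.read_span / rl;
        if (id < min_identity || cov < min_coverage) continue;
        // best hit: higher identity, then lower ref index, then fwd strand
        if (id > best_id + 1e-12 ||
            (std::abs(id - best_id) <= 1e-12 && best_j >= 0 && j < best_j)) {
          best_id = id; best_j = j; best_st = st; best_strand = sdir == 0 ? 1 : -1;
        }
      }
    }
    if (best_j >= 0) {
      hit[r] = best_j + 1;
      masked_bp[r] = best_st.read_span;
      matches[r] = best_st.matches;
      ts[r] = best_st.ts; tv[r] = best_st.tv;
      pairs[r] = best_st.matches + best_st.mismatches;
      identity[r] = best_id;
      coverage[r] = (double)best_st.read_span / rl;
      strand[r] = best_strand;
      ref_start[r] = best_st.ref_start;
      ref_end[r] = best_st.ref_end;
    }
  }
  return DataFrame::create(
      _["hit"] = hit, _["masked_bp"] = masked_bp, _["matches"] = matches,
      _["transitions"] = ts, _["transversions"] = tv, _["pairs"] = pairs,
      _["identity"] = identity, _["coverage"] = coverage, _["strand"] = strand,
      _["ref_start"] = ref_start, _["ref_end"] = ref_end,
      _["stringsAsFactors"] = false);
}

// Fit (glocal) alignment: `a` global, gaps at the ends of `ref` free.
// Gap cost for homology-tier identity: satellite families diverge mostly by
// substitution, and a permissive gap cost lets the aligner launder mismatches
// into matches, inflating the identity of unrelated pairs above the
// superfamily threshold. -6 keeps genuine short indels affordable while
// making cosmetic gaps unprofitable even between distant pairs.
static const int GAP_FIT = -12;

static double fit_identity_one(const std::string& a, const std::string& ref) {
  const int n = (int)a.size(), m = (int)ref.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<int> H((size_t)(n + 1) * (m + 1));
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) H[j] = 0;                    // free lead-in on ref
  for (int i = 1; i <= n; ++i) { H[(size_t)i * (m + 1)] = i * GAP_FIT; tb[(size_t)i * (m + 1)] = 2; }
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      int sub = (a[i - 1] == ref[j - 1] && is_acgt(a[i - 1])) ? MATCH : MISMATCH;
      int d = H[prow + j - 1] + sub;
      int u = H[prow + j] + GAP_FIT;
      int l = H[row + j - 1] + GAP_FIT;
      int v = d; uint8_t t = 1;
      if (u > v) { v = u; t = 2; }
      if (l > v) { v = l; t = 3; }
      H[row + j] = v; tb[row + j] = t;
    }
  }
  // free lead-out on ref: best cell in last row
  int bj = 0, best = H[(size_t)n * (m + 1)];
  for (int j = 1; j <= m; ++j)
    if (H[(size_t)n * (m + 1) + j] > best) { best = H[(size_t)n * (m + 1) + j]; bj = j; }
  int i = n, j = bj, matches = 0, columns = 0;
  while (i > 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    columns++;
    if (t == 1) { if (a[i - 1] == ref[j - 1] && is_acgt(a[i - 1])) matches++; --i; --j; }
    else if (t == 2) { --i; }
    else { --j; }
  }
  return columns > 0 ? (double)matches / columns : 0.0;
}

//' Rotation/strand-aware identity: shorter sequence fit-aligned into the
//' dimer of the longer, both strands, maximum taken. Sequences shorter than
//' MIN_FIT_LEN are tiled head-to-tail first (circular equivalence makes the
//' tiling exact): with very few alignment columns the maximum over
//' placements of a random alignment drifts toward the superfamily
//' threshold, and lengthening the alignment removes that selection bias
//' without changing the identity of true homologs.
//' @noRd
// [[Rcpp::export]]
double cpp_pair_identity(std::string a, std::string b) {
  static const size_t MIN_FIT_LEN = 50;
  if (a.size() > b.size()) std::swap(a, b);
  if (a.size() < MIN_FIT_LEN) {
    size_t reps = (MIN_FIT_LEN + a.size() - 1) / a.size();
    std::string ta;
    for (size_t i = 0; i < reps; ++i) ta += a;
    a = ta;
  }
  size_t ref_reps = std::max((size_t)2, a.size() / b.size() + 2);
  std::string ref;
  for (size_t i = 0; i < ref_reps; ++i) ref += b;
  double id = fit_identity_one(a, ref);
  double id2 = fit_identity_one(revcomp(a), ref);
  return id > id2 ? id : id2;
}

//' Ungapped periodic alignment of reads to a monomer; returns for each read
//' the extracted full-monomer window re-phased to monomer coordinate 0, or ""
//' if no acceptable placement exists.
//' @noRd
// [[Rcpp::export]]
CharacterVector cpp_extract_haplotypes(CharacterVector reads, std::string monomer,
                                       double min_identity, int seed_k = 10,
                                       int seed_step = 3) {
  const int m = (int)monomer.size();
  std::unordered_set<uint64_t> seeds;
  if (seed_k > 0) {
    std::string dimer = monomer + monomer;
    seed_set(dimer, seed_k, seeds);
    seed_set(revcomp(dimer), seed_k, seeds);
  }
  const R_xlen_t n = reads.size();
  CharacterVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    out[r] = "";
    const std::string rd = as<std::string>(reads[r]);
    const int rl = (int)rd.size();
    if (rl < m) continue;
    if (seed_k > 0 && !has_seed(rd, seed_k, seed_step, seeds)) continue;
    const std::string rc = revcomp(rd);
    int best_matches = -1, best_phase = 0; const std::string* best_seq = nullptr;
    for (int sdir = 0; sdir < 2; ++sdir) {
      const std::string& s = sdir == 0 ? rd : rc;
      for (int phase = 0; phase < m; ++phase) {
        int matches = 0;
        for (int i = 0; i < rl; ++i)
          if (s[i] == monomer[(phase + i) % m]) matches++;
        if (matches > best_matches) {
          best_matches = matches; best_phase = phase; best_seq = &s;
        }
      }
    }
    if (best_seq == nullptr) continue;
    double id = (double)best_matches / rl;
    if (id < min_identity) continue;
    int p0 = (m - best_phase) % m; // read position aligned to monomer coord 0
    if (p0 + m > rl) continue;     // no complete monomer window inside read
    out[r] = best_seq->substr((size_t)p0, (size_t)m);
  }
  return out;
}

//' Pairwise Hamming distance matrix of equal-length sequences.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(CharacterVector seqs) {
  const int n = (int)seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 1; i < n; ++i)
    if (s[i].size() != s[0].size()) stop("sequences must have equal length");
  IntegerMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int h = 0;
      for (size_t k = 0; k < s[i].size(); ++k)
        if (s[i][k] != s[j][k]) h++;
      d(i, j) = h; d(j, i) = h;
    }
  return d;
}

//' Count mismatches of each read against a given reference window (ungapped),
//' used by the simulator's self-checks.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_count_mismatches(CharacterVector reads, CharacterVector targets) {
  if (reads.size() != targets.size()) stop("length mismatch");
  IntegerVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const std::string a = as<std::string>(reads[r]);
    const std::string b = as<std::string>(targets[r]);
    size_t n = std::min(a.size(), b.size());
    int mm = 0;
    for (size_t i = 0; i < n; ++i) if (a[i] != b[i]) mm++;
    out[r] = mm + (int)(std::max(a.size(), b.size()) - n);
  }
  return out;
}
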