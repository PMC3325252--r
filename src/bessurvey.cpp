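#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// -------------------------------------------------------------------------
// Shared helpers
// -------------------------------------------------------------------------

// A=0 C=1 G=2 T=3, anything else (incl. N and lowercase) = 4
static inline int nt_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

static std::vector<int> encode_nt(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = nt_code(s[i]);
  return v;
}

// -------------------------------------------------------------------------
// Affine-gap local (Smith-Waterman) alignment over integer-coded sequences
// with an arbitrary substitution matrix.  Gap of length L costs
// gap_open + L * gap_extend (both passed as negative scores).
// -------------------------------------------------------------------------

struct AlnResult {
  double score;
  int q_start, q_end, s_start, s_end; // 1-based inclusive; 0 if no alignment
  int n_match, n_mismatch, n_gap_cols, n_gap_opens, aln_len;
  std::string status; // M match, X substitution, I gap-in-subject, D gap-in-query
};

static AlnResult sw_core(const std::vector<int> &a, const std::vector<int> &b,
                         const NumericMatrix &sub, double go, double ge,
                         bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  // H, E (gap in a, consumes b), F (gap in b, consumes a); row-wise DP
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  std::vector<double> Hprev(m + 1, 0.0);
  // traceback matrices: 0 stop, 1 diag, 2 from E (left), 3 from F (up)
  // plus gap-state provenance for affine traceback
  std::vector<uint8_t> tbH, tbE, tbF; // tbE: 1 = opened here, 0 = extended
  if (traceback) {
    tbH.assign((size_t)(n + 1) * (m + 1), 0);
    tbE.assign((size_t)(n + 1) * (m + 1), 0);
    tbF.assign((size_t)(n + 1) * (m + 1), 0);
  }
  std::vector<double> Fcol(m + 1, NEG);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hprev);
    H[0] = 0.0;
    std::fill(E.begin(), E.end(), NEG);
    double e = NEG;
    for (int j = 1; j <= m; ++j) {
      // E: gap in a (move left)
      double e_open = H[j - 1] + go + ge;
      double e_ext  = e + ge;
      bool e_from_open = e_open >= e_ext;
      e = e_from_open ? e_open : e_ext;
      // F: gap in b (move up)
      double f_open = Hprev[j] + go + ge;
      double f_ext  = Fcol[j] + ge;
      bool f_from_open = f_open >= f_ext;
      double f = f_from_open ? f_open : f_ext;
      Fcol[j] = f;
      double diag = Hprev[j - 1] + sub(a[i - 1], b[j - 1]);
      double h = 0.0;
      uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (e > h)    { h = e;    dir = 2; }
      if (f > h)    { h = f;    dir = 3; }
      H[j] = h;
      if (traceback) {
        size_t idx = (size_t)i * (m + 1) + j;
        tbH[idx] = dir;
        tbE[idx] = e_from_open ? 1 : 0;
        tbF[idx] = f_from_open ? 1 : 0;
      }
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  AlnResult res;
  res.score = best;
  res.q_start = res.q_end = res.s_start = res.s_end = 0;
  res.n_match = res.n_mismatch = res.n_gap_cols = res.n_gap_opens = 0;
  res.aln_len = 0;
  if (best <= 0.0 || !traceback) {
    if (best > 0.0) { res.q_end = bi; res.s_end = bj; }
    return res;
  }
  // traceback from (bi, bj)
  std::string rev;
  int i = bi, j = bj;
  int state = 0; // 0 in H, 2 in E, 3 in F
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t dir = tbH[idx];
      if (dir == 0) break;
      if (dir == 1) {
        rev.push_back(a[i - 1] == b[j - 1] && a[i - 1] != 4 ? 'M' : 'X');
        --i; --j;
      } else if (dir == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {
      rev.push_back('D'); // gap in query, subject base consumed
      bool opened = tbE[idx] == 1;
      --j;
      if (opened) { state = 0; res.n_gap_opens++; }
    } else {
      rev.push_back('I'); // gap in subject, query base consumed
      bool opened = tbF[idx] == 1;
      --i;
      if (opened) { state = 0; res.n_gap_opens++; }
    }
  }
  res.q_start = i + 1; res.q_end = bi;
  res.s_start = j + 1; res.s_end = bj;
  std::reverse(rev.begin(), rev.end());
  res.status = rev;
  res.aln_len = (int)rev.size();
  for (char c : rev) {
    if (c == 'M') res.n_match++;
    else if (c == 'X') res.n_mismatch++;
    else res.n_gap_cols++;
  }
  return res;
}

static List aln_to_list(const AlnResult &r) {
  return List::create(
    _["score"] = r.score,
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["s_start"] = r.s_start, _["s_end"] = r.s_end,
    _["n_match"] = r.n_match, _["n_mismatch"] = r.n_mismatch,
    _["n_gap_cols"] = r.n_gap_cols, _["n_gap_opens"] = r.n_gap_opens,
    _["aln_len"] = r.aln_len, _["status"] = r.status);
}

// [[Rcpp::export]]
List cpp_align_nt(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend, bool traceback = true) {
  NumericMatrix sub(5, 5);
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j)
      sub(i, j) = (i == j && i != 4) ? match : mismatch;
  std::vector<int> av = encode_nt(a), bv = encode_nt(b);
  return aln_to_list(sw_core(av, bv, sub, gap_open, gap_extend, traceback));
}

// a, b are integer codes (0-based rows/cols of sub); for proteins the caller
// maps residues through the dimnames of the substitution matrix.
// [[Rcpp::export]]
List cpp_align_coded(IntegerVector a, IntegerVector b, NumericMatrix sub,
                     double gap_open, double gap_extend, bool traceback = true) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  return aln_to_list(sw_core(av, bv, sub, gap_open, gap_extend, traceback));
}

// -------------------------------------------------------------------------
// k-mer machinery
// -------------------------------------------------------------------------

static inline bool kmer_at(const std::vector<int> &v, size_t i, int k,
                           uint64_t &out) {
  uint64_t key = 0;
  for (int t = 0; t < k; ++t) {
    int c = v[i + t];
    if (c > 3) return false;
    key = (key << 2) | (uint64_t)c;
  }
  out = key;
  return true;
}

static inline uint64_t revcomp_key(uint64_t key, int k) {
  uint64_t rc = 0;
  for (int t = 0; t < k; ++t) {
    rc = (rc << 2) | (3ULL - (key & 3ULL));
    key >>= 2;
  }
  return rc;
}

// Pairs of sequences sharing >= min_shared exact k-mers (distinct k-mer
// count, not occurrence count).  K-mers are canonicalized (the smaller of
// a k-mer and its reverse complement), so pairing is strand-symmetric.
// Returns 1-based (i, j, shared) rows, i < j.
// [[Rcpp::export]]
IntegerMatrix cpp_shared_kmer_pairs(CharacterVector seqs, int k,
                                    int min_shared) {
  int n = seqs.size();
  std::unordered_map<uint64_t, std::vector<int>> occ;
  occ.reserve(1 << 20);
  for (int s = 0; s < n; ++s) {
    std::string str = as<std::string>(seqs[s]);
    std::vector<int> v = encode_nt(str);
    if ((int)v.size() < k) continue;
    std::unordered_map<uint64_t, bool> seen;
    for (size_t i = 0; i + k <= v.size(); ++i) {
      uint64_t key;
      if (!kmer_at(v, i, k, key)) continue;
      uint64_t rc = revcomp_key(key, k);
      if (rc < key) key = rc;
      if (seen.count(key)) continue;
      seen[key] = true;
      occ[key].push_back(s);
    }
  }
  std::unordered_map<uint64_t, int> pair_count;
  for (auto &kv : occ) {
    std::vector<int> &lst = kv.second;
    size_t L = lst.size();
    if (L < 2) continue;
    for (size_t x = 0; x + 1 < L; ++x)
      for (size_t y = x + 1; y < L; ++y)
        pair_count[(uint64_t)lst[x] * (uint64_t)n + lst[y]]++;
  }
  std::vector<std::array<int, 3>> rows;
  for (auto &kv : pair_count) {
    if (kv.second >= min_shared) {
      int i = (int)(kv.first / n), j = (int)(kv.first % n);
      rows.push_back({i + 1, j + 1, kv.second});
    }
  }
  std::sort(rows.begin(), rows.end());
  IntegerMatrix out(rows.size(), 3);
  for (size_t r = 0; r < rows.size(); ++r) {
    out(r, 0) = rows[r][0]; out(r, 1) = rows[r][1]; out(r, 2) = rows[r][2];
  }
  colnames(out) = CharacterVector::create("i", "j", "shared");
  return out;
}

// For each read, the diagonal (subject_pos - query_pos) on `ref` carrying the
// most exact k-mer seeds, after clustering diagonals within +/- slack.
// Returns (n_reads x 2): best diagonal offset (0-based), seed count (0 = none).
// [[Rcpp::export]]
IntegerMatrix cpp_map_reads(std::string ref, CharacterVector reads, int k,
                            int slack = 32) {
  std::vector<int> rv = encode_nt(ref);
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve(rv.size() * 2);
  if ((int)rv.size() >= k) {
    for (size_t i = 0; i + k <= rv.size(); ++i) {
      uint64_t key;
      if (!kmer_at(rv, i, k, key)) continue;
      index[key].push_back((int)i);
    }
  }
  int n = reads.size();
  IntegerMatrix out(n, 2);
  for (int s = 0; s < n; ++s) {
    std::string str = as<std::string>(reads[s]);
    std::vector<int> v = encode_nt(str);
    std::unordered_map<int, int> diag_count;
    if ((int)v.size() >= k) {
      for (size_t i = 0; i + k <= v.size(); ++i) {
        uint64_t key;
        if (!kmer_at(v, i, k, key)) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        if (it->second.size() > 64) continue; // over-represented seed: skip
        for (int sp : it->second) {
          int d = sp - (int)i;
          diag_count[d / slack]++;  // coarse diagonal bin
        }
      }
    }
    int best_bin = 0, best_cnt = 0;
    for (auto &kv : diag_count)
      if (kv.second > best_cnt ||
          (kv.second == best_cnt && kv.first < best_bin)) {
        best_bin = kv.first; best_cnt = kv.second;
      }
    out(s, 0) = best_bin * slack;
    out(s, 1) = best_cnt;
  }
  colnames(out) = CharacterVector::create("diag", "seeds");
  return out;
}

// -------------------------------------------------------------------------
// Maximal perfect tandem repeats (SSRs), periods 1..6
// -------------------------------------------------------------------------

static bool is_primitive(const std::string &motif) {
  int p = (int)motif.size();
  for (int d = 1; d < p; ++d) {
    if (p % d != 0) continue;
    bool periodic = true;
    for (int i = d; i < p && periodic; ++i)
      if (motif[i] != motif[i - d]) periodic = false;
    if (periodic) return false;
  }
  return true;
}

// Thresholds: periods 1-3 require total length >= min_len_short;
// periods 4-6 require length >= min_units_long * period (fractional trailing
// units count toward length).  1-based inclusive output coordinates.
// [[Rcpp::export]]
DataFrame cpp_find_ssrs(std::string seq, int min_len_short = 12,
                        int min_units_long = 4) {
  int n = (int)seq.size();
  std::vector<int> starts, ends, periods;
  std::vector<std::string> motifs;
  for (int p = 1; p <= 6; ++p) {
    int i = 0;
    while (i + p < n) {
      char c = seq[i];
      bool ok = (c == 'A' || c == 'C' || c == 'G' || c == 'T') &&
                seq[i + p] == c;
      if (!ok) { ++i; continue; }
      int run_start = i;
      while (i + p < n) {
        char d = seq[i];
        if ((d == 'A' || d == 'C' || d == 'G' || d == 'T') && seq[i + p] == d)
          ++i;
        else
          break;
      }
      // positions run_start .. i-1 satisfy s[x] == s[x+p]
      int len = (i - run_start) + p;
      int end = run_start + len; // exclusive
      bool pass = (p <= 3) ? (len >= min_len_short)
                           : (len >= min_units_long * p);
      if (pass) {
        std::string motif = seq.substr(run_start, p);
        if (is_primitive(motif)) {
          starts.push_back(run_start + 1);
          ends.push_back(end);
          periods.push_back(p);
          motifs.push_back(motif);
        }
      }
    }
  }
  // identical intervals reported once, under smallest period
  std::vector<int> keep;
  for (size_t x = 0; x < starts.size(); ++x) {
    bool dup = false;
    for (size_t y = 0; y < starts.size(); ++y) {
      if (y == x) continue;
      if (starts[y] == starts[x] && ends[y] == ends[x] &&
          (periods[y] < periods[x])) { dup = true; break; }
    }
    if (!dup) keep.push_back((int)x);
  }
  std::sort(keep.begin(), keep.end(), [&](int x, int y) {
    if (starts[x] != starts[y]) return starts[x] < starts[y];
    return periods[x] < periods[y];
  });
  IntegerVector S(keep.size()), E(keep.size()), P(keep.size());
  CharacterVector M(keep.size());
  for (size_t x = 0; x < keep.size(); ++x) {
    S[x] = starts[keep[x]]; E[x] = ends[keep[x]];
    P[x] = periods[keep[x]]; M[x] = motifs[keep[x]];
  }
  return DataFrame::create(_["start"] = S, _["end"] = E, _["period"] = P,
                           _["motif"] = M, _["stringsAsFactors"] = false);
}

// -------------------------------------------------------------------------
// Low-complexity windows by trinucleotide Shannon entropy
// -------------------------------------------------------------------------

// Returns (start, end) 1-based inclusive of every window whose trinucleotide
// entropy falls below `threshold` bits; caller merges adjacent windows.
// [[Rcpp::export]]
IntegerMatrix cpp_low_complexity(std::string seq, int window = 64,
                                 int step = 32, double threshold = 1.4) {
  int n = (int)seq.size();
  std::vector<int> v = encode_nt(seq);
  std::vector<std::pair<int, int>> flagged;
  for (int w0 = 0; w0 + window <= n || (w0 == 0 && n >= 3); w0 += step) {
    int w_end = std::min(w0 + window, n);
    if (w_end - w0 < 3) break;
    int counts[64] = {0};
    int total = 0;
    for (int i = w0; i + 3 <= w_end; ++i) {
      if (v[i] > 3 || v[i + 1] > 3 || v[i + 2] > 3) continue;
      counts[v[i] * 16 + v[i + 1] * 4 + v[i + 2]]++;
      total++;
    }
    if (total < (w_end - w0 - 2) / 2 || total < 8) {
      if (w0 + window >= n) break;
      continue;
    }
    double H = 0.0;
    for (int c = 0; c < 64; ++c) {
      if (counts[c] == 0) continue;
      double p = (double)counts[c] / total;
      H -= p * std::log2(p);
    }
    if (H < threshold) flagged.push_back({w0 + 1, w_end});
    if (w0 + window >= n) break;
  }
  IntegerMatrix out(flagged.size(), 2);
  for (size_t i = 0; i < flagged.size(); ++i) {
    out(i, 0) = flagged[i].first; out(i, 1) = flagged[i].second;
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}
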