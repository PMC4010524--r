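// Local alignment engine: exact affine-gap Smith-Waterman, a band-constrained
// variant, and a seeded best-hit mapper over a k-mer positional index.
// Conventions: 0-based half-open spans; a gap of length L costs open + L*ext
// with gap_open/gap_ext given as nonnegative penalty magnitudes;
// identity = matches / alignment columns.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double NEG = -1e18;

struct AlnRes {
  bool found = false;
  double score = 0.0;
  long qs = 0, qe = 0, ss = 0, se = 0;
  long matches = 0, columns = 0;
};

// traceback codes packed per cell: bits 0-1 = H source (0 stop, 1 diag,
// 2 from E, 3 from F); bit 2 = E opened from H; bit 3 = F opened from H
static AlnRes sw_core(const std::string& a, const std::string& b,
                      double mt, double ms, double go, double ge,
                      long lo_diag, long hi_diag) {
  const long n = (long)a.size(), m = (long)b.size();
  if (go < 0 || ge < 0)
    stop("gap penalties must be given as nonnegative magnitudes");
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("alignment matrix too large for exact DP; use the banded path");
  std::vector<uint8_t> tbv((size_t)(n + 1) * (size_t)(m + 1), 0);
  std::vector<double> Hprev_v(m + 2, NEG), Hcur_v(m + 2, NEG),
      Fcol_v(m + 2, NEG);
  uint8_t* tb = tbv.data();
  double* Hprev = Hprev_v.data();
  double* Hcur = Hcur_v.data();
  double* Fcol = Fcol_v.data();
  // row 0: empty prefix of a, H = 0 inside "virtual" band start
  for (long j = 0; j <= m; ++j) Hprev[j] = 0.0;
  const double open_cost = go + ge;
  double best = 0.0;
  std::vector<std::pair<long, long>> cands;
  long prev_jmin = 0, prev_jmax = m;

  for (long i = 1; i <= n; ++i) {
    long jmin = std::max(1L, i + lo_diag), jmax = std::min(m, i + hi_diag);
    if (jmin > jmax) {
      // band has left the matrix on this side; clear the overlap region
      for (long j = std::max(0L, jmin - 2); j <= std::min(m, jmax + 1); ++j)
        Hcur[j] = NEG;
      std::swap(Hprev, Hcur);
      prev_jmin = jmin; prev_jmax = jmax;
      continue;
    }
    // clear only the band neighbourhood (+1 cell each side, read next row)
    for (long j = std::max(0L, jmin - 2); j <= std::min(m, jmax + 1); ++j)
      Hcur[j] = NEG;
    Hcur[jmin - 1] = 0.0;  // local-alignment start at the band edge
    // F cells newly entering the band on the right were never written
    for (long j = std::max(prev_jmax + 1, jmin); j <= jmax; ++j)
      Fcol[j] = NEG;
    double e = NEG;
    const char ai = a.c_str()[i - 1];
    const char* bp = b.c_str();
    uint8_t* tbrow = tb + (size_t)i * (m + 1);
    for (long j = jmin; j <= jmax; ++j) {
      uint8_t code = 0;
      // E: gap in a (consumes b[j-1]), horizontal
      double e_open = (Hcur[j - 1] > NEG / 2) ? Hcur[j - 1] - open_cost : NEG;
      double e_ext = (e > NEG / 2) ? e - ge : NEG;
      if (e_open >= e_ext) { e = e_open; code |= 4; } else { e = e_ext; }
      // F: gap in b (consumes a[i-1]), vertical
      double f_open = (Hprev[j] > NEG / 2) ? Hprev[j] - open_cost : NEG;
      double f_ext = (Fcol[j] > NEG / 2) ? Fcol[j] - ge : NEG;
      double f;
      if (f_open >= f_ext) { f = f_open; code |= 8; } else { f = f_ext; }
      Fcol[j] = f;
      double diag = (Hprev[j - 1] > NEG / 2)
        ? Hprev[j - 1] + (ai == bp[j - 1] ? mt : ms) : NEG;
      double h = 0.0; uint8_t src = 0;
      if (diag >= e && diag >= f && diag > 0) { h = diag; src = 1; }
      else if (e >= f && e > 0) { h = e; src = 2; }
      else if (f > 0) { h = f; src = 3; }
      Hcur[j] = h;
      tbrow[j] = (uint8_t)(code | src);
      if (h > best) {
        best = h; cands.clear(); cands.emplace_back(i, j);
      } else if (h == best && best > 0 && cands.size() < 256) {
        cands.emplace_back(i, j);
      }
    }
    std::swap(Hprev, Hcur);
    prev_jmin = jmin; prev_jmax = jmax;
  }

  AlnRes out;
  if (best <= 0 || cands.empty()) return out;

  AlnRes pick; bool have = false;
  for (auto& c : cands) {
    long i = c.first, j = c.second;
    long matches = 0, columns = 0;
    int state = 0;  // 0 = M, 1 = E, 2 = F
    while (true) {
      uint8_t t = tb[(size_t)i * (m + 1) + j];
      if (state == 0) {
        uint8_t src = t & 3;
        if (src == 0) break;
        if (src == 1) {
          ++columns; if (a[i - 1] == b[j - 1]) ++matches;
          --i; --j;
        } else if (src == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        ++columns; bool opened = (t & 4) != 0; --j; if (opened) state = 0;
      } else {
        ++columns; bool opened = (t & 8) != 0; --i; if (opened) state = 0;
      }
    }
    AlnRes r; r.found = true; r.score = best;
    r.qs = i; r.ss = j; r.qe = c.first; r.se = c.second;
    r.matches = matches; r.columns = columns;
    if (!have || r.qs < pick.qs || (r.qs == pick.qs && r.ss < pick.ss)) {
      pick = r; have = true;
    }
  }
  return pick;
}

static List aln_to_list(const AlnRes& r) {
  return List::create(
    _["found"] = r.found, _["score"] = r.score,
    _["q_start"] = (double)r.qs, _["q_end"] = (double)r.qe,
    _["s_start"] = (double)r.ss, _["s_end"] = (double)r.se,
    _["matches"] = (double)r.matches, _["columns"] = (double)r.columns);
}

// [[Rcpp::export]]
List cpp_sw_full(std::string a, std::string b, double match, double mismatch,
                 double gap_open, double gap_ext) {
  AlnRes r = sw_core(a, b, match, mismatch, gap_open, gap_ext,
                     -(long)a.size() - 1, (long)b.size() + 1);
  return aln_to_list(r);
}

// [[Rcpp::export]]
List cpp_sw_banded(std::string a, std::string b, double center, double band,
                   double match, double mismatch, double gap_open,
                   double gap_ext) {
  if (band < 0) stop("band must be >= 0");
  AlnRes r = sw_core(a, b, match, mismatch, gap_open, gap_ext,
                     (long)center - (long)band, (long)center + (long)band);
  return aln_to_list(r);
}

static inline int base2i(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

struct SeqIndex {
  std::string seq;
  int k;
  std::unordered_map<uint32_t, std::vector<int32_t>> pos;
};

// [[Rcpp::export]]
SEXP cpp_kmer_index(std::string seq, int k) {
  if (k < 4 || k > 15) stop("index k must be in [4, 15]");
  XPtr<SeqIndex> p(new SeqIndex(), true);
  p->seq = seq; p->k = k;
  uint32_t kmer = 0, mask = (1u << (2 * k)) - 1;
  int valid = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2i(seq[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)b) & mask;
    if (++valid >= k) p->pos[kmer].push_back((int32_t)(i + 1 - k));
  }
  return p;
}

// [[Rcpp::export]]
int cpp_index_len(SEXP xp) {
  XPtr<SeqIndex> p(xp);
  return (int)p->seq.size();
}

// Seed-and-extend best hit: vote diagonals with indexed k-mers, run a banded
// DP around each of the top diagonal buckets, return the best-scoring hit.
// [[Rcpp::export]]
List cpp_best_hit(SEXP xp, std::string q, int band, double match,
                  double mismatch, double gap_open, double gap_ext,
                  int max_hits_per_kmer = 64, int max_buckets = 3) {
  XPtr<SeqIndex> p(xp);
  const int k = p->k;
  const long qn = (long)q.size(), m = (long)p->seq.size();
  AlnRes best; best.found = false;
  if (qn < k) return aln_to_list(best);

  const long bw = std::max(band, 16);
  std::unordered_map<long, std::pair<long, double>> votes;  // bucket -> (n, sum diag)
  uint32_t kmer = 0, mask = (1u << (2 * k)) - 1;
  int valid = 0;
  for (long i = 0; i < qn; ++i) {
    int b = base2i(q[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)b) & mask;
    if (++valid < k) continue;
    auto it = p->pos.find(kmer);
    if (it == p->pos.end()) continue;
    const std::vector<int32_t>& v = it->second;
    if ((int)v.size() > max_hits_per_kmer) continue;  // low-complexity guard
    long qpos = i + 1 - k;
    for (int32_t spos : v) {
      long diag = (long)spos - qpos;
      long bkt = (long)std::floor((double)diag / (double)bw);
      auto& e = votes[bkt];
      e.first += 1; e.second += (double)diag;
    }
  }
  if (votes.empty()) return aln_to_list(best);

  std::vector<std::pair<long, long>> ranked;  // (count, bucket)
  ranked.reserve(votes.size());
  for (auto& kv : votes) ranked.emplace_back(kv.second.first, kv.first);
  std::sort(ranked.begin(), ranked.end(), [](const std::pair<long, long>& x,
                                             const std::pair<long, long>& y) {
    return x.first > y.first || (x.first == y.first && x.second < y.second);
  });
  int nb = std::min((int)ranked.size(), max_buckets);
  bool have = false;
  for (int r = 0; r < nb; ++r) {
    // a bucket with far fewer seeds than the leader cannot beat an
    // existing hit on substitution-divergent data; skip the extra DP
    if (have && ranked[r].first * 4 < ranked[0].first) break;
    auto& e = votes[ranked[r].second];
    long center = (long)std::llround(e.second / (double)e.first);
    long ws = std::max(0L, center - 2L * band);
    long we = std::min(m, center + qn + 2L * band);
    if (we <= ws) continue;
    std::string win = p->seq.substr((size_t)ws, (size_t)(we - ws));
    long c_local = center - ws;
    AlnRes a = sw_core(q, win, match, mismatch, gap_open, gap_ext,
                       c_local - band, c_local + band);
    if (!a.found) continue;
    a.ss += ws; a.se += ws;
    if (!have || a.score > best.score ||
        (a.score == best.score &&
         (a.qs < best.qs || (a.qs == best.qs && a.ss < best.ss)))) {
      best = a; have = true;
    }
  }
  return aln_to_list(best);
}

// Batched best-hit mapping of a read pool against one indexed subject.
// Returns one row per read: found, score, s_start, s_end, matches, columns.
// [[Rcpp::export]]
NumericMatrix cpp_map_reads(SEXP xp, CharacterVector reads, int band,
                            double match, double mismatch, double gap_open,
                            double gap_ext) {
  R_xlen_t n = reads.size();
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("found", "score", "s_start",
                                          "s_end", "matches", "columns");
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string q = as<std::string>(reads[i]);
    List r = cpp_best_hit(xp, q, band, match, mismatch, gap_open, gap_ext,
                          64, 3);
    out(i, 0) = as<bool>(r["found"]) ? 1.0 : 0.0;
    out(i, 1) = as<double>(r["score"]);
    out(i, 2) = as<double>(r["s_start"]);
    out(i, 3) = as<double>(r["s_end"]);
    out(i, 4) = as<double>(r["matches"]);
    out(i, 5) = as<double>(r["columns"]);
  }
  return out;
}

// Order-m Markov chain over {A,C,G,T}. w has 4^order rows (contexts in
// lexicographic order, most recent base varying fastest) and 4 columns.
// u supplies one uniform deviate per emitted base; init gives the first
// `order` bases as 0..3 codes.
// [[Rcpp::export]]
std::string cpp_markov_sim(NumericMatrix w, int order, int n,
                           NumericVector u, IntegerVector init) {
  const long nctx = (long)std::pow(4.0, order);
  if (w.nrow() != nctx || w.ncol() != 4)
    stop("transition weight matrix must be 4^order x 4");
  if ((int)init.size() != order) stop("init must supply `order` bases");
  if ((int)u.size() < n) stop("too few uniform deviates");
  std::vector<double> cum((size_t)nctx * 4);
  for (long r = 0; r < nctx; ++r) {
    double s = 0;
    for (int c = 0; c < 4; ++c) { s += w(r, c); cum[(size_t)r * 4 + c] = s; }
  }
  static const char bases[] = "ACGT";
  std::string out((size_t)n, 'A');
  long ctx = 0;
  const long ctx_mod = nctx;
  for (long i = 0; i < n; ++i) {
    int b;
    if (i < order) {
      b = init[i];
      if (b < 0 || b > 3) stop("init bases must be 0..3");
    } else {
      double uu = u[i];
      const double* c = &cum[(size_t)ctx * 4];
      double tot = c[3];
      double x = uu * tot;
      b = 0;
      while (b < 3 && x >= c[b]) ++b;
    }
    out[(size_t)i] = bases[b];
    if (order > 0) ctx = (ctx * 4 + b) % ctx_mod;
  }
  return out;
}
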