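// Block-structured affine-gap pairwise alignment.
//
// Semantics: global in the query (optionally free query ends), local in
// the target (target prefix/suffix unpenalised).  A gap of length L costs
// gap_open + L * gap_extend.  Aligned N bases score as mismatches.
//
// Two modes share one implementation:
//   * exact  -- full dynamic programme over all (i, j);
//   * banded -- shared k-mers between the sequences define a diagonal
//     range; the programme is restricted to diagonals within `band_pad`
//     of that range (seed-and-extend, as spliced aligners do).  With no
//     shared k-mer the banded mode reports no alignment.
//
// Tie-break (mirrored by the R test oracle): candidate order is
// diagonal (M), then target-side gap (It), then query-side gap (Iq); a
// later candidate replaces an earlier one only on strict improvement.
// The traceback end cell takes the smallest coordinates among maxima.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstring>
using namespace Rcpp;

static const double NEG_INF = -1e30;

enum State : unsigned char { ST_M = 0, ST_IQ = 1, ST_IT = 2, ST_START = 3 };

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;  // N or other: breaks k-mer seeds
  }
}

// diagonal range (d = j - i, 0-based) of shared k-mers; false if none
static bool seed_diagonals(const std::string& q, const std::string& t,
                           int k, int& dmin, int& dmax) {
  const int n = (int)q.size(), m = (int)t.size();
  if (n < k || m < k) return false;
  std::unordered_multimap<uint32_t, int> tidx;
  tidx.reserve(m);
  uint32_t mask = (k == 16) ? 0xffffffffu : ((1u << (2 * k)) - 1u);
  uint32_t kmer = 0; int run = 0;
  for (int j = 0; j < m; ++j) {
    int c = base_code(t[j]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)c) & mask;
    if (++run >= k) tidx.emplace(kmer, j - k + 1);
  }
  bool any = false;
  kmer = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(q[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)c) & mask;
    if (++run >= k) {
      auto range = tidx.equal_range(kmer);
      for (auto it = range.first; it != range.second; ++it) {
        int d = it->second - (i - k + 1);
        if (!any) { dmin = dmax = d; any = true; }
        else { if (d < dmin) dmin = d; if (d > dmax) dmax = d; }
      }
    }
  }
  return any;
}

// [[Rcpp::export(name = ".align_affine")]]
SEXP align_affine(std::string q, std::string t,
                  double match_score, double mismatch_penalty,
                  double gap_open, double gap_extend,
                  bool free_query_ends, double max_cells,
                  bool banded, int band_pad, int seed_k) {
  const int n = (int)q.size(), m = (int)t.size();
  if (n == 0 || m == 0) return R_NilValue;

  // diagonal band (d = j - i on 1-based DP indices equals j0 - i0 on
  // 0-based sequence positions)
  int band_lo = -n, band_hi = m;  // full range
  if (banded) {
    int dmin, dmax;
    if (!seed_diagonals(q, t, seed_k, dmin, dmax)) return R_NilValue;
    band_lo = dmin - band_pad;
    band_hi = dmax + band_pad;
    if (band_lo < -n) band_lo = -n;
    if (band_hi > m) band_hi = m;
  }
  double width = (double)band_hi - (double)band_lo + 1.0;
  if ((double)(n + 1) * (width + 2.0) > max_cells &&
      (double)(n + 1) * (double)(m + 1) > max_cells)
    stop("alignment DP budget exceeded (%d x %d cells); supply an external PSL/PAF alignment instead",
         n + 1, m + 1);

  const double go = gap_open, ge = gap_extend;
  const size_t W = (size_t)m + 1;

  std::vector<double> Mp(W, NEG_INF), Ip(W, NEG_INF), Tp(W, NEG_INF);
  std::vector<double> Mc(W, NEG_INF), Ic(W, NEG_INF), Tc(W, NEG_INF);
  std::vector<unsigned char> ptrM((size_t)(n + 1) * W),
      ptrQ((size_t)(n + 1) * W), ptrT((size_t)(n + 1) * W);

  double best = NEG_INF;
  int best_i = -1, best_j = -1;

  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    // this row's column range from the diagonal band
    int jlo = 1 + ((i + band_lo > 1) ? (i + band_lo - 1) : 0);
    int jhi = i + band_hi;
    if (jhi > m) jhi = m;
    if (jlo < 1) jlo = 1;
    if (jlo > m) break;

    // clear cells at and just outside the row's range that later reads
    // could see as stale (left edge j = jlo - 1, right edge up to jhi)
    if (jlo - 1 >= 0) { Mc[jlo - 1] = Ic[jlo - 1] = Tc[jlo - 1] = NEG_INF; }
    // previous row's stale right edge: cell j = jhi was outside row i-1's
    // range when the band shifts right
    {
      int prev_hi = (i - 1) + band_hi;
      if (prev_hi > m) prev_hi = m;
      int cl = prev_hi + 1;
      if (cl < jlo) cl = jlo;
      for (int j = cl; j <= jhi; ++j) {
        Mp[j] = Ip[j] = Tp[j] = NEG_INF;
      }
    }
    if (jhi < jlo) { std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Tp, Tc); continue; }

    // column 0: leading query gap, only while the band allows j = 0
    if (band_lo <= -i || !banded) {
      double ext = (i >= 2) ? Ip[0] - ge : NEG_INF;
      double open0 = (i == 1) ? -(go + ge) : NEG_INF;
      double v = open0;
      unsigned char p = ST_START;
      if (ext > v) { v = ext; p = ST_IQ; }
      if (free_query_ends) { Ic[0] = NEG_INF; }
      else { Ic[0] = v; ptrQ[(size_t)i * W] = p; Mc[0] = NEG_INF; Tc[0] = NEG_INF; }
    } else {
      Mc[0] = Ic[0] = Tc[0] = NEG_INF;
    }

    const bool row_can_start = free_query_ends || i == 1;
    for (int j = jlo; j <= jhi; ++j) {
      const char tc = t[j - 1];
      const bool is_match = (qc == tc) && qc != 'N';
      const double s = is_match ? match_score : -mismatch_penalty;

      double v = Mp[j - 1];
      unsigned char p = ST_M;
      if (Tp[j - 1] > v) { v = Tp[j - 1]; p = ST_IT; }
      if (Ip[j - 1] > v) { v = Ip[j - 1]; p = ST_IQ; }
      if (row_can_start && 0.0 > v) { v = 0.0; p = ST_START; }
      Mc[j] = v + s;
      ptrM[(size_t)i * W + j] = p;

      double vq = Mp[j] - go - ge;
      unsigned char pq = ST_M;
      if (Ip[j] - ge > vq) { vq = Ip[j] - ge; pq = ST_IQ; }
      Ic[j] = vq;
      ptrQ[(size_t)i * W + j] = pq;

      double vt = Mc[j - 1] - go - ge;
      unsigned char pt = ST_M;
      if (Tc[j - 1] - ge > vt) { vt = Tc[j - 1] - ge; pt = ST_IT; }
      Tc[j] = vt;
      ptrT[(size_t)i * W + j] = pt;

      if (i == n || free_query_ends) {
        if (Mc[j] > best) { best = Mc[j]; best_i = i; best_j = j; }
      }
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Tp, Tc);
  }

  if (best_i < 0 || best <= 0.0) return R_NilValue;

  // traceback from (best_i, best_j) in state M
  std::vector<int> path_q, path_t;
  std::vector<unsigned char> path_s;
  int i = best_i, j = best_j;
  unsigned char st = ST_M;
  while (true) {
    path_s.push_back(st);
    path_q.push_back(i);
    path_t.push_back(j);
    unsigned char prev;
    if (st == ST_M) prev = ptrM[(size_t)i * W + j];
    else if (st == ST_IQ) prev = ptrQ[(size_t)i * W + j];
    else prev = ptrT[(size_t)i * W + j];
    if (st == ST_M) { --i; --j; }
    else if (st == ST_IQ) { --i; }
    else { --j; }
    if (prev == ST_START) break;
    if (st == ST_M && i == 0) break;
    st = (State)prev;
  }

  int lo = (int)path_s.size() - 1, hi = 0;
  while (lo >= 0 && path_s[lo] != ST_M) --lo;
  while (hi < (int)path_s.size() && path_s[hi] != ST_M) ++hi;
  if (lo < hi) return R_NilValue;

  std::vector<int> bsize, bq, bt;
  int matches = 0, mismatches = 0;
  int q_num = 0, q_base = 0, t_num = 0, t_base = 0;
  bool in_block = false;
  unsigned char last = 255;
  for (int k2 = lo; k2 >= hi; --k2) {
    unsigned char s0 = path_s[k2];
    int qi = path_q[k2], tj = path_t[k2];
    if (s0 == ST_M) {
      if (!in_block) {
        bsize.push_back(0);
        bq.push_back(qi - 1);
        bt.push_back(tj - 1);
        in_block = true;
      }
      bsize.back() += 1;
      bool is_match = (q[qi - 1] == t[tj - 1]) && q[qi - 1] != 'N';
      if (is_match) ++matches; else ++mismatches;
    } else {
      in_block = false;
      if (s0 == ST_IQ) { ++q_base; if (last != ST_IQ) ++q_num; }
      else { ++t_base; if (last != ST_IT) ++t_num; }
    }
    last = s0;
  }

  return List::create(
      _["score"] = best,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["q_num_insert"] = q_num, _["q_base_insert"] = q_base,
      _["t_num_insert"] = t_num, _["t_base_insert"] = t_base,
      _["q_start"] = bq.front(), _["q_end"] = bq.back() + bsize.back(),
      _["t_start"] = bt.front(), _["t_end"] = bt.back() + bsize.back(),
      _["block_size"] = wrap(bsize),
      _["block_q_start"] = wrap(bq),
      _["block_t_start"] = wrap(bt));
}
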