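#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Affine-gap Smith-Waterman with a fixed, documented traceback tie-break so
// that outputs are bit-reproducible: the start cell is the first maximum in
// row-major order, and at equal scores the diagonal (match) predecessor is
// preferred over a gap in the subject ("up"), which is preferred over a gap
// in the query ("left"), which is preferred over stopping.
//
// Gap convention: a gap of length k costs open + (k - 1) * extend, so
// open == extend yields linear gap scoring.

static const double NEG_INF = -1e30;

struct SwResult {
  double score;
  int q_start, q_end, s_start, s_end;       // 1-based inclusive
  std::vector<int> aq, as;                  // residue codes, -1 = gap
  bool empty;
};

static SwResult sw_core(int n, int m,
                        const std::function<double(int, int)>& score_at,
                        double gap_open, double gap_extend) {
  // state matrices: M ends in a match column, Ix ends with a gap in the
  // subject (query residue consumed), Iy ends with a gap in the query.
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(std::max(M[at(i - 1, j - 1)], Ix[at(i - 1, j - 1)]),
                             std::max(Iy[at(i - 1, j - 1)], 0.0));
      M[at(i, j)] = diag + score_at(i - 1, j - 1);
      Ix[at(i, j)] = std::max(M[at(i - 1, j)] - gap_open,
                              Ix[at(i - 1, j)] - gap_extend);
      Iy[at(i, j)] = std::max(M[at(i, j - 1)] - gap_open,
                              Iy[at(i, j - 1)] - gap_extend);
      if (M[at(i, j)] > best) {  // strict: keeps first maximum row-major
        best = M[at(i, j)];
        bi = i; bj = j;
      }
    }
  }

  SwResult res;
  if (best <= 0.0 || bi < 0) {
    res.empty = true;
    res.score = 0.0;
    return res;
  }
  res.empty = false;
  res.score = best;
  res.q_end = bi;
  res.s_end = bj;

  // traceback (alignments always start and end in state M)
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  std::vector<int> aq, as;
  for (;;) {
    if (state == 0) {
      aq.push_back(i - 1);
      as.push_back(j - 1);
      double tgt = M[at(i, j)] - score_at(i - 1, j - 1);
      --i; --j;
      if (tgt <= 1e-9) break;  // predecessor is the local start (value 0)
      if (std::abs(M[at(i, j)] - tgt) < 1e-9) state = 0;
      else if (std::abs(Ix[at(i, j)] - tgt) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      aq.push_back(i - 1);
      as.push_back(-1);
      double tgt = Ix[at(i, j)];
      --i;
      if (std::abs(M[at(i, j)] - gap_open - tgt) < 1e-9) state = 0;
      else state = 1;  // Ix[at(i,j)] - gap_extend == tgt
    } else {
      aq.push_back(-1);
      as.push_back(j - 1);
      double tgt = Iy[at(i, j)];
      --j;
      if (std::abs(M[at(i, j)] - gap_open - tgt) < 1e-9) state = 0;
      else state = 2;
    }
  }
  res.q_start = i + 1;
  res.s_start = j + 1;
  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());
  res.aq = aq;
  res.as = as;
  return res;
}

static List sw_wrap(const SwResult& res) {
  if (res.empty) return List::create(Named("score") = 0.0,
                                     Named("empty") = true);
  return List::create(
    Named("score") = res.score,
    Named("empty") = false,
    Named("q_start") = res.q_start, Named("q_end") = res.q_end,
    Named("s_start") = res.s_start, Named("s_end") = res.s_end,
    Named("aligned_q") = IntegerVector(res.aq.begin(), res.aq.end()),
    Named("aligned_s") = IntegerVector(res.as.begin(), res.as.end()));
}

// [[Rcpp::export(name = ".sw_align_seq")]]
List sw_align_seq(IntegerVector q, IntegerVector s, NumericMatrix smat,
                  double gap_open, double gap_extend) {
  int n = q.size(), m = s.size();
  const int* qp = INTEGER(q);
  const int* sp = INTEGER(s);
  std::function<double(int, int)> sc = [&](int i, int j) {
    return smat(qp[i], sp[j]);
  };
  return sw_wrap(sw_core(n, m, sc, gap_open, gap_extend));
}

// [[Rcpp::export(name = ".sw_align_profile")]]
List sw_align_profile(NumericMatrix prof, IntegerVector s,
                      double gap_open, double gap_extend) {
  int n = prof.nrow(), m = s.size();
  const int* sp = INTEGER(s);
  std::function<double(int, int)> sc = [&](int i, int j) {
    return prof(i, sp[j]);
  };
  return sw_wrap(sw_core(n, m, sc, gap_open, gap_extend));
}
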