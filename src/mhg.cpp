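// Minimum-hypergeometric (mHG) machinery: hypergeometric tails in log space,
// the mHG score with its data-driven cutoff, and the exact p-value DP over
// the (n, b) lattice. All heavy per-candidate work lives here; R wrappers add
// argument checking and the user-facing interface.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// cumulative log-factorials 0..N
std::vector<double> lfact_table(int N) {
  std::vector<double> lf(N + 1, 0.0);
  for (int i = 2; i <= N; ++i) lf[i] = lf[i - 1] + std::log((double)i);
  return lf;
}

inline double lchoose_tab(const std::vector<double>& lf, int n, int k) {
  if (k < 0 || k > n) return R_NegInf;
  return lf[n] - lf[k] - lf[n - k];
}

// log P(X >= b), X ~ Hypergeometric(N, B, n): sum the pmf upward from b
// with a multiplicative recurrence, then log-sum-exp.
double log_hgt_tab(const std::vector<double>& lf, int b, int N, int B, int n) {
  int lo = std::max(0, n - (N - B));
  int hi = std::min(n, B);
  if (b <= lo) return 0.0;      // event is certain
  if (b > hi) return R_NegInf;  // event is impossible
  double lt = lchoose_tab(lf, B, b) + lchoose_tab(lf, N - B, n - b) -
              lchoose_tab(lf, N, n);
  double lmax = lt;
  std::vector<double> terms;
  terms.reserve(hi - b + 1);
  terms.push_back(lt);
  for (int i = b; i < hi; ++i) {
    lt += std::log((double)(B - i)) + std::log((double)(n - i)) -
          std::log((double)(i + 1)) - std::log((double)(N - B - n + i + 1));
    terms.push_back(lt);
    if (lt > lmax) lmax = lt;
  }
  double s = 0.0;
  for (size_t j = 0; j < terms.size(); ++j) s += std::exp(terms[j] - lmax);
  double res = lmax + std::log(s);
  return res > 0.0 ? 0.0 : res;
}

inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = (a > b) ? a : b;
  double o = (a > b) ? b : a;
  return m + std::log1p(std::exp(o - m));
}

// mHG score of one label vector, given the 1-based ranks of its ones.
// The minimum over cutoffs n in 1..N-1 is only ever attained at a rank
// where the label is one (appending a zero cannot decrease the tail), so
// evaluation is restricted to those ranks. Ties keep the smallest n.
void mhg_score_core(const std::vector<double>& lf, const int* ones, int B,
                    int N, double& log_score, int& n_star, int& b_star) {
  if (B == 0 || B == N) {
    log_score = 0.0;
    n_star = 1;
    b_star = (B == N) ? 1 : 0;
    return;
  }
  double lbest = 0.0;
  int bn = -1, bb = -1;
  for (int i = 0; i < B; ++i) {
    int n = ones[i];
    if (n > N - 1) break;
    int b = i + 1;
    double lh = log_hgt_tab(lf, b, N, B, n);
    if (lh < lbest) {
      lbest = lh;
      bn = n;
      bb = b;
    }
  }
  if (bn < 0) {  // flat profile: score 1, smallest attaining cutoff is n = 1
    lbest = 0.0;
    bn = 1;
    bb = (ones[0] == 1) ? 1 : 0;
  }
  log_score = lbest;
  n_star = bn;
  b_star = bb;
}

}  // namespace

// [[Rcpp::export(name = ".hgt_cpp")]]
double hgt_cpp(int b, int N, int B, int n) {
  std::vector<double> lf = lfact_table(N);
  return std::exp(log_hgt_tab(lf, b, N, B, n));
}

// fixed-cutoff tails for a batch of candidates sharing (N, n)
// [[Rcpp::export(name = ".hgt_fixed_batch_cpp")]]
NumericVector hgt_fixed_batch_cpp(IntegerVector b, IntegerVector B, int N,
                                  int n) {
  std::vector<double> lf = lfact_table(N);
  int m = b.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = std::exp(log_hgt_tab(lf, b[i], N, B[i], n));
  return out;
}

// [[Rcpp::export(name = ".mhg_score_cpp")]]
List mhg_score_cpp(IntegerVector ones, int N) {
  std::vector<double> lf = lfact_table(N);
  double ls;
  int ns, bs;
  mhg_score_core(lf, ones.begin(), ones.size(), N, ls, ns, bs);
  return List::create(_["score"] = std::exp(ls), _["log_score"] = ls,
                      _["n_star"] = ns, _["b_star"] = bs);
}

// [[Rcpp::export(name = ".mhg_score_batch_cpp")]]
NumericMatrix mhg_score_batch_cpp(List ones_list, int N) {
  std::vector<double> lf = lfact_table(N);
  int m = ones_list.size();
  NumericMatrix out(m, 4);
  for (int j = 0; j < m; ++j) {
    IntegerVector ones = ones_list[j];
    double ls;
    int ns, bs;
    mhg_score_core(lf, ones.begin(), ones.size(), N, ls, ns, bs);
    out(j, 0) = std::exp(ls);
    out(j, 1) = ls;
    out(j, 2) = ns;
    out(j, 3) = bs;
  }
  colnames(out) =
      CharacterVector::create("score", "log_score", "n_star", "b_star");
  return out;
}

// Exact mHG p-value: weighted monotone lattice paths from (0,0) to (N,B),
// zeroing every cell (n, b), n <= N-1, whose hypergeometric tail is <= the
// score. Every path either survives or first hits exactly one zeroed cell,
// so the p-value is accumulated directly as the killed path mass
//   sum over zeroed cells of W(n, b) * C(N - n, B - b) / C(N, B)
// in log space, which keeps full relative precision for very small p
// (the 1 - surviving/C formulation loses everything below ~1e-16).
// [[Rcpp::export(name = ".mhg_pvalue_cpp")]]
double mhg_pvalue_cpp(double log_score, int N, int B) {
  if (N < 1 || B < 0 || B > N) stop("invalid N or B");
  if (log_score >= 0.0) return 1.0;
  const double eps = 1e-10;  // tie tolerance on the log scale
  std::vector<double> lf = lfact_table(N);
  const double lC = lchoose_tab(lf, N, B);
  std::vector<double> lW(B + 1, R_NegInf);
  lW[0] = 0.0;
  std::vector<double> lpmf(B + 2), ltail(B + 2);
  double lacc = R_NegInf;  // log of the killed path mass / C(N, B)
  for (int n = 1; n <= N - 1; ++n) {
    int lo = std::max(0, n - (N - B));
    int hi = std::min(n, B);
    int bstart = std::max(lo, 1);
    for (int b = hi; b >= bstart; --b) lW[b] = lse2(lW[b], lW[b - 1]);
    for (int b = 0; b < lo; ++b) lW[b] = R_NegInf;
    lpmf[lo] = lchoose_tab(lf, B, lo) + lchoose_tab(lf, N - B, n - lo) -
               lchoose_tab(lf, N, n);
    for (int b = lo; b < hi; ++b)
      lpmf[b + 1] = lpmf[b] + std::log((double)(B - b)) +
                    std::log((double)(n - b)) - std::log((double)(b + 1)) -
                    std::log((double)(N - B - n + b + 1));
    ltail[hi] = lpmf[hi];
    for (int b = hi - 1; b >= lo; --b) ltail[b] = lse2(lpmf[b], ltail[b + 1]);
    for (int b = lo; b <= hi; ++b) {
      double lt = (ltail[b] > 0.0) ? 0.0 : ltail[b];
      if (lt <= log_score + eps && lW[b] != R_NegInf) {
        lacc = lse2(lacc, lW[b] + lchoose_tab(lf, N - n, B - b) - lC);
        lW[b] = R_NegInf;
      }
    }
  }
  if (lacc == R_NegInf) return 0.0;
  double p = std::exp(lacc > 0.0 ? 0.0 : lacc);
  if (p > 1.0) p = 1.0;
  return p;
}
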