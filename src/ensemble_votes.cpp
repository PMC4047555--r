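#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-subsample voting for the three base classifiers, over all test sites at
// once. X0/X1: training feature matrices for class omega0 (SoM) / omega1
// (nonSoM); Tm: test matrix; S: j x q matrix of 1-based feature indices (one
// row per subclassifier). Returns the omega0 vote count per test row
// (half-votes possible when a Dirac subclassifier finds no match in either
// class). tie_som: 1 = exact nonzero ties vote omega0, 0 = omega1.
//
// Conditionals are compared in the log domain; the Gaussian normalisation
// constant and the class priors are equal across classes and cancel.

static inline double logsumexp_mean(const std::vector<double>& expo) {
  double m = expo[0];
  for (double e : expo) if (e > m) m = e;
  double s = 0.0;
  for (double e : expo) s += std::exp(e - m);
  return m + std::log(s) - std::log((double)expo.size());
}

// [[Rcpp::export]]
NumericVector ensemble_votes_cpp(IntegerMatrix X0, IntegerMatrix X1,
                                 IntegerMatrix Tm, IntegerMatrix S,
                                 std::string base, double h, int tie_som) {
  const int N0 = X0.nrow(), N1 = X1.nrow(), nt = Tm.nrow();
  const int L = Tm.ncol(), j = S.nrow(), q = S.ncol();
  if (X0.ncol() != L || X1.ncol() != L)
    stop("training and test vectors differ in length");
  if (N0 < 1 || N1 < 1) stop("both classes must be non-empty");
  NumericVector votes0(nt);

  const double tie_vote = tie_som ? 1.0 : 0.0;

  if (base == "nb") {
    // C_l depends only on the column and the test value, not the subsample:
    // count per column once per test item, then sum logs per subsample.
    std::vector<double> lp0(L), lp1(L);
    const double ld0 = std::log((double)N0 + 2.0), ld1 = std::log((double)N1 + 2.0);
    for (int i = 0; i < nt; ++i) {
      for (int l = 0; l < L; ++l) {
        int c0 = 0, c1 = 0, tv = Tm(i, l);
        for (int k = 0; k < N0; ++k) if (X0(k, l) == tv) ++c0;
        for (int k = 0; k < N1; ++k) if (X1(k, l) == tv) ++c1;
        lp0[l] = std::log((double)c0 + 1.0) - ld0;
        lp1[l] = std::log((double)c1 + 1.0) - ld1;
      }
      double v = 0.0;
      for (int s = 0; s < j; ++s) {
        double a = 0.0, b = 0.0;
        for (int c = 0; c < q; ++c) {
          int l = S(s, c) - 1;
          a += lp0[l]; b += lp1[l];
        }
        if (a > b) v += 1.0;
        else if (a == b) v += tie_vote;
      }
      votes0[i] = v;
    }
  } else if (base == "prw") {
    if (h <= 0) stop("bandwidth h must be > 0");
    const double inv2h2 = 1.0 / (2.0 * h * h);
    std::vector<double> e0(N0), e1(N1);
    for (int i = 0; i < nt; ++i) {
      double v = 0.0;
      for (int s = 0; s < j; ++s) {
        for (int k = 0; k < N0; ++k) {
          double d2 = 0.0;
          for (int c = 0; c < q; ++c) {
            int l = S(s, c) - 1;
            double diff = (double)Tm(i, l) - (double)X0(k, l);
            d2 += diff * diff;
          }
          e0[k] = -d2 * inv2h2;
        }
        for (int k = 0; k < N1; ++k) {
          double d2 = 0.0;
          for (int c = 0; c < q; ++c) {
            int l = S(s, c) - 1;
            double diff = (double)Tm(i, l) - (double)X1(k, l);
            d2 += diff * diff;
          }
          e1[k] = -d2 * inv2h2;
        }
        double a = logsumexp_mean(e0), b = logsumexp_mean(e1);
        if (a > b) v += 1.0;
        else if (a == b) v += tie_vote;
      }
      votes0[i] = v;
    }
  } else if (base == "rascal") {
    for (int i = 0; i < nt; ++i) {
      double v = 0.0;
      for (int s = 0; s < j; ++s) {
        long long m0 = 0, m1 = 0;
        for (int k = 0; k < N0; ++k) {
          bool eq = true;
          for (int c = 0; c < q; ++c) {
            int l = S(s, c) - 1;
            if (X0(k, l) != Tm(i, l)) { eq = false; break; }
          }
          if (eq) ++m0;
        }
        for (int k = 0; k < N1; ++k) {
          bool eq = true;
          for (int c = 0; c < q; ++c) {
            int l = S(s, c) - 1;
            if (X1(k, l) != Tm(i, l)) { eq = false; break; }
          }
          if (eq) ++m1;
        }
        if (m0 == 0 && m1 == 0) { v += 0.5; continue; }  // undetermined: half-vote
        long long lhs = m0 * (long long)N1, rhs = m1 * (long long)N0;
        if (lhs > rhs) v += 1.0;
        else if (lhs == rhs) v += tie_vote;
      }
      votes0[i] = v;
    }
  } else {
    stop("unknown base classifier '%s'", base.c_str());
  }
  return votes0;
}
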