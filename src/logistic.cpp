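// Newton/IRLS logistic regression on aggregated genotype-by-status count
// tables.  A case-control scan with an additive genotype term (plus at most
// one additive covariate genotype) only depends on the data through the
// counts in at most 3 x 3 cells, so each per-site fit works on <= 9
// weighted rows instead of thousands of individuals.  Wald statistics are
// reported for the genotype coefficient; the log-likelihoods of the fitted
// and genotype-free models support a likelihood-ratio alternative.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const int MAXP = 3;       // intercept + genotype + optional covariate
const double BIG_BETA = 15.0;

// Solve A x = b in place for p <= 3 (A symmetric positive definite).
// Returns false if a pivot collapses (collinear / degenerate design).
bool solve_small(double A[MAXP][MAXP], double b[MAXP], int p, double x[MAXP]) {
  double M[MAXP][MAXP + 1];
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) M[i][j] = A[i][j];
    M[i][p] = b[i];
  }
  for (int c = 0; c < p; ++c) {
    int piv = c;
    for (int r = c + 1; r < p; ++r) if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
    if (std::fabs(M[piv][c]) < 1e-12) return false;
    if (piv != c) for (int j = c; j <= p; ++j) std::swap(M[c][j], M[piv][j]);
    for (int r = 0; r < p; ++r) {
      if (r == c) continue;
      double fac = M[r][c] / M[c][c];
      for (int j = c; j <= p; ++j) M[r][j] -= fac * M[c][j];
    }
  }
  for (int i = 0; i < p; ++i) x[i] = M[i][p] / M[i][i];
  return true;
}

bool invert_small(double A[MAXP][MAXP], int p, double Ainv[MAXP][MAXP]) {
  for (int c = 0; c < p; ++c) {
    double e[MAXP] = {0, 0, 0}, x[MAXP];
    e[c] = 1.0;
    if (!solve_small(A, e, p, x)) return false;
    for (int r = 0; r < p; ++r) Ainv[r][c] = x[r];
  }
  return true;
}

struct FitResult {
  double beta[MAXP];
  double se_g;        // Wald SE of the genotype coefficient (index g_idx)
  double loglik;
  bool converged, separated, singular;
};

// Weighted logistic fit.  X is K x p (row-major pointer access through a
// lambda), y = case counts, n = totals.  g_idx marks the genotype column
// for SE extraction; g_idx < 0 means no single coefficient of interest.
FitResult fit_counts(int K, int p, const double *X, const double *y, const double *n,
                     int g_idx) {
  FitResult out;
  for (int j = 0; j < p; ++j) out.beta[j] = 0.0;
  out.se_g = NA_REAL; out.loglik = NA_REAL;
  out.converged = false; out.separated = false; out.singular = false;

  double beta[MAXP] = {0, 0, 0};
  for (int it = 0; it < 100; ++it) {
    double score[MAXP] = {0, 0, 0};
    double info[MAXP][MAXP] = {{0}};
    for (int k = 0; k < K; ++k) {
      double eta = 0;
      for (int j = 0; j < p; ++j) eta += X[k * p + j] * beta[j];
      double mu = 1.0 / (1.0 + std::exp(-eta));
      double w = n[k] * mu * (1.0 - mu);
      double r = y[k] - n[k] * mu;
      for (int j = 0; j < p; ++j) {
        score[j] += X[k * p + j] * r;
        for (int l = j; l < p; ++l) info[j][l] += X[k * p + j] * X[k * p + l] * w;
      }
    }
    for (int j = 0; j < p; ++j)
      for (int l = 0; l < j; ++l) info[j][l] = info[l][j];

    double delta[MAXP];
    if (!solve_small(info, score, p, delta)) { out.singular = true; break; }
    double maxd = 0;
    for (int j = 0; j < p; ++j) { beta[j] += delta[j]; maxd = std::max(maxd, std::fabs(delta[j])); }
    if (maxd < 1e-10) { out.converged = true; break; }
    bool runaway = false;
    for (int j = 0; j < p; ++j) if (std::fabs(beta[j]) > BIG_BETA) runaway = true;
    if (runaway) { out.separated = true; break; }
  }
  if (!out.converged && !out.separated && !out.singular) out.separated = true;

  for (int j = 0; j < p; ++j) out.beta[j] = beta[j];
  double ll = 0;
  for (int k = 0; k < K; ++k) {
    double eta = 0;
    for (int j = 0; j < p; ++j) eta += X[k * p + j] * beta[j];
    double lse = (eta > 0) ? eta + std::log1p(std::exp(-eta)) : std::log1p(std::exp(eta));
    ll += y[k] * eta - n[k] * lse;
  }
  out.loglik = ll;

  if (out.converged && g_idx >= 0) {
    double info[MAXP][MAXP] = {{0}};
    for (int k = 0; k < K; ++k) {
      double eta = 0;
      for (int j = 0; j < p; ++j) eta += X[k * p + j] * beta[j];
      double mu = 1.0 / (1.0 + std::exp(-eta));
      double w = n[k] * mu * (1.0 - mu);
      for (int j = 0; j < p; ++j)
        for (int l = j; l < p; ++l) info[j][l] += X[k * p + j] * X[k * p + l] * w;
    }
    for (int j = 0; j < p; ++j)
      for (int l = 0; l < j; ++l) info[j][l] = info[l][j];
    double inv[MAXP][MAXP];
    if (invert_small(info, p, inv) && inv[g_idx][g_idx] > 0)
      out.se_g = std::sqrt(inv[g_idx][g_idx]);
    else
      out.singular = true;
  }
  return out;
}

}  // namespace

// Per-site additive logistic scan on aggregated tables.
// case_counts, ctrl_counts: S x K matrices of cell counts.
// gval: K genotype values (0/1/2); cval: K covariate genotype values or NULL.
// Returns beta, se, loglik of full fit and loglik of the genotype-free fit
// (intercept [+ covariate] only) for likelihood-ratio testing.
// [[Rcpp::export(name = ".logit_scan_counts")]]
List logit_scan_counts(NumericMatrix case_counts, NumericMatrix ctrl_counts,
                       NumericVector gval, Nullable<NumericVector> cval) {
  const int S = case_counts.nrow(), K = case_counts.ncol();
  if (ctrl_counts.nrow() != S || ctrl_counts.ncol() != K)
    stop("count matrices must agree");
  bool has_cov = cval.isNotNull();
  NumericVector cv;
  if (has_cov) cv = cval.get();
  const int p = has_cov ? 3 : 2;

  NumericVector beta(S), se(S), ll_full(S), ll_null(S);
  LogicalVector converged(S), separated(S), singular(S);

  std::vector<double> X(K * 3), X0(K * 2), y(K), n(K);
  for (int s = 0; s < S; ++s) {
    int kk = 0;
    for (int k = 0; k < K; ++k) {
      double tot = case_counts(s, k) + ctrl_counts(s, k);
      if (tot <= 0) continue;
      X[kk * p + 0] = 1.0;
      X[kk * p + 1] = gval[k];
      if (has_cov) X[kk * p + 2] = cv[k];
      X0[kk * (p - 1) + 0] = 1.0;
      if (has_cov) X0[kk * (p - 1) + 1] = cv[k];
      y[kk] = case_counts(s, k);
      n[kk] = tot;
      ++kk;
    }
    FitResult full = fit_counts(kk, p, X.data(), y.data(), n.data(), 1);
    FitResult null0 = fit_counts(kk, p - 1, X0.data(), y.data(), n.data(), -1);
    beta[s] = full.beta[1];
    se[s] = full.se_g;
    ll_full[s] = full.loglik;
    ll_null[s] = null0.loglik;
    converged[s] = full.converged && !full.singular;
    separated[s] = full.separated;
    singular[s] = full.singular;
  }
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["loglik"] = ll_full, _["loglik_null"] = ll_null,
                      _["converged"] = converged, _["separated"] = separated,
                      _["singular"] = singular);
}
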