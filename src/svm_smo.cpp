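// Minimal C-SVC solver (SMO with maximal-violating-pair working-set
// selection, as in libSVM) specialised for small-n pattern classification
// on a precomputed linear Gram matrix.  Precomputing the Gram matrix once
// lets leave-one-out cross-validation and label-permutation nulls reuse it
// across thousands of refits, which is what makes whole-null calibration
// studies tractable on one CPU.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double TAU = 1e-12;

// Train C-SVC on the subset `idx` of a precomputed kernel.
// y must be +1/-1.  Returns alpha*y (signed coefficients) and rho.
void smo_train(const NumericMatrix &K, const std::vector<int> &idx,
               const std::vector<double> &y, double C, double tol,
               std::vector<double> &coef, double &rho) {
  const int n = (int)idx.size();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  const int max_iter = std::max(10000000, 100 * n);
  int iter = 0;
  while (iter++ < max_iter) {
    // second-order working-set selection (libSVM WSS2):
    // i maximises the violation, j minimises the quadratic gain with i
    int i = -1, j = -1;
    double gmax = -INFINITY, gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      bool up = (y[idx[t]] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      double v = -y[idx[t]] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
    }
    if (i < 0) break;
    const int gi_sel = idx[i];
    double best_obj = INFINITY;
    for (int t = 0; t < n; ++t) {
      bool low = (y[idx[t]] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!low) continue;
      double v = -y[idx[t]] * G[t];
      if (v < gmin) gmin = v;
      double b = gmax - v;
      if (b > 0) {
        double a = K(gi_sel, gi_sel) + K(idx[t], idx[t]) -
                   2.0 * K(gi_sel, idx[t]);
        if (a <= 0) a = TAU;
        double obj = -(b * b) / a;
        if (obj < best_obj) { best_obj = obj; j = t; }
      }
    }
    if (j < 0 || gmax - gmin < tol) break;

    const int gi = idx[i], gj = idx[j];
    const double yi = y[gi], yj = y[gj];
    const double Kii = K(gi, gi), Kjj = K(gj, gj), Kij = K(gi, gj);
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = TAU;

    const double old_ai = alpha[i], old_aj = alpha[j];
    if (yi != yj) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      const int gt = idx[t];
      G[t] += y[gt] * (yi * K(gt, gi) * dai + yj * K(gt, gj) * daj);
    }
  }

  // rho: average -y G over free support vectors, midpoint of bounds otherwise
  double ub = INFINITY, lb = -INFINITY, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[idx[t]] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { sum_free += yG; ++n_free; }
    else if ((y[idx[t]] > 0 && alpha[t] == 0) || (y[idx[t]] < 0 && alpha[t] == C)) {
      ub = std::min(ub, yG);
    } else {
      lb = std::max(lb, yG);
    }
  }
  rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  coef.assign(n, 0.0);
  for (int t = 0; t < n; ++t) coef[t] = alpha[t] * y[idx[t]];
}

// decision value for sample g given a model trained on idx
double decision(const NumericMatrix &K, const std::vector<int> &idx,
                const std::vector<double> &coef, double rho, int g) {
  double f = 0.0;
  for (size_t t = 0; t < idx.size(); ++t) f += coef[t] * K(idx[t], g);
  return f - rho;
}

double loocv_accuracy(const NumericMatrix &K, const std::vector<double> &y,
                      double C, double tol) {
  const int n = (int)y.size();
  std::vector<int> idx(n - 1);
  std::vector<double> coef;
  double rho;
  int n_correct = 0;
  for (int held = 0; held < n; ++held) {
    int k = 0;
    for (int t = 0; t < n; ++t) if (t != held) idx[k++] = t;
    smo_train(K, idx, y, C, tol, coef, rho);
    const double f = decision(K, idx, coef, rho, held);
    // ties (f == 0) count as errors: no vote for either class
    if (f * y[held] > 0) ++n_correct;
  }
  return (double)n_correct / n;
}

} // namespace

// [[Rcpp::export(name = ".svm_decision_values")]]
NumericVector svm_decision_values(NumericMatrix K, NumericVector y,
                                  double C, double tol = 1e-3) {
  const int n = y.size();
  std::vector<int> idx(n);
  std::vector<double> yy(y.begin(), y.end());
  for (int t = 0; t < n; ++t) idx[t] = t;
  std::vector<double> coef;
  double rho;
  smo_train(K, idx, yy, C, tol, coef, rho);
  NumericVector out(n);
  for (int g = 0; g < n; ++g) out[g] = decision(K, idx, coef, rho, g);
  return out;
}

// [[Rcpp::export(name = ".svm_loocv")]]
List svm_loocv(NumericMatrix K, NumericVector y, double C, double tol = 1e-3) {
  const int n = y.size();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<int> idx(n - 1);
  std::vector<double> coef;
  double rho;
  NumericVector pred(n);
  int n_correct = 0;
  for (int held = 0; held < n; ++held) {
    int k = 0;
    for (int t = 0; t < n; ++t) if (t != held) idx[k++] = t;
    smo_train(K, idx, yy, C, tol, coef, rho);
    const double f = decision(K, idx, coef, rho, held);
    pred[held] = (f > 0) ? 1.0 : -1.0;
    if (f * yy[held] > 0) ++n_correct;
  }
  return List::create(_["predicted"] = pred,
                      _["accuracy"] = (double)n_correct / n);
}

// Full LOOCV accuracy for each column of a permutation matrix of +1/-1
// labels (n x n_perm).  Returns the vector of null accuracies.
// [[Rcpp::export(name = ".svm_loocv_perm")]]
NumericVector svm_loocv_perm(NumericMatrix K, IntegerMatrix perm_labels,
                             double C, double tol = 1e-3) {
  const int n = perm_labels.nrow(), n_perm = perm_labels.ncol();
  NumericVector acc(n_perm);
  std::vector<double> y(n);
  for (int p = 0; p < n_perm; ++p) {
    for (int t = 0; t < n; ++t) y[t] = (double)perm_labels(t, p);
    acc[p] = loocv_accuracy(K, y, C, tol);
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return acc;
}
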