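// Sequential minimal optimization for a binary, per-sample-weighted C-SVC.
// Working-set selection is first order for i, second order for j (libsvm
// WSS2), with periodic shrinking of bound variables and gradient
// reconstruction before the final convergence check. Kernel rows are
// computed lazily and cached. Follows the standard dual formulation
//   min 1/2 a' Q a - e' a,  0 <= a_i <= C_i,  y' a = 0,
// with Q_ij = y_i y_j K(x_i, x_j).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

enum KernelType { LINEAR = 0, RBF = 1, POLY = 2, SIGMOID = 3 };

struct Kernel {
  const double *X;
  int n, d, type, degree;
  double gamma, coef0;

  double dot(int i, int j) const {
    double s = 0.0;
    for (int k = 0; k < d; ++k) s += X[i + (size_t)k * n] * X[j + (size_t)k * n];
    return s;
  }
  double sqdist(int i, int j) const {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double t = X[i + (size_t)k * n] - X[j + (size_t)k * n];
      s += t * t;
    }
    return s;
  }
  double k(int i, int j) const {
    switch (type) {
      case LINEAR: return dot(i, j);
      case RBF: return std::exp(-gamma * sqdist(i, j));
      case POLY: return std::pow(gamma * dot(i, j) + coef0, degree);
      default: return std::tanh(gamma * dot(i, j) + coef0);
    }
  }
};

// [[Rcpp::export(name = ".svm_smo_train")]]
List svm_smo_train(NumericMatrix X, IntegerVector y, NumericVector Ci,
                   int kernel, double gamma, double coef0, int degree,
                   double tol = 1e-3, int max_iter = 200000) {
  const int n = X.nrow();
  Kernel K{REAL(X), n, X.ncol(), kernel, degree, gamma, coef0};
  const double TAU = 1e-12;
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> alpha(n, 0.0), G(n, -1.0), QD(n);
  for (int t = 0; t < n; ++t) QD[t] = K.k(t, t);

  // lazy kernel-row cache (row t holds y_t * y_j * K_tj for all j)
  std::vector<std::vector<double> > Qrow(n);
  auto get_row = [&](int t) -> const std::vector<double> & {
    if (Qrow[t].empty()) {
      Qrow[t].resize(n);
      for (int j = 0; j < n; ++j) Qrow[t][j] = y[t] * y[j] * K.k(t, j);
    }
    return Qrow[t];
  };

  std::vector<int> active(n);
  for (int t = 0; t < n; ++t) active[t] = t;
  bool unshrink_done = false;
  int shrink_counter = std::min(n, 1000);

  auto at_upper = [&](int t) { return alpha[t] >= Ci[t] - 1e-12; };
  auto at_lower = [&](int t) { return alpha[t] <= 1e-12; };

  // reconstruct the gradient of every inactive variable from the SVs
  auto reconstruct = [&]() {
    std::vector<char> is_active(n, 0);
    for (size_t a = 0; a < active.size(); ++a) is_active[active[a]] = 1;
    for (int t = 0; t < n; ++t) {
      if (is_active[t]) continue;
      double g = -1.0;
      for (int j = 0; j < n; ++j)
        if (alpha[j] > 0) g += alpha[j] * y[t] * y[j] * K.k(t, j);
      G[t] = g;
    }
    active.resize(n);
    for (int t = 0; t < n; ++t) active[t] = t;
  };

  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    if (--shrink_counter == 0) {
      shrink_counter = std::min(n, 1000);
      // libsvm-style shrinking of variables stuck at a bound
      double Gmax1 = -INF, Gmax2 = -INF;  // over I_up, I_low
      for (size_t a = 0; a < active.size(); ++a) {
        int t = active[a];
        bool in_up = (y[t] == 1) ? !at_upper(t) : !at_lower(t);
        bool in_low = (y[t] == 1) ? !at_lower(t) : !at_upper(t);
        if (in_up && -y[t] * G[t] > Gmax1) Gmax1 = -y[t] * G[t];
        if (in_low && y[t] * G[t] > Gmax2) Gmax2 = y[t] * G[t];
      }
      if (!unshrink_done && Gmax1 + Gmax2 <= tol * 10) {
        unshrink_done = true;
        reconstruct();
      } else {
        std::vector<int> keep;
        keep.reserve(active.size());
        for (size_t a = 0; a < active.size(); ++a) {
          int t = active[a];
          bool shrunk;
          if (at_upper(t))
            shrunk = (y[t] == 1) ? (-G[t] > Gmax1) : (-G[t] > Gmax2);
          else if (at_lower(t))
            shrunk = (y[t] == 1) ? (G[t] > Gmax2) : (G[t] > Gmax1);
          else shrunk = false;
          if (!shrunk) keep.push_back(t);
        }
        if (keep.size() >= 2) active.swap(keep);
      }
    }

    // first index: maximal violator in I_up; second index: the I_low
    // violator giving the largest second-order gain
    double gmax = -INF, gmin = INF;
    int i = -1;
    for (size_t a = 0; a < active.size(); ++a) {
      int t = active[a];
      double v = -y[t] * G[t];
      bool in_up = (y[t] == 1) ? !at_upper(t) : !at_lower(t);
      bool in_low = (y[t] == 1) ? !at_lower(t) : !at_upper(t);
      if (in_up && v > gmax) { gmax = v; i = t; }
      if (in_low && v < gmin) gmin = v;
    }
    if (i < 0 || gmax - gmin < tol) {
      if (!unshrink_done || active.size() < (size_t)n) {
        // optimal on the active set: verify on the full problem
        unshrink_done = true;
        reconstruct();
        shrink_counter = std::min(n, 1000);
        continue;
      }
      converged = true;
      break;
    }

    const std::vector<double> &Qi = get_row(i);
    int j = -1;
    double best_obj = 0.0;
    for (size_t a = 0; a < active.size(); ++a) {
      int t = active[a];
      bool in_low = (y[t] == 1) ? !at_lower(t) : !at_upper(t);
      if (!in_low) continue;
      double v = -y[t] * G[t];
      double grad_diff = gmax - v;
      if (grad_diff <= 0) continue;
      double kit = y[i] * y[t] * Qi[t];  // K(i, t)
      double aq = QD[i] + QD[t] - 2.0 * kit;
      if (aq <= 0) aq = TAU;
      double obj = -(grad_diff * grad_diff) / aq;
      if (obj < best_obj) { best_obj = obj; j = t; }
    }
    if (j < 0) {
      if (!unshrink_done || active.size() < (size_t)n) {
        unshrink_done = true;
        reconstruct();
        shrink_counter = std::min(n, 1000);
        continue;
      }
      converged = true;
      break;
    }
    const std::vector<double> &Qj = get_row(j);
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = QD[i] + QD[j] + 2.0 * Qi[j];
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > Ci[i] - Ci[j]) {
        if (alpha[i] > Ci[i]) { alpha[i] = Ci[i]; alpha[j] = Ci[i] - diff; }
      } else {
        if (alpha[j] > Ci[j]) { alpha[j] = Ci[j]; alpha[i] = Ci[j] + diff; }
      }
    } else {
      double quad = QD[i] + QD[j] - 2.0 * Qi[j];
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > Ci[i]) {
        if (alpha[i] > Ci[i]) { alpha[i] = Ci[i]; alpha[j] = sum - Ci[i]; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > Ci[j]) {
        if (alpha[j] > Ci[j]) { alpha[j] = Ci[j]; alpha[i] = sum - Ci[j]; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (size_t a = 0; a < active.size(); ++a) {
      int t = active[a];
      G[t] += Qi[t] * dai + Qj[t] * daj;
    }
    ++iter;
  }
  if (!converged) reconstruct();

  // rho such that f(x) = sum_i alpha_i y_i K(x_i, x) - rho
  double ub = INF, lb = -INF, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (at_upper(t)) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (at_lower(t)) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++n_free; sum_free += yG; }
  }
  double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iterations"] = iter,
                      _["converged"] = converged);
}

// [[Rcpp::export(name = ".svm_smo_decision")]]
NumericVector svm_smo_decision(NumericMatrix Xtrain, IntegerVector y,
                               NumericVector alpha, double rho,
                               int kernel, double gamma, double coef0,
                               int degree, NumericMatrix Xnew) {
  const int n = Xtrain.nrow(), m = Xnew.nrow(), d = Xtrain.ncol();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double f = 0.0;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] == 0.0) continue;
      double dp = 0.0, sq = 0.0;
      for (int k = 0; k < d; ++k) {
        double a = Xtrain(i, k), b = Xnew(q, k);
        dp += a * b;
        double t = a - b;
        sq += t * t;
      }
      double kv;
      switch (kernel) {
        case LINEAR: kv = dp; break;
        case RBF: kv = std::exp(-gamma * sq); break;
        case POLY: kv = std::pow(gamma * dp + coef0, degree); break;
        default: kv = std::tanh(gamma * dp + coef0);
      }
      f += alpha[i] * y[i] * kv;
    }
    out[q] = f - rho;
  }
  return out;
}
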