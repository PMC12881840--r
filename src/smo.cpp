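// Sequential minimal optimization solver for the soft-margin C-SVC dual,
// with second-order working-set selection and a dense kernel cache.
// Decision values follow the usual convention f(x) = sum_i alpha_i y_i
// K(x_i, x) - rho, so f > 0 predicts the positive class.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TAU = 1e-12;

static inline double dot(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) s += a[k] * b[k];
  return s;
}

static inline double kern(const double* a, const double* b, int d,
                          bool rbf, double gamma) {
  if (!rbf) return dot(a, b, d);
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double t = a[k] - b[k];
    s += t * t;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".svm_smo_fit", rng = false)]]
List svm_smo_fit(NumericMatrix X, NumericVector y, double C,
                 double gamma, bool rbf, double tol = 1e-3,
                 double max_passes = 1e7) {
  const int n = X.nrow(), d = X.ncol();
  if (n < 2) stop("need at least two training points");

  // row-major copy for cache-friendly kernel evaluation
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) Xr[(size_t)i * d + k] = X(i, k);

  // full kernel cache (desk-scale cohorts: n up to a few thousand)
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xr[(size_t)i * d];
    for (int j = i; j < n; ++j) {
      double v = kern(xi, &Xr[(size_t)j * d], d, rbf, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  long long iter = 0;
  const long long iter_cap = (long long)max_passes;

  while (iter < iter_cap) {
    ++iter;
    // working-set selection: i = most violating in I_up,
    // j = second-order best in I_low
    int i = -1;
    double m_up = -HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      if (in_up) {
        double v = -y[t] * G[t];
        if (v > m_up) { m_up = v; i = t; }
      }
    }
    if (i < 0) break;

    int j = -1;
    double m_low = HUGE_VAL, obj_best = HUGE_VAL;
    const double Kii = K[(size_t)i * n + i];
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (!in_low) continue;
      double v = -y[t] * G[t];
      if (v < m_low) m_low = v;
      double b_it = m_up - v;
      if (b_it > 0) {
        double a_it = Kii + K[(size_t)t * n + t] - 2.0 * K[(size_t)i * n + t];
        if (a_it <= 0) a_it = TAU;
        double obj = -(b_it * b_it) / a_it;
        if (obj < obj_best) { obj_best = obj; j = t; }
      }
    }
    if (j < 0 || m_up - m_low < tol) break;

    // two-variable analytic update with box clipping
    const double Kjj = K[(size_t)j * n + j], Kij = K[(size_t)i * n + j];
    double a_ij = Kii + Kjj - 2.0 * Kij;
    if (a_ij <= 0) a_ij = TAU;
    const double ai_old = alpha[i], aj_old = alpha[j];
    double delta = (-y[i] * G[i] + y[j] * G[j]) / a_ij;
    double ai = ai_old + y[i] * delta;
    double aj = aj_old - y[j] * delta;

    // project back onto the feasible box preserving y_i a_i + y_j a_j
    double sum = y[i] * ai_old + y[j] * aj_old;
    if (ai < 0) ai = 0; else if (ai > C) ai = C;
    aj = y[j] * (sum - y[i] * ai);
    if (aj < 0) aj = 0; else if (aj > C) aj = C;
    ai = y[i] * (sum - y[j] * aj);
    if (ai < 0) ai = 0; else if (ai > C) ai = C;

    const double dai = ai - ai_old, daj = aj - aj_old;
    if (std::fabs(dai) < 1e-15 && std::fabs(daj) < 1e-15) break;
    alpha[i] = ai; alpha[j] = aj;
    const double ci = y[i] * dai, cj = y[j] * daj;
    const double* Ki = &K[(size_t)i * n];
    const double* Kj = &K[(size_t)j * n];
    for (int t = 0; t < n; ++t) G[t] += y[t] * (ci * Ki[t] + cj * Kj[t]);
  }

  // rho from free support vectors, else midpoint of the violating bounds
  double rho;
  int n_free = 0; double sum_free = 0.0;
  double ub = HUGE_VAL, lb = -HUGE_VAL;
  for (int t = 0; t < n; ++t) {
    double ygt = y[t] * G[t];
    bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { ++n_free; sum_free += ygt; }
    if (in_up && ygt < ub) ub = ygt;
    if (in_low && ygt > lb) lb = ygt;
  }
  rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  NumericVector coef(n);  // alpha_i * y_i
  for (int t = 0; t < n; ++t) coef[t] = alpha[t] * y[t];
  return List::create(_["coef"] = coef, _["rho"] = rho,
                      _["iterations"] = (double)iter);
}

// [[Rcpp::export(name = ".svm_decision_values", rng = false)]]
NumericVector svm_decision_values(NumericMatrix Xsv, NumericVector coef,
                                  double rho, NumericMatrix Xnew,
                                  double gamma, bool rbf) {
  const int nsv = Xsv.nrow(), d = Xsv.ncol(), m = Xnew.nrow();
  if (Xnew.ncol() != d) stop("feature dimension mismatch");
  std::vector<double> Sr((size_t)nsv * d), Nr((size_t)m * d);
  for (int i = 0; i < nsv; ++i)
    for (int k = 0; k < d; ++k) Sr[(size_t)i * d + k] = Xsv(i, k);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < d; ++k) Nr[(size_t)i * d + k] = Xnew(i, k);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const double* xi = &Nr[(size_t)i * d];
    double s = 0.0;
    for (int j = 0; j < nsv; ++j)
      if (coef[j] != 0.0)
        s += coef[j] * kern(&Sr[(size_t)j * d], xi, d, rbf, gamma);
    out[i] = s - rho;
  }
  return out;
}
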