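#include <Rcpp.h>
using namespace Rcpp;

// Weighted soft-margin C-SVC dual solver on a precomputed kernel matrix.
//
// Minimizes 0.5 * t(a*y) K (a*y) - sum(a) subject to 0 <= a_i <= C_i and
// sum(a_i y_i) = 0, by sequential minimal optimization with the maximal
// violating pair working-set rule and the standard two-variable analytic
// update. The offset rho follows the usual KKT rule (mean of y_i * G_i
// over free support vectors, interval midpoint when none are free).
// The decision value of a point x is then sum_i a_i y_i K(x, x_i) - rho,
// positive for the +1 class.
//
// [[Rcpp::export(name = ".smoSvcFit")]]
List smoSvcFit(NumericMatrix K, IntegerVector y, NumericVector C,
               double tol = 1e-6, int maxIter = 10000000) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n || C.size() != n) stop("y and C must match K");
  const double TAU = 1e-12;

  std::vector<double> a(n, 0.0), G(n, -1.0);  // gradient of the min form
  std::vector<double> Q_i(n), Q_j(n);
  int iter = 0;
  double gap = R_PosInf;

  while (iter < maxIter) {
    // maximal violating pair
    int i = -1, j = -1;
    double m = -R_PosInf, M = R_PosInf;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] == 1) ? (a[t] < C[t]) : (a[t] > 0.0);
      bool lo = (y[t] == 1) ? (a[t] > 0.0) : (a[t] < C[t]);
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    gap = m - M;
    if (i < 0 || j < 0 || gap < tol) break;

    for (int t = 0; t < n; ++t) {
      Q_i[t] = y[i] * y[t] * K(t, i);
      Q_j[t] = y[j] * y[t] * K(t, j);
    }
    double ai_old = a[i], aj_old = a[j];

    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j) * y[i] * y[j];
      // note: y_i != y_j makes Q_ij = -K_ij, so this is Kii + Kjj - 2Kij
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = a[i] - a[j];
      a[i] += delta; a[j] += delta;
      if (diff > 0) { if (a[j] < 0) { a[j] = 0; a[i] = diff; } }
      else          { if (a[i] < 0) { a[i] = 0; a[j] = -diff; } }
      if (diff > C[i] - C[j]) { if (a[i] > C[i]) { a[i] = C[i]; a[j] = C[i] - diff; } }
      else                    { if (a[j] > C[j]) { a[j] = C[j]; a[i] = C[j] + diff; } }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = a[i] + a[j];
      a[i] -= delta; a[j] += delta;
      if (sum > C[i]) { if (a[i] > C[i]) { a[i] = C[i]; a[j] = sum - C[i]; } }
      else            { if (a[j] < 0)    { a[j] = 0;    a[i] = sum; } }
      if (sum > C[j]) { if (a[j] > C[j]) { a[j] = C[j]; a[i] = sum - C[j]; } }
      else            { if (a[i] < 0)    { a[i] = 0;    a[j] = sum; } }
    }

    double dai = a[i] - ai_old, daj = a[j] - aj_old;
    if (dai == 0.0 && daj == 0.0) break;  // numerically stuck pair
    for (int t = 0; t < n; ++t) G[t] += Q_i[t] * dai + Q_j[t] * daj;
    ++iter;
  }

  // offset
  double ub = R_PosInf, lb = -R_PosInf, sumFree = 0.0;
  int nFree = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (a[t] >= C[t] - 1e-12 * C[t]) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (a[t] <= 1e-12 * C[t]) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++nFree; sumFree += yG;
    }
  }
  double rho = nFree > 0 ? sumFree / nFree : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["rho"] = rho, _["iterations"] = iter,
                      _["gap"] = gap);
}
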