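#include <Rcpp.h>
using namespace Rcpp;

// Epsilon-insensitive SVR dual solved by SMO on a precomputed kernel matrix.
//
// The 2n-variable dual is min 0.5 a'Qa + p'a subject to s'a = 0, 0 <= a <= C,
// where a = (alpha, alpha*), s = (+1,...,-1,...), Q[t,u] = s_t s_u K[t%n,u%n],
// p_t = eps - y_t for the alpha block and eps + y_t for the alpha* block.
// Working-set selection is second order (maximal violating index i, then the
// maximal-gain partner j), and the two-variable update with bound clipping
// follows the standard libsvm solver; the pair curvature in real-kernel terms
// is K_ii + K_jj - 2 K_ij in both label branches. Returns the net dual
// coefficients beta = alpha - alpha* (prediction f(x) = sum_i beta_i K(x_i,x)
// + b), interchangeable with any libsvm-family SVR trained on the same
// kernel.
//
// [[Rcpp::export(name = ".smo_svr")]]
List smo_svr(NumericMatrix K, NumericVector y, double C, double eps,
             double tol = 1e-3, int max_iter = 200000) {
  const int n = y.size();
  if (K.nrow() != n || K.ncol() != n)
    stop("kernel matrix dimensions do not match y");
  const int m = 2 * n;
  std::vector<double> a(m, 0.0), G(m), s(m);
  for (int t = 0; t < m; ++t) {
    s[t] = (t < n) ? 1.0 : -1.0;
    G[t] = (t < n) ? (eps - y[t]) : (eps + y[t - n]);
  }
  const double tau = 1e-12;
  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    // i: maximal violating index over I_up
    int i = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < m; ++t) {
      const bool up = (s[t] > 0) ? (a[t] < C) : (a[t] > 0);
      if (up) {
        const double v = -s[t] * G[t];
        if (v > gmax) { gmax = v; i = t; }
      }
    }
    if (i < 0) { converged = true; break; }
    const int ri = i % n;
    const double Kii = K(ri, ri);
    // j: maximal second-order gain over I_low with positive violation
    int j = -1;
    double best = 1e300;
    for (int t = 0; t < m; ++t) {
      const bool low = (s[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (!low) continue;
      const double v = -s[t] * G[t];
      if (v < gmin) gmin = v;
      const double gd = gmax - v;
      if (gd > 0) {
        const int rt = t % n;
        double quad = Kii + K(rt, rt) - 2.0 * K(ri, rt);
        if (quad <= 0) quad = tau;
        const double obj = -(gd * gd) / quad;
        if (obj < best) { best = obj; j = t; }
      }
    }
    if (gmax - gmin < tol || j < 0) { converged = true; break; }
    const int rj = j % n;
    const double Kjj = K(rj, rj), Kij = K(ri, rj);
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = tau;
    const double old_ai = a[i], old_aj = a[j];
    if (s[i] != s[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = a[i] - a[j];
      a[i] += delta; a[j] += delta;
      if (diff > 0) { if (a[j] < 0) { a[j] = 0; a[i] = diff; } }
      else          { if (a[i] < 0) { a[i] = 0; a[j] = -diff; } }
      if (diff > 0) { if (a[i] > C) { a[i] = C; a[j] = C - diff; } }
      else          { if (a[j] > C) { a[j] = C; a[i] = C + diff; } }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = a[i] + a[j];
      a[i] -= delta; a[j] += delta;
      if (sum > C) { if (a[i] > C) { a[i] = C; a[j] = sum - C; } }
      else         { if (a[j] < 0) { a[j] = 0; a[i] = sum; } }
      if (sum > C) { if (a[j] > C) { a[j] = C; a[i] = sum - C; } }
      else         { if (a[i] < 0) { a[i] = 0; a[j] = sum; } }
    }
    const double dai = a[i] - old_ai, daj = a[j] - old_aj;
    if (dai == 0 && daj == 0) { converged = true; break; }
    for (int t = 0; t < m; ++t) {
      const int rt = t % n;
      G[t] += s[t] * s[i] * K(rt, ri) * dai + s[t] * s[j] * K(rt, rj) * daj;
    }
  }
  // bias: average of -s_t G_t over free variables, else midpoint of bounds
  double bsum = 0; int nfree = 0;
  double ub = 1e300, lb = -1e300;
  for (int t = 0; t < m; ++t) {
    const double v = -s[t] * G[t];
    const bool up  = (s[t] > 0) ? (a[t] < C) : (a[t] > 0);
    const bool low = (s[t] > 0) ? (a[t] > 0) : (a[t] < C);
    if (a[t] > 0 && a[t] < C) { bsum += v; ++nfree; }
    if (up  && v > lb) lb = v;
    if (low && v < ub) ub = v;
  }
  const double b = nfree > 0 ? bsum / nfree : (ub + lb) / 2.0;
  NumericVector beta(n);
  for (int r = 0; r < n; ++r) beta[r] = a[r] - a[r + n];
  return List::create(_["coefs"] = beta, _["b"] = b,
                      _["iterations"] = iter, _["converged"] = converged);
}
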