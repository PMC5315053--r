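#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin linear SVM trained by SMO (maximal-violating-pair working-set
// selection) on the dual problem
//   min 1/2 a' Q a - e' a   s.t.  y' a = 0,  0 <= a <= C,
// with Q_ij = y_i y_j x_i . x_j.  Sample counts here are tiny (a handful of
// block betas per fold), so the dense Gram matrix is cheap.
//
// [[Rcpp::export(name = ".svm_smo")]]
List svm_smo(NumericMatrix X, IntegerVector y, double C,
             double tol = 1e-8, int max_iter = 100000) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("label length mismatch");

  // Gram matrix
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += X(i, k) * X(j, k);
      K[i + (size_t)n * j] = K[j + (size_t)n * i] = s;
    }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G = Q a - e
  int iter = 0;
  double m_val = 0.0, M_val = 0.0;
  for (; iter < max_iter; ++iter) {
    // working pair: i = argmax_{I_up} -y G, j = argmin_{I_low} -y G
    int i = -1, j = -1;
    m_val = -1e300; M_val = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up  = (y[t] > 0) ? (alpha[t] < C - 1e-12) : (alpha[t] > 1e-12);
      bool low = (y[t] > 0) ? (alpha[t] > 1e-12) : (alpha[t] < C - 1e-12);
      if (up && v > m_val)  { m_val = v; i = t; }
      if (low && v < M_val) { M_val = v; j = t; }
    }
    if (i < 0 || j < 0 || m_val - M_val < tol) break;

    double Kii = K[i + (size_t)n * i], Kjj = K[j + (size_t)n * j],
           Kij = K[i + (size_t)n * j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 1e-12) eta = 1e-12;
    double ai = alpha[i], aj = alpha[j];
    // u_t = sum_k a_k y_k K_tk = y_t (G_t + 1)
    double Ei = y[i] * (G[i] + 1.0) - y[i];
    double Ej = y[j] * (G[j] + 1.0) - y[j];
    double L, H;
    if (y[i] != y[j]) { L = std::max(0.0, aj - ai); H = std::min(C, C + aj - ai); }
    else              { L = std::max(0.0, ai + aj - C); H = std::min(C, ai + aj); }
    double aj_new = aj + y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = ai + y[i] * y[j] * (aj - aj_new);
    double di = ai_new - ai, dj = aj_new - aj;
    if (std::fabs(di) < 1e-15 && std::fabs(dj) < 1e-15) break;
    alpha[i] = ai_new; alpha[j] = aj_new;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * di * K[t + (size_t)n * i] +
                      y[j] * dj * K[t + (size_t)n * j]);
  }

  NumericVector w(d);
  for (int t = 0; t < n; ++t) {
    if (alpha[t] == 0.0) continue;
    double c = alpha[t] * y[t];
    for (int k = 0; k < d; ++k) w[k] += c * X(t, k);
  }
  // bias from free support vectors, else midpoint of the gradient bounds
  double b = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-9 && alpha[t] < C - 1e-9) {
      double u = y[t] * (G[t] + 1.0);
      b += y[t] - u; ++nfree;
    }
  if (nfree > 0) b /= nfree;
  else b = (m_val + M_val) / 2.0;

  return List::create(_["w"] = w, _["b"] = b,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter);
}

// Leave-one-run-out cross-decoding accuracy for one sphere, over all
// direction x fold combinations.  `feat` is samples x voxels (rows indexed
// by flat run/condition sample id); each evaluation has integer row indices
// and +/-1 labels prepared in R.
//
// [[Rcpp::export(name = ".cv_decode")]]
double cv_decode(NumericMatrix feat, List train_rows, List train_labels,
                 List test_rows, List test_labels, double C) {
  const int n_eval = train_rows.size();
  const int d = feat.ncol();
  double acc_sum = 0.0;
  for (int e = 0; e < n_eval; ++e) {
    IntegerVector tr = train_rows[e], ty = train_labels[e];
    IntegerVector te = test_rows[e],  sy = test_labels[e];
    const int ntr = tr.size(), nte = te.size();
    NumericMatrix Xtr(ntr, d);
    for (int r = 0; r < ntr; ++r)
      for (int k = 0; k < d; ++k) Xtr(r, k) = feat(tr[r] - 1, k);
    List fit = svm_smo(Xtr, ty, C);
    NumericVector w = fit["w"];
    double b = fit["b"];
    int correct = 0;
    for (int r = 0; r < nte; ++r) {
      double dec = b;
      for (int k = 0; k < d; ++k) dec += feat(te[r] - 1, k) * w[k];
      int pred = dec > 0 ? 1 : (dec < 0 ? -1 : 1);  // ties -> first class (+1)
      if (pred == sy[r]) ++correct;
    }
    acc_sum += (double)correct / nte;
  }
  return acc_sum / n_eval;
}
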