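#include <Rcpp.h>
using namespace Rcpp;

// Scale a to unit L2 norm after soft-thresholding at delta.
static void soft_unit(const std::vector<double>& a, double delta,
                      std::vector<double>& out, double& l1, double& l2) {
  l1 = 0.0;
  l2 = 0.0;
  const size_t p = a.size();
  for (size_t i = 0; i < p; ++i) {
    double x = std::fabs(a[i]) - delta;
    x = x > 0.0 ? x : 0.0;
    out[i] = (a[i] >= 0.0) ? x : -x;
    l1 += x;
    l2 += x * x;
  }
  l2 = std::sqrt(l2);
  if (l2 > 0.0) {
    for (size_t i = 0; i < p; ++i) out[i] /= l2;
    l1 /= l2;
  }
}

// argmax_u u'a  s.t. ||u||_2 <= 1, ||u||_1 <= c:  u = S(a, delta)/||S(a, delta)||_2
// with delta >= 0 found by bisection (delta = 0 when the L1 constraint is slack).
// The L1 norm of the normalized vector at a given delta is evaluated in
// O(log p) from descending-sorted |a| and its prefix sums.
static void l1_unit(const std::vector<double>& a, double c,
                    std::vector<double>& u) {
  double l1, l2;
  soft_unit(a, 0.0, u, l1, l2);
  if (l1 <= c) return;

  const size_t p = a.size();
  std::vector<double> mag(p);
  for (size_t i = 0; i < p; ++i) mag[i] = std::fabs(a[i]);
  std::sort(mag.begin(), mag.end(), std::greater<double>());
  std::vector<double> s1(p + 1, 0.0), s2(p + 1, 0.0);
  for (size_t i = 0; i < p; ++i) {
    s1[i + 1] = s1[i] + mag[i];
    s2[i + 1] = s2[i] + mag[i] * mag[i];
  }
  // ||S(a,delta)||_1 / ||S(a,delta)||_2 for the j entries exceeding delta
  auto l1_ratio = [&](double delta) {
    const size_t j = std::upper_bound(mag.begin(), mag.end(), delta,
                                      std::greater<double>()) - mag.begin();
    if (j == 0) return 0.0;
    const double num = s1[j] - j * delta;
    const double den = std::sqrt(s2[j] - 2.0 * delta * s1[j] + j * delta * delta);
    return den > 0.0 ? num / den : 0.0;
  };

  double lo = 0.0, hi = mag[0];
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    const double r = l1_ratio(mid);
    if (std::fabs(r - c) < 1e-8) { soft_unit(a, mid, u, l1, l2); return; }
    if (r > c) lo = mid; else hi = mid;
  }
  // land on the feasible side of the bracket
  soft_unit(a, hi, u, l1, l2);
}

// [[Rcpp::export(name = ".cpp_l1_constrained_unit")]]
NumericVector cpp_l1_constrained_unit(NumericVector a, double c) {
  std::vector<double> av(a.begin(), a.end()), u(a.size());
  l1_unit(av, c, u);
  return NumericVector(u.begin(), u.end());
}

// One rank-1 penalized decomposition of K (p x q): alternate
//   u <- l1_unit(K v, c1),  v <- l1_unit(K' u, c2)
// from v0 until the relative L2 change of v drops below tol.
// [[Rcpp::export(name = ".cpp_pmd_rank1")]]
List cpp_pmd_rank1(NumericMatrix K, NumericVector v0, double c1, double c2,
                   int max_iter, double tol) {
  const int p = K.nrow(), q = K.ncol();
  std::vector<double> u(p), v(v0.begin(), v0.end()), vnew(q);
  std::vector<double> Kv(p), Ktu(q);
  std::vector<double> obj;
  obj.reserve(max_iter);
  int iters = max_iter;

  for (int it = 0; it < max_iter; ++it) {
    // Kv
    std::fill(Kv.begin(), Kv.end(), 0.0);
    for (int j = 0; j < q; ++j) {
      const double vj = v[j];
      if (vj == 0.0) continue;
      const double* col = &K(0, j);
      for (int i = 0; i < p; ++i) Kv[i] += col[i] * vj;
    }
    l1_unit(Kv, c1, u);
    // K'u
    for (int j = 0; j < q; ++j) {
      const double* col = &K(0, j);
      double s = 0.0;
      for (int i = 0; i < p; ++i) s += col[i] * u[i];
      Ktu[j] = s;
    }
    l1_unit(Ktu, c2, vnew);
    // objective u'K v after this alternation
    double d = 0.0;
    for (int j = 0; j < q; ++j) d += Ktu[j] * vnew[j];
    obj.push_back(d);
    // relative change of v
    double num = 0.0, den = 0.0;
    for (int j = 0; j < q; ++j) {
      const double dv = vnew[j] - v[j];
      num += dv * dv;
      den += v[j] * v[j];
    }
    v = vnew;
    if (den > 0.0 && std::sqrt(num) / std::sqrt(den) < tol) {
      iters = it + 1;
      break;
    }
  }
  double d = obj.empty() ? 0.0 : obj.back();
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["d"] = d, _["iterations"] = iters,
                      _["objective"] = NumericVector(obj.begin(), obj.end()));
}
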