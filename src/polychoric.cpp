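#include <Rcpp.h>
using namespace Rcpp;

// Bivariate standard normal CDF P(X <= h, Y <= k) with correlation rho,
// via Sheppard's arcsine-integral form
//   Phi2(h,k,rho) = Phi(h)Phi(k)
//                   + (1/2pi) Int_0^{asin(rho)} exp(-(h^2+k^2-2hk sin t)/(2 cos^2 t)) dt,
// evaluated with fixed 48-node Gauss-Legendre quadrature.  The integrand is
// smooth for |rho| <= 0.999, giving ~1e-13 absolute accuracy.

// 48-point Gauss-Legendre nodes/weights on [-1, 1] (symmetric; positive half stored)
static const double gl_x[24] = {
  3.2380170962869603e-02,
  9.7004699209462752e-02,
  1.6122235606889190e-01,
  2.2476379039468930e-01,
  2.8736248735545533e-01,
  3.4875588629216059e-01,
  4.0868648199071689e-01,
  4.6690290475095875e-01,
  5.2316097472223300e-01,
  5.7722472608397268e-01,
  6.2886739677651371e-01,
  6.7787237963266400e-01,
  7.2403413092381474e-01,
  7.6715903251574025e-01,
  8.0706620402944274e-01,
  8.4358826162439360e-01,
  8.7657202027424785e-01,
  9.0587913671556963e-01,
  9.3138669070655422e-01,
  9.5298770316043091e-01,
  9.7059159254624716e-01,
  9.8412458372282685e-01,
  9.9353017226635076e-01,
  9.9877100725242618e-01
};
static const double gl_w[24] = {
  6.4737696812683473e-02,
  6.4466164435949380e-02,
  6.3924238584647505e-02,
  6.3114192286254561e-02,
  6.2039423159893914e-02,
  6.0704439165893929e-02,
  5.9114839698396128e-02,
  5.7277292100403443e-02,
  5.5199503699984311e-02,
  5.2890189485193528e-02,
  5.0359035553854424e-02,
  4.7616658492490596e-02,
  4.4674560856694218e-02,
  4.1545082943464810e-02,
  3.8241351065830438e-02,
  3.4777222564770616e-02,
  3.1167227832798069e-02,
  2.7426509708356795e-02,
  2.3570760839324512e-02,
  1.9616160457355706e-02,
  1.5579315722943821e-02,
  1.1477234579234401e-02,
  7.3275539012761810e-03,
  3.1533460523058051e-03
};

static double phi2_lower(double h, double k, double rho) {
  double ph = R::pnorm(h, 0.0, 1.0, 1, 0);
  double pk = R::pnorm(k, 0.0, 1.0, 1, 0);
  if (rho == 0.0) return ph * pk;
  if (rho > 0.999) rho = 0.999;
  if (rho < -0.999) rho = -0.999;
  double up = std::asin(rho);
  // map [0, up] onto the symmetric GL rule
  double c = 0.5 * up, acc = 0.0;
  for (int i = 0; i < 24; i++) {
    for (int s = -1; s <= 1; s += 2) {
      double t = c + s * c * gl_x[i];
      double st = std::sin(t), ct2 = std::cos(t) * std::cos(t);
      acc += c * gl_w[i] * std::exp(-(h * h + k * k - 2.0 * h * k * st) / (2.0 * ct2));
    }
  }
  return ph * pk + acc / (2.0 * M_PI);
}

// [[Rcpp::export(name = ".bvn_cdf_cpp")]]
NumericVector bvn_cdf_cpp(NumericVector h, NumericVector k, NumericVector rho) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = phi2_lower(h[i], k[i], rho[i]);
  return out;
}

// Cell probabilities of the discretized bivariate normal for threshold vectors
// a (rows) and b (cols); a, b are the interior thresholds.
static void cell_probs(const std::vector<double> &a, const std::vector<double> &b,
                       double rho, std::vector<double> &P) {
  int r = (int)a.size() + 1, c = (int)b.size() + 1;
  // cumulative at grid (including +inf edges)
  std::vector<double> C((r + 1) * (c + 1), 0.0);
  for (int i = 0; i <= r; i++) {
    for (int j = 0; j <= c; j++) {
      double v;
      if (i == 0 || j == 0) v = 0.0;
      else if (i == r && j == c) v = 1.0;
      else if (i == r) v = R::pnorm(b[j - 1], 0.0, 1.0, 1, 0);
      else if (j == c) v = R::pnorm(a[i - 1], 0.0, 1.0, 1, 0);
      else v = phi2_lower(a[i - 1], b[j - 1], rho);
      C[i * (c + 1) + j] = v;
    }
  }
  P.assign(r * c, 0.0);
  for (int i = 1; i <= r; i++)
    for (int j = 1; j <= c; j++)
      P[(i - 1) * c + (j - 1)] = C[i * (c + 1) + j] - C[(i - 1) * (c + 1) + j]
        - C[i * (c + 1) + (j - 1)] + C[(i - 1) * (c + 1) + (j - 1)];
}

static double table_loglik(const std::vector<double> &a, const std::vector<double> &b,
                           const std::vector<double> &n, double rho) {
  int r = (int)a.size() + 1, c = (int)b.size() + 1;
  std::vector<double> P;
  cell_probs(a, b, rho, P);
  double ll = 0.0;
  for (int i = 0; i < r * c; i++) {
    if (n[i] > 0.0) {
      double p = P[i];
      if (p < 1e-300) p = 1e-300;
      ll += n[i] * std::log(p);
    }
  }
  return ll;
}

// Golden-section + parabolic (Brent) maximization of the profile likelihood
// over rho in [lo, hi], tolerance tol.
static double brent_rho(const std::vector<double> &a, const std::vector<double> &b,
                        const std::vector<double> &n, double lo, double hi, double tol) {
  const double gold = 0.3819660112501051;
  double x, w, v, fx, fw, fv, d = 0.0, e = 0.0;
  x = w = v = lo + gold * (hi - lo);
  fx = fw = fv = -table_loglik(a, b, n, x);
  for (int iter = 0; iter < 200; iter++) {
    double xm = 0.5 * (lo + hi);
    double tol1 = tol * std::fabs(x) + 1e-12, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (hi - lo)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (lo - x) && p < q * (hi - x)) {
        d = p / q;
        double u = x + d;
        if (u - lo < tol2 || hi - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? lo - x : hi - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = -table_loglik(a, b, n, u);
    if (fu <= fx) {
      if (u >= x) lo = x; else hi = x;
      v = w; w = x; x = u; fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) lo = u; else hi = u;
      if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

// thresholds from a vector of margin counts (length = n categories)
static std::vector<double> margin_thresholds(const std::vector<double> &cnt) {
  double tot = 0.0;
  for (double v : cnt) tot += v;
  std::vector<double> th;
  double cum = 0.0;
  for (size_t i = 0; i + 1 < cnt.size(); i++) {
    cum += cnt[i];
    th.push_back(R::qnorm(cum / tot, 0.0, 1.0, 1, 0));
  }
  return th;
}

// [[Rcpp::export(name = ".polychoric_table_cpp")]]
List polychoric_table_cpp(NumericMatrix tab, double rho_max, double tol) {
  int r = tab.nrow(), c = tab.ncol();
  std::vector<double> rowc(r, 0.0), colc(c, 0.0), n(r * c);
  for (int i = 0; i < r; i++)
    for (int j = 0; j < c; j++) {
      rowc[i] += tab(i, j);
      colc[j] += tab(i, j);
      n[i * c + j] = tab(i, j);
    }
  // drop empty margins
  std::vector<double> rc, cc;
  std::vector<int> rkeep, ckeep;
  for (int i = 0; i < r; i++) if (rowc[i] > 0) { rc.push_back(rowc[i]); rkeep.push_back(i); }
  for (int j = 0; j < c; j++) if (colc[j] > 0) { cc.push_back(colc[j]); ckeep.push_back(j); }
  bool degenerate = (rc.size() < 2 || cc.size() < 2);
  if (degenerate)
    return List::create(_["rho"] = NA_REAL, _["degenerate"] = true,
                        _["loglik"] = NA_REAL);
  std::vector<double> n2(rc.size() * cc.size());
  for (size_t i = 0; i < rkeep.size(); i++)
    for (size_t j = 0; j < ckeep.size(); j++)
      n2[i * cc.size() + j] = tab(rkeep[i], ckeep[j]);
  std::vector<double> a = margin_thresholds(rc), b = margin_thresholds(cc);
  double rho = brent_rho(a, b, n2, -rho_max, rho_max, tol);
  double ll = table_loglik(a, b, n2, rho);
  // flag an all-mass-on-one-diagonal style degenerate table via boundary estimate
  bool at_bound = (std::fabs(rho) > rho_max - 1e-4);
  return List::create(_["rho"] = rho, _["degenerate"] = at_bound, _["loglik"] = ll);
}

// Full pairwise-complete polychoric matrix.  codes: persons x items integer
// matrix of category codes 0..K-1, NA allowed.  Returns correlation matrix,
// pairwise n matrix, and a flag matrix for degenerate/boundary pairs.
// [[Rcpp::export(name = ".polychoric_matrix_cpp")]]
List polychoric_matrix_cpp(IntegerMatrix codes, double rho_max, double tol) {
  int n = codes.nrow(), p = codes.ncol();
  NumericMatrix R(p, p), N(p, p);
  LogicalMatrix flag(p, p);
  R.fill(1.0);
  std::vector<int> kmax(p, 0);
  for (int j = 0; j < p; j++) {
    int m = 0;
    for (int i = 0; i < n; i++)
      if (codes(i, j) != NA_INTEGER && codes(i, j) > m) m = codes(i, j);
    kmax[j] = m;
    int nj = 0;
    for (int i = 0; i < n; i++) if (codes(i, j) != NA_INTEGER) nj++;
    N(j, j) = nj;
  }
  for (int j1 = 0; j1 < p; j1++) {
    for (int j2 = j1 + 1; j2 < p; j2++) {
      int r = kmax[j1] + 1, c = kmax[j2] + 1;
      NumericMatrix tab(r, c);
      int npair = 0;
      for (int i = 0; i < n; i++) {
        int x = codes(i, j1), y = codes(i, j2);
        if (x != NA_INTEGER && y != NA_INTEGER) {
          tab(x, y) += 1.0;
          npair++;
        }
      }
      double rho = 0.0;
      bool fl = false;
      if (npair == 0) {
        rho = NA_REAL;
        fl = true;
      } else {
        List res = polychoric_table_cpp(tab, rho_max, tol);
        rho = as<double>(res["rho"]);
        fl = as<bool>(res["degenerate"]);
        if (NumericVector::is_na(rho)) { rho = 0.0; fl = true; }
      }
      R(j1, j2) = R(j2, j1) = rho;
      N(j1, j2) = N(j2, j1) = npair;
      flag(j1, j2) = flag(j2, j1) = fl;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["rho"] = R, _["pair_n"] = N, _["flagged"] = flag);
}
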