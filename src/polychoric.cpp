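// Two-step maximum-likelihood polychoric correlation.
//
// Step 1 fixes each item's thresholds at the inverse-normal of the
// cumulative margin proportions; step 2 maximizes the contingency-table
// multinomial log-likelihood over the latent correlation rho alone.
// Rectangle probabilities come from the bivariate normal CDF; the
// derivative of a rectangle probability with respect to rho is the
// bivariate normal density summed over the rectangle's corners with
// alternating signs, which gives an analytic score function for a fast
// safeguarded secant/bisection solve.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// Gauss-Legendre nodes/weights (6, 12 and 20 point rules, symmetric halves).
static const double GL6_W[3] = {0.1713244923791704, 0.3607615730481386,
                                0.4679139345726910};
static const double GL6_X[3] = {-0.9324695142031521, -0.6612093864662645,
                                -0.2386191860831969};
static const double GL12_W[6] = {0.04717533638651183, 0.1069393259953184,
                                 0.1600783285433462,  0.2031674267230659,
                                 0.2334925365383548,  0.2491470458134028};
static const double GL12_X[6] = {-0.9815606342467192, -0.9041172563704749,
                                 -0.7699026741943047, -0.5873179542866175,
                                 -0.3678314989981802, -0.1252334085114689};
static const double GL20_W[10] = {0.01761400713915212, 0.04060142980038694,
                                  0.06267204833410907, 0.08327674157670475,
                                  0.1019301198172404,  0.1181945319615184,
                                  0.1316886384491766,  0.1420961093183820,
                                  0.1491729864726037,  0.1527533871307258};
static const double GL20_X[10] = {-0.9931285991850949,  -0.9639719272779138,
                                  -0.9122344282513259,  -0.8391169718222188,
                                  -0.7463319064601508,  -0.6360536807265150,
                                  -0.5108670019508271,  -0.3737060887154195,
                                  -0.2277858511416451,  -0.07652652113349734};

static inline double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// Upper-orthant bivariate normal probability P(X > dh, Y > dk), correlation r.
// Genz (2004) hybrid: Drezner-Wesolowsky quadrature for |r| <= 0.925 and an
// asymptotic-expansion-corrected quadrature near the singular |r| -> 1 limit.
static double bvnd_upper(double dh, double dk, double r) {
  const double *w, *x;
  int lg;
  double ar = std::fabs(r);
  if (ar < 0.3) {
    lg = 3; w = GL6_W; x = GL6_X;
  } else if (ar < 0.75) {
    lg = 6; w = GL12_W; x = GL12_X;
  } else {
    lg = 10; w = GL20_W; x = GL20_X;
  }

  double h = dh, k = dk;
  double hk = h * k;
  double bvn = 0.0;

  if (ar < 0.925) {
    if (ar > 0.0) {
      double hs = (h * h + k * k) / 2.0;
      double asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
          bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * TWO_PI);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0.0) {
      k = -k;
      hk = -hk;
    }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(TWO_PI) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a = a / 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          asr = -(bs / xs + hk) / 2.0;
          if (asr > -100.0)
            bvn += a * w[i] * std::exp(asr) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
        }
      }
      bvn = -bvn / TWO_PI;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// CDF P(X <= x, Y <= y); tolerates infinite arguments.
static double bvn_cdf(double x, double y, double r) {
  if (x == R_NegInf || y == R_NegInf) return 0.0;
  if (x == R_PosInf && y == R_PosInf) return 1.0;
  if (x == R_PosInf) return phid(y);
  if (y == R_PosInf) return phid(x);
  return bvnd_upper(-x, -y, r);
}

// Standard bivariate normal density; zero at infinite coordinates.
static inline double bvn_pdf(double x, double y, double r) {
  if (!R_FINITE(x) || !R_FINITE(y)) return 0.0;
  double omr2 = 1.0 - r * r;
  double z = (x * x - 2.0 * r * x * y + y * y) / omr2;
  return std::exp(-z / 2.0) / (TWO_PI * std::sqrt(omr2));
}

// [[Rcpp::export(name = ".bvn_cdf_cpp")]]
double bvn_cdf_cpp(double x, double y, double rho) {
  if (rho <= -1.0 || rho >= 1.0) stop("rho must be in (-1, 1)");
  return bvn_cdf(x, y, rho);
}

// ---------------------------------------------------------------------------
// Pair likelihood machinery
// ---------------------------------------------------------------------------

struct PairTable {
  std::vector<double> tab;   // R x C counts, row-major
  std::vector<double> tau_r; // length R+1, first -Inf, last +Inf
  std::vector<double> tau_c; // length C+1
  int nr, nc;
  double n;
};

static PairTable make_pair_table(const NumericMatrix &tab) {
  PairTable pt;
  pt.nr = tab.nrow();
  pt.nc = tab.ncol();
  pt.tab.assign(pt.nr * pt.nc, 0.0);
  std::vector<double> rm(pt.nr, 0.0), cm(pt.nc, 0.0);
  double n = 0.0;
  for (int i = 0; i < pt.nr; i++)
    for (int j = 0; j < pt.nc; j++) {
      double v = tab(i, j);
      if (v < 0 || !R_FINITE(v)) stop("table counts must be finite and non-negative");
      pt.tab[i * pt.nc + j] = v;
      rm[i] += v;
      cm[j] += v;
      n += v;
    }
  if (n < 1) stop("table has no observations");
  pt.n = n;
  int nzr = 0, nzc = 0;
  for (int i = 0; i < pt.nr; i++) if (rm[i] > 0) nzr++;
  for (int j = 0; j < pt.nc; j++) if (cm[j] > 0) nzc++;
  if (nzr < 2 || nzc < 2)
    stop("degenerate margin: need at least two non-empty categories per item");
  pt.tau_r.resize(pt.nr + 1);
  pt.tau_c.resize(pt.nc + 1);
  pt.tau_r[0] = R_NegInf;
  pt.tau_c[0] = R_NegInf;
  pt.tau_r[pt.nr] = R_PosInf;
  pt.tau_c[pt.nc] = R_PosInf;
  double cum = 0.0;
  for (int i = 0; i < pt.nr - 1; i++) {
    cum += rm[i];
    pt.tau_r[i + 1] = R::qnorm(cum / n, 0.0, 1.0, 1, 0);
  }
  cum = 0.0;
  for (int j = 0; j < pt.nc - 1; j++) {
    cum += cm[j];
    pt.tau_c[j + 1] = R::qnorm(cum / n, 0.0, 1.0, 1, 0);
  }
  return pt;
}

static const double PROB_FLOOR = 1e-12;

// Log-likelihood and score in rho. Cells with zero count are skipped;
// cells with positive count but model probability below PROB_FLOOR are
// floored (their derivative contribution is damped accordingly).
static void pair_loglik_grad(const PairTable &pt, double rho, double *ll,
                             double *grad) {
  int R1 = pt.nr + 1, C1 = pt.nc + 1;
  std::vector<double> F(R1 * C1), D(R1 * C1);
  for (int a = 0; a < R1; a++)
    for (int b = 0; b < C1; b++) {
      F[a * C1 + b] = bvn_cdf(pt.tau_r[a], pt.tau_c[b], rho);
      if (grad) D[a * C1 + b] = bvn_pdf(pt.tau_r[a], pt.tau_c[b], rho);
    }
  double l = 0.0, g = 0.0;
  for (int i = 0; i < pt.nr; i++)
    for (int j = 0; j < pt.nc; j++) {
      double nij = pt.tab[i * pt.nc + j];
      if (nij <= 0) continue;
      double pij = F[(i + 1) * C1 + (j + 1)] - F[i * C1 + (j + 1)] -
                   F[(i + 1) * C1 + j] + F[i * C1 + j];
      double pf = std::max(pij, PROB_FLOOR);
      l += nij * std::log(pf);
      if (grad) {
        double dij = D[(i + 1) * C1 + (j + 1)] - D[i * C1 + (j + 1)] -
                     D[(i + 1) * C1 + j] + D[i * C1 + j];
        g += nij * dij / pf;
      }
    }
  *ll = l;
  if (grad) *grad = g;
}

// [[Rcpp::export(name = ".poly_loglik_cpp")]]
NumericVector poly_loglik_cpp(NumericMatrix tab, NumericVector rho) {
  PairTable pt = make_pair_table(tab);
  int m = rho.size();
  NumericVector out(m);
  for (int t = 0; t < m; t++) {
    if (rho[t] <= -1.0 || rho[t] >= 1.0) stop("rho must be in (-1, 1)");
    double ll;
    pair_loglik_grad(pt, rho[t], &ll, nullptr);
    out[t] = ll;
  }
  return out;
}

static const double RHO_BOUND = 0.9999; // 1 - 1e-4 clamp

// Moment-style starting value: correlation of conditional-mean normal scores.
static double start_rho(const PairTable &pt) {
  int nr = pt.nr, nc = pt.nc;
  std::vector<double> zr(nr), zc(nc), rm(nr, 0.0), cm(nc, 0.0);
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++) {
      rm[i] += pt.tab[i * nc + j];
      cm[j] += pt.tab[i * nc + j];
    }
  for (int i = 0; i < nr; i++) {
    double lo = pt.tau_r[i], hi = pt.tau_r[i + 1];
    double p = rm[i] / pt.n;
    double dlo = R_FINITE(lo) ? R::dnorm(lo, 0, 1, 0) : 0.0;
    double dhi = R_FINITE(hi) ? R::dnorm(hi, 0, 1, 0) : 0.0;
    zr[i] = p > 0 ? (dlo - dhi) / p : 0.0;
  }
  for (int j = 0; j < nc; j++) {
    double lo = pt.tau_c[j], hi = pt.tau_c[j + 1];
    double p = cm[j] / pt.n;
    double dlo = R_FINITE(lo) ? R::dnorm(lo, 0, 1, 0) : 0.0;
    double dhi = R_FINITE(hi) ? R::dnorm(hi, 0, 1, 0) : 0.0;
    zc[j] = p > 0 ? (dlo - dhi) / p : 0.0;
  }
  double sxy = 0.0, sxx = 0.0, syy = 0.0;
  for (int i = 0; i < nr; i++) {
    sxx += rm[i] * zr[i] * zr[i];
    for (int j = 0; j < nc; j++) sxy += pt.tab[i * nc + j] * zr[i] * zc[j];
  }
  for (int j = 0; j < nc; j++) syy += cm[j] * zc[j] * zc[j];
  double denom = std::sqrt(sxx * syy);
  double r0 = denom > 0 ? sxy / denom : 0.0;
  if (r0 > 0.9) r0 = 0.9;
  if (r0 < -0.9) r0 = -0.9;
  return r0;
}

struct PairFit {
  double rho, loglik;
  bool converged, at_bound;
};

// Golden-section maximization of the log-likelihood on [a, b].
static double golden_max(const PairTable &pt, double a, double b, double tol,
                         double *ll_out) {
  const double gr = 0.61803398874989484820;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1, f2;
  pair_loglik_grad(pt, x1, &f1, nullptr);
  pair_loglik_grad(pt, x2, &f2, nullptr);
  while (b - a > tol) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      pair_loglik_grad(pt, x2, &f2, nullptr);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      pair_loglik_grad(pt, x1, &f1, nullptr);
    }
  }
  double xm = 0.5 * (a + b);
  pair_loglik_grad(pt, xm, ll_out, nullptr);
  return xm;
}

// Maximize the profile likelihood over rho in [-RHO_BOUND, RHO_BOUND]:
// a coarse likelihood scan brackets the global maximum (the profile can
// be irregular near +/-1 when sparse cells hit the probability floor),
// then the score is root-found inside the bracket by secant steps
// safeguarded with bisection, with golden-section as a fallback.
static PairFit fit_pair(const PairTable &pt, double tol) {
  PairFit out;
  static const double scan[15] = {-RHO_BOUND, -0.96, -0.80, -0.64, -0.48,
                                  -0.32, -0.16, 0.0,  0.16,  0.32,  0.48,
                                  0.64,  0.80,  0.96, RHO_BOUND};
  double ll, best_ll = -1e300;
  int best_i = 0;
  double ll_scan[15];
  for (int i = 0; i < 15; i++) {
    pair_loglik_grad(pt, scan[i], &ll, nullptr);
    ll_scan[i] = ll;
    if (ll > best_ll) { best_ll = ll; best_i = i; }
  }
  if (best_i == 0 || best_i == 14) { // boundary solution; clamp
    out.rho = scan[best_i];
    out.loglik = ll_scan[best_i];
    out.converged = true;
    out.at_bound = true;
    return out;
  }
  double a = scan[best_i - 1], b = scan[best_i + 1];
  double ga, gb;
  pair_loglik_grad(pt, a, &ll, &ga);
  pair_loglik_grad(pt, b, &ll, &gb);
  if (!(ga > 0.0 && gb < 0.0)) {
    // score not cleanly bracketed (floored cells): fall back to direct
    // likelihood maximization on the bracket
    out.rho = golden_max(pt, a, b, tol, &out.loglik);
    out.converged = true;
    out.at_bound = false;
    return out;
  }
  double x = start_rho(pt), gx;
  if (x <= a || x >= b) x = 0.5 * (a + b);
  bool conv = false;
  double xprev = a, gprev = ga;
  double rho_hat = x;
  for (int it = 0; it < 100; it++) {
    pair_loglik_grad(pt, x, &ll, &gx);
    if (std::fabs(gx) < 1e-10 * pt.n) { rho_hat = x; conv = true; break; }
    if (gx > 0) { a = x; ga = gx; } else { b = x; gb = gx; }
    if ((b - a) < tol) { rho_hat = 0.5 * (a + b); conv = true; break; }
    // secant proposal from the two most recent points
    double xn = x - gx * (x - xprev) / (gx - gprev);
    xprev = x; gprev = gx;
    if (!R_FINITE(xn) || xn <= a || xn >= b)
      xn = 0.5 * (a + b); // bisection safeguard
    x = xn;
    rho_hat = x;
  }
  pair_loglik_grad(pt, rho_hat, &ll, nullptr);
  out.rho = rho_hat;
  out.loglik = ll;
  out.converged = conv;
  out.at_bound = false;
  return out;
}

// [[Rcpp::export(name = ".poly_pair_cpp")]]
List poly_pair_cpp(NumericMatrix tab, double tol = 1e-7) {
  PairTable pt = make_pair_table(tab);
  PairFit f = fit_pair(pt, tol);
  NumericVector tr(pt.tau_r.begin() + 1, pt.tau_r.end() - 1);
  NumericVector tc(pt.tau_c.begin() + 1, pt.tau_c.end() - 1);
  return List::create(_["rho"] = f.rho, _["loglik"] = f.loglik,
                      _["converged"] = f.converged,
                      _["at_bound"] = f.at_bound, _["n"] = pt.n,
                      _["tau_row"] = tr, _["tau_col"] = tc);
}

// Full pairwise polychoric matrix from integer codes (0-based categories).
// [[Rcpp::export(name = ".poly_matrix_cpp")]]
List poly_matrix_cpp(IntegerMatrix X, int n_categories, double tol = 1e-7) {
  int n = X.nrow(), p = X.ncol(), C = n_categories;
  NumericMatrix R(p, p);
  LogicalMatrix conv(p, p);
  int n_bound = 0;
  std::vector<int> xi(n), xj(n);
  for (int i = 0; i < p; i++) {
    R(i, i) = 1.0;
    conv(i, i) = true;
  }
  NumericMatrix tab(C, C);
  for (int i = 0; i < p; i++) {
    for (int j = i + 1; j < p; j++) {
      std::fill(tab.begin(), tab.end(), 0.0);
      for (int t = 0; t < n; t++) {
        int a = X(t, i), b = X(t, j);
        if (a == NA_INTEGER || b == NA_INTEGER)
          stop("missing codes: apply complete-case filtering first");
        if (a < 0 || a >= C || b < 0 || b >= C)
          stop("code out of range in column %d or %d", i + 1, j + 1);
        tab(a, b) += 1.0;
      }
      PairTable pt = make_pair_table(tab);
      PairFit f = fit_pair(pt, tol);
      R(i, j) = f.rho;
      R(j, i) = f.rho;
      conv(i, j) = f.converged;
      conv(j, i) = f.converged;
      if (f.at_bound) n_bound++;
    }
  }
  return List::create(_["rho"] = R, _["converged"] = conv,
                      _["n_at_bound"] = n_bound);
}
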