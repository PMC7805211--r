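// Laplace-approximated marginal likelihood for a beta-regression mixed
// model with logit link and up to two Gaussian random-intercept factors
// (slide, and patient nested within slide).  The inner mode search over
// the random-effect vector is a damped Newton iteration; the outer
// parameters (fixed effects, log sigmas, log phi) are optimised from R.
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct GlmmData {
  arma::vec y;       // responses in (0,1)
  arma::mat X;       // fixed-effect design
  arma::ivec g1;     // factor-1 index per obs (0-based), empty if unused
  arma::ivec g2;     // factor-2 index per obs
  int n1, n2;        // number of levels per factor
  arma::vec u;       // cached random-effect mode (warm start)
};

// per-observation beta log-likelihood and first two derivatives wrt eta
inline void beta_derivs(double y, double eta, double phi,
                        double &ll, double &g, double &h) {
  double mu = 1.0 / (1.0 + std::exp(-eta));
  // keep mu off the boundary so lgamma stays finite
  const double eps = 1e-10;
  if (mu < eps) mu = eps;
  if (mu > 1 - eps) mu = 1 - eps;
  double a = mu * phi, b = (1.0 - mu) * phi;
  double ly = std::log(y), l1y = std::log1p(-y);
  ll = R::lgammafn(phi) - R::lgammafn(a) - R::lgammafn(b)
       + (a - 1.0) * ly + (b - 1.0) * l1y;
  double dmu = phi * (-R::digamma(a) + R::digamma(b) + ly - l1y);
  double d2mu = -phi * phi * (R::trigamma(a) + R::trigamma(b));
  double v = mu * (1.0 - mu);        // dmu/deta
  g = dmu * v;
  h = d2mu * v * v + dmu * (1.0 - 2.0 * mu) * v;
}

// joint negative log density F(u) (includes Gaussian prior normalisers),
// with gradient and Hessian wrt u on request
double joint_nll(const GlmmData &d, const arma::vec &beta, double s1,
                 double s2, double phi, const arma::vec &u,
                 arma::vec *grad, arma::mat *hess) {
  const int n = d.y.n_elem, dim = d.n1 + d.n2;
  arma::vec eta = d.X * beta;
  for (int i = 0; i < n; ++i) {
    if (d.n1 > 0) eta[i] += u[d.g1[i]];
    if (d.n2 > 0) eta[i] += u[d.n1 + d.g2[i]];
  }
  double F = 0.0;
  if (grad) grad->zeros(dim);
  if (hess) hess->zeros(dim, dim);
  for (int i = 0; i < n; ++i) {
    double ll, g, h;
    beta_derivs(d.y[i], eta[i], phi, ll, g, h);
    F -= ll;
    if (grad) {
      if (d.n1 > 0) (*grad)[d.g1[i]] -= g;
      if (d.n2 > 0) (*grad)[d.n1 + d.g2[i]] -= g;
    }
    if (hess) {
      double w = -h;              // negative curvature of loglik
      if (w < 1e-8) w = 1e-8;     // guard: keep H positive definite
      if (d.n1 > 0) {
        int a = d.g1[i];
        (*hess)(a, a) += w;
        if (d.n2 > 0) {
          int b = d.n1 + d.g2[i];
          (*hess)(a, b) += w;
          (*hess)(b, a) += w;
        }
      }
      if (d.n2 > 0) {
        int b = d.n1 + d.g2[i];
        (*hess)(b, b) += w;
      }
    }
  }
  const double l2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < d.n1; ++k) {
    F += 0.5 * u[k] * u[k] / (s1 * s1) + std::log(s1) + 0.5 * l2pi;
    if (grad) (*grad)[k] += u[k] / (s1 * s1);
    if (hess) (*hess)(k, k) += 1.0 / (s1 * s1);
  }
  for (int k = 0; k < d.n2; ++k) {
    int j = d.n1 + k;
    F += 0.5 * u[j] * u[j] / (s2 * s2) + std::log(s2) + 0.5 * l2pi;
    if (grad) (*grad)[j] += u[j] / (s2 * s2);
    if (hess) (*hess)(j, j) += 1.0 / (s2 * s2);
  }
  return F;
}

// damped Newton mode search; returns F(u*) and leaves u* in d.u
double inner_newton(GlmmData &d, const arma::vec &beta, double s1, double s2,
                    double phi, arma::mat &H, bool &ok) {
  const int dim = d.n1 + d.n2;
  arma::vec u = d.u, grad(dim), gc(dim);
  arma::mat Hc(dim, dim);
  double F = joint_nll(d, beta, s1, s2, phi, u, &grad, &H);
  ok = true;
  for (int it = 0; it < 100; ++it) {
    if (arma::norm(grad, "inf") < 1e-9) break;
    arma::vec step;
    bool solved = arma::solve(step, H, grad, arma::solve_opts::likely_sympd);
    if (!solved) { ok = false; break; }
    double t = 1.0;
    for (int ls = 0; ls < 30; ++ls) {
      arma::vec cand = u - t * step;
      double Fc = joint_nll(d, beta, s1, s2, phi, cand, &gc, &Hc);
      if (std::isfinite(Fc) && Fc <= F + 1e-12) {
        u = cand;
        F = Fc;
        grad = gc;
        H = Hc;
        break;
      }
      t *= 0.5;
      if (ls == 29) ok = false;
    }
    if (!ok) break;
  }
  d.u = u;
  return F;
}

double laplace_nll(GlmmData &d, const arma::vec &par) {
  const int p = d.X.n_cols;
  arma::vec beta = par.subvec(0, p - 1);
  int k = p;
  double s1 = 1.0, s2 = 1.0;
  // project variance/precision parameters into their box so that an
  // unbounded optimizer pass cannot reach numerically singular regions
  if (d.n1 > 0) s1 = std::exp(std::min(std::max(par[k++], -6.0), 2.0));
  if (d.n2 > 0) s2 = std::exp(std::min(std::max(par[k++], -6.0), 2.0));
  double phi = std::exp(std::min(std::max(par[k], std::log(0.5)),
                                 std::log(5e4)));
  const int dim = d.n1 + d.n2;
  if (dim == 0) {
    arma::vec eta = d.X * beta;
    double F = 0.0;
    for (arma::uword i = 0; i < d.y.n_elem; ++i) {
      double ll, g, h;
      beta_derivs(d.y[i], eta[i], phi, ll, g, h);
      F -= ll;
    }
    return F;
  }
  arma::mat H(dim, dim);
  bool ok;
  double F = inner_newton(d, beta, s1, s2, phi, H, ok);
  if (!ok || !std::isfinite(F)) return 1e10;
  double sign, ldet;
  arma::log_det(ldet, sign, H);
  if (sign <= 0) return 1e10;
  return F + 0.5 * ldet - 0.5 * dim * std::log(2.0 * M_PI);
}

// full derivative bundle of the per-observation beta log-likelihood:
// l1..l3 = d^k l / d eta^k, lp = dl/dphi, l1p = d2l/(deta dphi),
// l2p = d3l/(deta^2 dphi)
struct ObsDerivs {
  double l1, l2, l3, lp, l1p, l2p;
};

inline ObsDerivs beta_derivs_full(double y, double eta, double phi) {
  double mu = 1.0 / (1.0 + std::exp(-eta));
  const double eps = 1e-10;
  if (mu < eps) mu = eps;
  if (mu > 1 - eps) mu = 1 - eps;
  double a = mu * phi, b = (1.0 - mu) * phi;
  double ly = std::log(y), l1y = std::log1p(-y);
  double pg_a = R::digamma(a), pg_b = R::digamma(b);
  double tg_a = R::trigamma(a), tg_b = R::trigamma(b);
  double qg_a = R::psigamma(a, 2), qg_b = R::psigamma(b, 2);
  double v = mu * (1.0 - mu), w = 1.0 - 2.0 * mu;
  double dmu = phi * (-pg_a + pg_b + ly - l1y);
  double d2mu = -phi * phi * (tg_a + tg_b);
  double d3mu = -phi * phi * phi * (qg_a - qg_b);
  ObsDerivs o;
  o.l1 = dmu * v;
  o.l2 = d2mu * v * v + dmu * w * v;
  o.l3 = (d3mu * v * v + 3.0 * d2mu * v * w + dmu * (w * w - 2.0 * v)) * v;
  o.lp = R::digamma(phi) - mu * pg_a - (1.0 - mu) * pg_b + mu * ly +
         (1.0 - mu) * l1y;
  double dmu_p = (-pg_a + pg_b + ly - l1y) +
                 phi * (-mu * tg_a + (1.0 - mu) * tg_b);
  double d2mu_p = -2.0 * phi * (tg_a + tg_b) -
                  phi * phi * (mu * qg_a + (1.0 - mu) * qg_b);
  o.l1p = dmu_p * v;
  o.l2p = d2mu_p * v * v + dmu_p * w * v;
  return o;
}

// analytic gradient of the Laplace negative log-likelihood wrt the outer
// parameters, via implicit differentiation of the inner mode
arma::vec laplace_grad(GlmmData &d, const arma::vec &par) {
  const int p = d.X.n_cols, n = d.y.n_elem;
  arma::vec beta = par.subvec(0, p - 1);
  int k = p;
  double s1 = 1.0, s2 = 1.0;
  bool has1 = d.n1 > 0, has2 = d.n2 > 0;
  if (has1) s1 = std::exp(std::min(std::max(par[k++], -6.0), 2.0));
  if (has2) s2 = std::exp(std::min(std::max(par[k++], -6.0), 2.0));
  double phi = std::exp(std::min(std::max(par[k], std::log(0.5)),
                                 std::log(5e4)));
  const int dim = d.n1 + d.n2;
  const int npar = par.n_elem;
  arma::vec grad(npar, arma::fill::zeros);

  if (dim == 0) {
    arma::vec eta = d.X * beta;
    for (int i = 0; i < n; ++i) {
      ObsDerivs o = beta_derivs_full(d.y[i], eta[i], phi);
      for (int j = 0; j < p; ++j) grad[j] -= o.l1 * d.X(i, j);
      grad[p] -= o.lp;
    }
    grad[p] *= phi;                    // chain rule through log phi
    return grad;
  }

  arma::mat H(dim, dim);
  bool ok;
  inner_newton(d, beta, s1, s2, phi, H, ok);
  if (!ok) return grad;                // caller falls back to FD behaviour
  arma::mat Hinv = arma::inv_sympd(arma::symmatu(H));
  arma::vec eta = d.X * beta;
  for (int i = 0; i < n; ++i) {
    if (has1) eta[i] += d.u[d.g1[i]];
    if (has2) eta[i] += d.u[d.n1 + d.g2[i]];
  }

  // per-observation derivative bundles and c_i = z_i' Hinv z_i
  arma::vec l1(n), l2(n), l3(n), lp(n), l1p(n), l2p(n), c(n);
  for (int i = 0; i < n; ++i) {
    ObsDerivs o = beta_derivs_full(d.y[i], eta[i], phi);
    l1[i] = o.l1; l2[i] = o.l2; l3[i] = o.l3;
    lp[i] = o.lp; l1p[i] = o.l1p; l2p[i] = o.l2p;
    double ci = 0;
    if (has1) ci += Hinv(d.g1[i], d.g1[i]);
    if (has2) ci += Hinv(d.n1 + d.g2[i], d.n1 + d.g2[i]);
    if (has1 && has2) ci += 2.0 * Hinv(d.g1[i], d.n1 + d.g2[i]);
    c[i] = ci;
  }

  // gu[k] = d/du_k of 0.5 log|H| = -0.5 sum_i l3_i c_i Z_ik
  arma::vec gu(dim, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double t = -0.5 * l3[i] * c[i];
    if (has1) gu[d.g1[i]] += t;
    if (has2) gu[d.n1 + d.g2[i]] += t;
  }
  arma::vec gHinv = Hinv * gu;         // reused: gu' Hinv b_j terms

  // fixed effects
  for (int j = 0; j < p; ++j) {
    double direct = 0, trace = 0;
    arma::vec bj(dim, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      double x = d.X(i, j);
      direct -= l1[i] * x;
      trace += -0.5 * l3[i] * x * c[i];
      double wv = -l2[i] * x;          // d2F/(du deta) contribution
      if (has1) bj[d.g1[i]] += wv;
      if (has2) bj[d.n1 + d.g2[i]] += wv;
    }
    grad[j] = direct + trace - arma::dot(gHinv, bj);
  }

  int kk = p;
  if (has1) {
    double dF = 0, tr = 0;
    arma::vec b(dim, arma::fill::zeros);
    for (int q = 0; q < d.n1; ++q) {
      dF += 1.0 - d.u[q] * d.u[q] / (s1 * s1);
      tr += -(1.0 / (s1 * s1)) * Hinv(q, q);
      b[q] = -2.0 * d.u[q] / (s1 * s1);
    }
    grad[kk++] = dF + tr - arma::dot(gHinv, b);
  }
  if (has2) {
    double dF = 0, tr = 0;
    arma::vec b(dim, arma::fill::zeros);
    for (int q = 0; q < d.n2; ++q) {
      int j = d.n1 + q;
      dF += 1.0 - d.u[j] * d.u[j] / (s2 * s2);
      tr += -(1.0 / (s2 * s2)) * Hinv(j, j);
      b[j] = -2.0 * d.u[j] / (s2 * s2);
    }
    grad[kk++] = dF + tr - arma::dot(gHinv, b);
  }
  {
    double dF = 0, tr = 0;
    arma::vec b(dim, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      dF -= lp[i];
      tr += -0.5 * l2p[i] * c[i];
      double wv = -l1p[i];
      if (has1) b[d.g1[i]] += wv;
      if (has2) b[d.n1 + d.g2[i]] += wv;
    }
    grad[kk] = phi * (dF + tr - arma::dot(gHinv, b));
  }
  return grad;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".glmm_grad")]]
NumericVector glmm_grad(SEXP handle, NumericVector par) {
  XPtr<GlmmData> d(handle);
  return wrap(laplace_grad(*d, as<arma::vec>(par)));
}

//' @noRd
// [[Rcpp::export(name = ".glmm_make")]]
SEXP glmm_make(NumericVector y, NumericMatrix X, IntegerVector g1,
               IntegerVector g2, int n1, int n2) {
  GlmmData *d = new GlmmData;
  d->y = as<arma::vec>(y);
  d->X = as<arma::mat>(X);
  d->g1 = as<arma::ivec>(g1);
  d->g2 = as<arma::ivec>(g2);
  d->n1 = n1;
  d->n2 = n2;
  d->u = arma::zeros(n1 + n2);
  XPtr<GlmmData> ptr(d, true);
  return ptr;
}

//' @noRd
// [[Rcpp::export(name = ".glmm_nll")]]
double glmm_nll(SEXP handle, NumericVector par) {
  XPtr<GlmmData> d(handle);
  return laplace_nll(*d, as<arma::vec>(par));
}

// covariance of the fixed effects from the joint (beta, u) observed
// information at the mode, variance parameters held at their estimates
//' @noRd
// [[Rcpp::export(name = ".glmm_beta_cov")]]
NumericMatrix glmm_beta_cov(SEXP handle, NumericVector par) {
  XPtr<GlmmData> d(handle);
  const int p = d->X.n_cols, n = d->y.n_elem;
  arma::vec pv = as<arma::vec>(par);
  arma::vec beta = pv.subvec(0, p - 1);
  int k = p;
  double s1 = 1.0, s2 = 1.0;
  if (d->n1 > 0) s1 = std::exp(std::min(std::max(pv[k++], -6.0), 2.0));
  if (d->n2 > 0) s2 = std::exp(std::min(std::max(pv[k++], -6.0), 2.0));
  double phi = std::exp(std::min(std::max(pv[k], std::log(0.5)),
                                 std::log(5e4)));
  const int dim = d->n1 + d->n2;
  arma::mat Huu(std::max(dim, 1), std::max(dim, 1));
  if (dim > 0) {
    bool ok;
    inner_newton(*d, beta, s1, s2, phi, Huu, ok);
  }
  arma::vec eta = d->X * beta;
  for (int i = 0; i < n; ++i) {
    if (d->n1 > 0) eta[i] += d->u[d->g1[i]];
    if (d->n2 > 0) eta[i] += d->u[d->n1 + d->g2[i]];
  }
  arma::mat Hbb(p, p, arma::fill::zeros);
  arma::mat Hbu(p, std::max(dim, 1), arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double ll, g, h;
    beta_derivs(d->y[i], eta[i], phi, ll, g, h);
    double w = -h;
    if (w < 1e-8) w = 1e-8;
    arma::vec xi = d->X.row(i).t();
    Hbb += w * xi * xi.t();
    if (d->n1 > 0) Hbu.col(d->g1[i]) += w * xi;
    if (d->n2 > 0) Hbu.col(d->n1 + d->g2[i]) += w * xi;
  }
  arma::mat cov;
  if (dim == 0) {
    cov = arma::inv_sympd(Hbb);
  } else {
    // Schur complement of the random-effect block
    arma::mat S = Hbb - Hbu * arma::solve(Huu, Hbu.t());
    cov = arma::inv_sympd(arma::symmatu(S));
  }
  return wrap(cov);
}

//' @noRd
// [[Rcpp::export(name = ".glmm_ranef")]]
NumericVector glmm_ranef(SEXP handle) {
  XPtr<GlmmData> d(handle);
  return wrap(d->u);
}
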