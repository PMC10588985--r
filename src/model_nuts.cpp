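// Joint log-density (non-centred parameterisation) and gradient of the
// hierarchical wrapped Cauchy phase model, plus a No-U-Turn sampler
// (Hoffman & Gelman, Algorithm 6) with dual-averaging step-size and
// diagonal mass-matrix adaptation.
//
// Unconstrained parameter vector layout (length D):
//   alpha[c]              c = 0..C-1        condition effects (logit of S_c)
//   z_beta[p + P*c]       participant slope innovations, N(0,1)
//   u_g[p]                log of the Gamma(nu/2, nu/2) t-mixing variable
//   z_delta[c + C*e]      electrode slope innovations, N(0,1)
//   xy[2*m], xy[2*m+1]    planar mean-phase coordinates, cell m = p + P*c + P*C*e
//   lsb[c]                log sigma_beta
//   lsd[c]                log sigma_delta
//   zc[t]                 atanh of the canonical partial correlations,
//                         strict lower triangle in row order
//   lnu                   log(nu - 2), only when nu is estimated
//
// The centred slopes are beta[p,c] = sigma_beta[c] * (L z_p)_c / sqrt(g_p)
// with L the Cholesky factor of the slope correlation matrix, and
// delta[c,e] = sigma_delta[c] * z_delta[c,e].  Trial phases are wrapped
// Cauchy with q = exp(-gamma) = 1 - logistic(upsilon) evaluated through
// the Poisson-kernel form, which is stable for all gamma > 0.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct ModelData {
  int P, C, E, n_cells, n_obs;
  std::vector<double> cth, sth;     // cos/sin of observed phases, cell-sorted
  std::vector<int> cell_start;      // length n_cells + 1
  double a, b;                      // Beta prior on S_c
  double rshape, rrate;             // Bundt radial profile
  double sb_scale, sd_scale;        // half-normal hyperprior scales
  double eta;                       // LKJ shape
  double nu;                        // fixed df (ignored when estimate_nu)
  bool estimate_nu;
  double nu_a, nu_b;                // Gamma prior on nu - 2
  double gamma_scale;               // likelihood corruption factor (SBC control)
  bool prior_only;
  int m_corr;                       // C*(C-1)/2

  int dim() const {
    return C + P * C + P + C * E + 2 * n_cells + 2 * C + m_corr +
           (estimate_nu ? 1 : 0);
  }
  int o_alpha() const { return 0; }
  int o_zbeta() const { return C; }
  int o_ug() const { return C + P * C; }
  int o_zdelta() const { return C + P * C + P; }
  int o_xy() const { return C + P * C + P + C * E; }
  int o_lsb() const { return o_xy() + 2 * n_cells; }
  int o_lsd() const { return o_lsb() + C; }
  int o_zc() const { return o_lsd() + C; }
  int o_lnu() const { return o_zc() + m_corr; }
};

static ModelData unpack_data(const List& md) {
  ModelData d;
  d.P = as<int>(md["P"]); d.C = as<int>(md["C"]); d.E = as<int>(md["E"]);
  d.n_cells = d.P * d.C * d.E;
  NumericVector cth = md["cth"], sth = md["sth"];
  d.cth.assign(cth.begin(), cth.end());
  d.sth.assign(sth.begin(), sth.end());
  d.n_obs = d.cth.size();
  IntegerVector cs = md["cell_start"];
  d.cell_start.assign(cs.begin(), cs.end());
  d.a = as<double>(md["a"]); d.b = as<double>(md["b"]);
  d.rshape = as<double>(md["rshape"]); d.rrate = as<double>(md["rrate"]);
  d.sb_scale = as<double>(md["sb_scale"]); d.sd_scale = as<double>(md["sd_scale"]);
  d.eta = as<double>(md["eta"]);
  d.nu = as<double>(md["nu"]);
  d.estimate_nu = as<bool>(md["estimate_nu"]);
  d.nu_a = as<double>(md["nu_a"]); d.nu_b = as<double>(md["nu_b"]);
  d.gamma_scale = as<double>(md["gamma_scale"]);
  d.prior_only = as<bool>(md["prior_only"]);
  d.m_corr = d.C * (d.C - 1) / 2;
  return d;
}

// log posterior and gradient; returns -inf (grad untouched) on a
// numerical-domain failure, which NUTS treats as a rejected/divergent state
static double logpost_grad(const ModelData& d, const double* q, double* grad,
                           bool want_grad) {
  const int P = d.P, C = d.C, E = d.E;
  const double* alpha = q + d.o_alpha();
  const double* zbeta = q + d.o_zbeta();
  const double* ug    = q + d.o_ug();
  const double* zdel  = q + d.o_zdelta();
  const double* xy    = q + d.o_xy();
  const double* lsb   = q + d.o_lsb();
  const double* lsd   = q + d.o_lsd();
  const double* zcr   = q + d.o_zc();

  const int D = d.dim();
  if (want_grad) std::fill(grad, grad + D, 0.0);

  double lp = 0.0;
  double nu = d.estimate_nu ? 2.0 + std::exp(q[d.o_lnu()]) : d.nu;
  if (!std::isfinite(nu)) return R_NegInf;

  // --- transforms -----------------------------------------------------------
  std::vector<double> sb(C), sd(C), g(P), sqg(P);
  for (int c = 0; c < C; ++c) { sb[c] = std::exp(lsb[c]); sd[c] = std::exp(lsd[c]); }
  for (int p = 0; p < P; ++p) { g[p] = std::exp(ug[p]); sqg[p] = std::sqrt(g[p]); }

  // correlation Cholesky from partials (tanh of zc), row-major strict lower
  std::vector<double> z(d.m_corr), L(C * C, 0.0);
  for (int t = 0; t < d.m_corr; ++t) z[t] = std::tanh(zcr[t]);
  L[0] = 1.0;
  {
    int t = 0;
    for (int i = 1; i < C; ++i) {
      double rem = 1.0;
      for (int j = 0; j < i; ++j, ++t) {
        L[i * C + j] = z[t] * std::sqrt(rem);
        rem *= (1.0 - z[t] * z[t]);
      }
      L[i * C + i] = std::sqrt(std::max(rem, 0.0));
    }
  }

  // centred slopes
  std::vector<double> beta(P * C), delta(C * E);
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      double acc = 0.0;
      for (int j = 0; j <= c; ++j) acc += L[c * C + j] * zbeta[p + P * j];
      beta[p + P * c] = sb[c] * acc / sqg[p];
    }
  }
  for (int c = 0; c < C; ++c)
    for (int e = 0; e < E; ++e)
      delta[c + C * e] = sd[c] * zdel[c + C * e];

  // --- likelihood -----------------------------------------------------------
  std::vector<double> gups, gbeta_cc;
  if (want_grad) gbeta_cc.assign(P * C, 0.0);
  std::vector<double> galpha_lik(C, 0.0), gdelta_cc(C * E, 0.0);
  const double gs = d.gamma_scale;

  for (int m = 0; m < d.n_cells; ++m) {
    const int p = m % P, c = (m / P) % C, e = m / (P * C);
    const double x = xy[2 * m], y = xy[2 * m + 1];
    const double rho2 = x * x + y * y;
    if (rho2 < 1e-24) return R_NegInf;
    const double rho = std::sqrt(rho2);
    // Bundt prior on the planar coordinates
    lp += (d.rshape - 1.0) * std::log(rho) - d.rrate * rho;
    if (want_grad) {
      const double dr = ((d.rshape - 1.0) / rho - d.rrate) / rho;
      grad[d.o_xy() + 2 * m]     += dr * x;
      grad[d.o_xy() + 2 * m + 1] += dr * y;
    }
    if (d.prior_only) continue;
    const int k0 = d.cell_start[m], k1 = d.cell_start[m + 1];
    if (k0 == k1) continue;

    const double ups = alpha[c] + beta[p + P * c] + delta[c + C * e];
    if (ups < -36.0) return R_NegInf;  // S numerically 1: q -> 1, density singular
    const double qw = 1.0 / (1.0 + std::exp(ups));   // e^{-gamma}
    const double qe = (gs == 1.0) ? qw : std::pow(qw, gs);
    const double A = 1.0 - qe * qe;
    if (A <= 0.0) return R_NegInf;
    const double cmu = x / rho, smu = y / rho;
    const double logA = std::log1p(-qe * qe);

    double dq_sum = 0.0, dmu_sum = 0.0;
    for (int k = k0; k < k1; ++k) {
      const double cd = d.cth[k] * cmu + d.sth[k] * smu;
      const double sdn = d.sth[k] * cmu - d.cth[k] * smu;
      const double B = 1.0 + qe * qe - 2.0 * qe * cd;
      lp += logA - std::log(B);
      if (want_grad) {
        dq_sum += -2.0 * qe / A - (2.0 * qe - 2.0 * cd) / B;
        dmu_sum += 2.0 * qe * sdn / B;
      }
    }
    // the per-observation log(2*pi) constant is dropped
    if (want_grad) {
      const double dqe_dups = -gs * qe * (1.0 - qw);  // gs*q^{gs-1} * (-q(1-q))
      const double dups = dq_sum * dqe_dups;
      galpha_lik[c] += dups;
      gbeta_cc[p + P * c] += dups;
      gdelta_cc[c + C * e] += dups;
      grad[d.o_xy() + 2 * m]     += dmu_sum * (-y / rho2);
      grad[d.o_xy() + 2 * m + 1] += dmu_sum * ( x / rho2);
    }
  }

  // --- priors ---------------------------------------------------------------
  // Beta(a, b) on S_c = logistic(alpha_c), with logit Jacobian
  for (int c = 0; c < C; ++c) {
    double logS, log1mS;
    if (alpha[c] > 0) { logS = -std::log1p(std::exp(-alpha[c])); log1mS = -alpha[c] + logS; }
    else { log1mS = -std::log1p(std::exp(alpha[c])); logS = alpha[c] + log1mS; }
    lp += d.a * logS + d.b * log1mS;
    if (want_grad) {
      const double S = std::exp(logS);
      grad[d.o_alpha() + c] = galpha_lik[c] + d.a * (1.0 - S) - d.b * S;
    }
  }
  // innovations
  for (int i = 0; i < P * C; ++i) lp -= 0.5 * zbeta[i] * zbeta[i];
  for (int i = 0; i < C * E; ++i) lp -= 0.5 * zdel[i] * zdel[i];
  // t-mixing variables: g ~ Gamma(nu/2, nu/2) in log space (Jacobian included)
  for (int p = 0; p < P; ++p) lp += 0.5 * nu * ug[p] - 0.5 * nu * g[p];
  if (d.estimate_nu) {
    lp += P * (0.5 * nu * std::log(0.5 * nu) - std::lgamma(0.5 * nu));
    lp += (d.nu_a - 1.0) * std::log(nu - 2.0) - d.nu_b * (nu - 2.0) +
          std::log(nu - 2.0);  // Jacobian of lnu
  }
  // half-normal hyperpriors in log space
  for (int c = 0; c < C; ++c) {
    lp += -0.5 * sb[c] * sb[c] / (d.sb_scale * d.sb_scale) + lsb[c];
    lp += -0.5 * sd[c] * sd[c] / (d.sd_scale * d.sd_scale) + lsd[c];
  }
  // LKJ through independent scaled Betas on the partials + tanh Jacobian:
  // each contributes b_j * log(1 - z^2), b_j = eta + (C - 1 - j)/2 (1-based j)
  {
    int t = 0;
    for (int i = 1; i < C; ++i)
      for (int j = 0; j < i; ++j, ++t) {
        // (b_j - 1) from the scaled Beta kernel plus 1 from the tanh Jacobian
        const double bj = d.eta + 0.5 * (C - 2 - j);
        const double om = 1.0 - z[t] * z[t];
        if (om <= 0.0) return R_NegInf;
        lp += bj * std::log(om);
      }
  }

  if (!std::isfinite(lp)) return R_NegInf;
  if (!want_grad) return lp;

  // --- remaining gradients --------------------------------------------------
  // G_L(c, j): sensitivity of lp to L[c][j] through beta
  std::vector<double> GL(C * C, 0.0);
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      const double gb = gbeta_cc[p + P * c];
      if (gb == 0.0) continue;
      const double f = gb * sb[c] / sqg[p];
      for (int j = 0; j <= c; ++j) GL[c * C + j] += f * zbeta[p + P * j];
      // z_beta gradient
      for (int j = 0; j <= c; ++j)
        grad[d.o_zbeta() + p + P * j] += f * L[c * C + j];
      // u_g gradient: d beta / d u = -0.5 * beta
      grad[d.o_ug() + p] += gb * (-0.5) * beta[p + P * c];
      // lsb gradient: d beta / d lsb_c = beta
      grad[d.o_lsb() + c] += gb * beta[p + P * c];
    }
  }
  for (int i = 0; i < P * C; ++i) grad[d.o_zbeta() + i] -= zbeta[i];
  for (int p = 0; p < P; ++p)
    grad[d.o_ug() + p] += 0.5 * nu - 0.5 * nu * g[p];
  for (int c = 0; c < C; ++c) {
    grad[d.o_lsb() + c] += -sb[c] * sb[c] / (d.sb_scale * d.sb_scale) + 1.0;
    grad[d.o_lsd() + c] += -sd[c] * sd[c] / (d.sd_scale * d.sd_scale) + 1.0;
  }
  for (int c = 0; c < C; ++c)
    for (int e = 0; e < E; ++e) {
      grad[d.o_zdelta() + c + C * e] += gdelta_cc[c + C * e] * sd[c] -
                                        zdel[c + C * e];
      // d delta / d lsd_c = delta
      grad[d.o_lsd() + c] += gdelta_cc[c + C * e] * delta[c + C * e];
    }
  // partial-correlation gradients.  Within row i: L_ij = z_j * sqrt(rem_j),
  // rem_j = prod_{k<j} (1 - z_k^2), L_ii = sqrt(rem_i), so
  //   dL_ij/dz_k = -z_k/(1-z_k^2) * L_ij   (k < j <= i, incl. diagonal)
  //   dL_ij/dz_j = sqrt(rem_j)
  {
    int row_t0 = 0;
    for (int i = 1; i < C; ++i) {
      // rem_j values for this row
      std::vector<double> rem(i + 1);
      rem[0] = 1.0;
      for (int j = 0; j < i; ++j)
        rem[j + 1] = rem[j] * (1.0 - z[row_t0 + j] * z[row_t0 + j]);
      for (int k = 0; k < i; ++k) {
        const double zk = z[row_t0 + k];
        const double om = 1.0 - zk * zk;
        double dz = GL[i * C + k] * std::sqrt(rem[k]);
        for (int j = k + 1; j <= i; ++j)
          dz += GL[i * C + j] * L[i * C + j] * (-zk / om);
        const double bj = d.eta + 0.5 * (C - 2 - k);
        // chain through tanh (dz/dy = om) plus the Beta+Jacobian term -2*b_j*z
        grad[d.o_zc() + row_t0 + k] += dz * om - 2.0 * bj * zk;
      }
      row_t0 += i;
    }
  }
  if (d.estimate_nu) {
    double dnu = 0.0;
    for (int p = 0; p < P; ++p) dnu += 0.5 * ug[p] - 0.5 * g[p];
    dnu += P * (0.5 * std::log(0.5 * nu) + 0.5 - 0.5 * R::digamma(0.5 * nu));
    dnu += (d.nu_a - 1.0) / (nu - 2.0) - d.nu_b;
    grad[d.o_lnu()] = dnu * (nu - 2.0) + 1.0;
  }
  return lp;
}

// [[Rcpp::export]]
List cpp_logpost(NumericVector q, List model_data, bool gradient = true) {
  ModelData d = unpack_data(model_data);
  if ((int)q.size() != d.dim()) stop("parameter vector has wrong length");
  NumericVector grad(d.dim());
  double lp = logpost_grad(d, q.begin(), grad.begin(), gradient);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// [[Rcpp::export]]
int cpp_model_dim(List model_data) { return unpack_data(model_data).dim(); }

// ---------------------------------------------------------------------------
// NUTS

struct Sampler {
  const ModelData& d;
  int D;
  std::vector<double> minv;  // diagonal inverse mass (posterior variances)
  explicit Sampler(const ModelData& dd) : d(dd), D(dd.dim()), minv(dd.dim(), 1.0) {}

  double joint(const std::vector<double>& q, const std::vector<double>& p,
               double& lp_out, std::vector<double>& grad) {
    lp_out = logpost_grad(d, q.data(), grad.data(), true);
    double kin = 0.0;
    for (int i = 0; i < D; ++i) kin += 0.5 * p[i] * p[i] * minv[i];
    return lp_out - kin;
  }

  // one leapfrog step; returns log posterior at the new point
  double leapfrog(std::vector<double>& q, std::vector<double>& p,
                  std::vector<double>& grad, double eps) {
    for (int i = 0; i < D; ++i) p[i] += 0.5 * eps * grad[i];
    for (int i = 0; i < D; ++i) q[i] += eps * minv[i] * p[i];
    double lp = logpost_grad(d, q.data(), grad.data(), true);
    if (std::isfinite(lp)) {
      for (int i = 0; i < D; ++i) p[i] += 0.5 * eps * grad[i];
    }
    return lp;
  }

  bool no_uturn(const std::vector<double>& qm, const std::vector<double>& qp,
                const std::vector<double>& pm, const std::vector<double>& pp) {
    double sm = 0.0, sp = 0.0;
    for (int i = 0; i < D; ++i) {
      const double dq = qp[i] - qm[i];
      sm += dq * minv[i] * pm[i];
      sp += dq * minv[i] * pp[i];
    }
    return sm >= 0.0 && sp >= 0.0;
  }
};

struct Tree {
  std::vector<double> qm, pm, gm, qp, pp, gp, qprop;
  double lpprop;
  int n;
  bool ok;         // no divergence / U-turn inside
  bool divergent;
  double alpha;    // sum of acceptance statistics
  int nalpha;
};

static void build_tree(Sampler& S, const std::vector<double>& q,
                       const std::vector<double>& p,
                       const std::vector<double>& grad,
                       double logu, int dir, int depth, double eps,
                       double H0, Tree& out) {
  if (depth == 0) {
    out.qm = q; out.pm = p; out.gm = grad;
    double lp = 0.0;
    {
      std::vector<double> q1 = q, p1 = p, g1 = grad;
      lp = S.leapfrog(q1, p1, g1, dir * eps);
      out.qm = q1; out.pm = p1; out.gm = g1;
    }
    out.qp = out.qm; out.pp = out.pm; out.gp = out.gm;
    double H;
    if (std::isfinite(lp)) {
      double kin = 0.0;
      for (int i = 0; i < S.D; ++i) kin += 0.5 * out.pm[i] * out.pm[i] * S.minv[i];
      H = lp - kin;
    } else {
      H = R_NegInf;
    }
    out.qprop = out.qm; out.lpprop = lp;
    out.n = (logu <= H) ? 1 : 0;
    out.divergent = !(H - logu > -1000.0);  // logu - H > 1000 => divergence
    out.ok = !out.divergent;
    double adiff = H - H0;
    out.alpha = std::isfinite(adiff) ? std::min(1.0, std::exp(adiff)) : 0.0;
    out.nalpha = 1;
    return;
  }
  Tree t1;
  build_tree(S, q, p, grad, logu, dir, depth - 1, eps, H0, t1);
  out = t1;
  if (!t1.ok) return;
  Tree t2;
  if (dir == -1) {
    build_tree(S, t1.qm, t1.pm, t1.gm, logu, dir, depth - 1, eps, H0, t2);
    out.qm = t2.qm; out.pm = t2.pm; out.gm = t2.gm;
  } else {
    build_tree(S, t1.qp, t1.pp, t1.gp, logu, dir, depth - 1, eps, H0, t2);
    out.qp = t2.qp; out.pp = t2.pp; out.gp = t2.gp;
  }
  out.n = t1.n + t2.n;
  out.alpha = t1.alpha + t2.alpha;
  out.nalpha = t1.nalpha + t2.nalpha;
  out.divergent = t1.divergent || t2.divergent;
  if (t2.n > 0 && out.n > 0 &&
      R::unif_rand() < (double)t2.n / (double)out.n) {
    out.qprop = t2.qprop; out.lpprop = t2.lpprop;
  }
  out.ok = t2.ok && !out.divergent &&
           S.no_uturn(out.qm, out.qp, out.pm, out.pp);
}

static double find_epsilon(Sampler& S, const std::vector<double>& q0) {
  double eps = 0.1;
  std::vector<double> grad0(S.D);
  double lp0 = logpost_grad(S.d, q0.data(), grad0.data(), true);
  if (!std::isfinite(lp0)) return eps;
  std::vector<double> p0(S.D);
  for (int i = 0; i < S.D; ++i) p0[i] = R::norm_rand() / std::sqrt(S.minv[i]);
  double kin0 = 0.0;
  for (int i = 0; i < S.D; ++i) kin0 += 0.5 * p0[i] * p0[i] * S.minv[i];
  const double H0 = lp0 - kin0;
  std::vector<double> q = q0, p = p0, g = grad0;
  double lp = S.leapfrog(q, p, g, eps);
  double H;
  {
    double kin = 0.0;
    for (int i = 0; i < S.D; ++i) kin += 0.5 * p[i] * p[i] * S.minv[i];
    H = std::isfinite(lp) ? lp - kin : R_NegInf;
  }
  double diff = H - H0;
  const int dir = (std::isfinite(diff) && diff > std::log(0.5)) ? 1 : -1;
  for (int it = 0; it < 50; ++it) {
    q = q0; p = p0; g = grad0;
    lp = S.leapfrog(q, p, g, eps);
    double kin = 0.0;
    for (int i = 0; i < S.D; ++i) kin += 0.5 * p[i] * p[i] * S.minv[i];
    H = std::isfinite(lp) ? lp - kin : R_NegInf;
    diff = H - H0;
    if (dir == 1 && !(std::isfinite(diff) && diff > std::log(0.5))) break;
    if (dir == -1 && !(!std::isfinite(diff) || diff < std::log(0.5))) break;
    eps *= (dir == 1) ? 2.0 : 0.5;
    if (eps < 1e-10 || eps > 1e4) break;
  }
  return eps;
}

// [[Rcpp::export]]
List cpp_nuts(List model_data, NumericVector init, int n_warmup, int n_keep,
              double target_accept = 0.9, int max_treedepth = 10,
              bool adapt_mass = true) {
  ModelData d = unpack_data(model_data);
  Sampler S(d);
  const int D = d.dim();
  if ((int)init.size() != D) stop("init has wrong length");
  std::vector<double> q(init.begin(), init.end());
  {
    std::vector<double> g(D);
    double lp0 = logpost_grad(d, q.data(), g.data(), true);
    if (!std::isfinite(lp0)) stop("initial point has zero posterior density");
  }

  // dual averaging state
  double eps = find_epsilon(S, q);
  double mu_da = std::log(10.0 * eps), log_eps_bar = 0.0, h_bar = 0.0;
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  int da_count = 0;
  auto da_restart = [&](double e) {
    mu_da = std::log(10.0 * e); log_eps_bar = std::log(e);
    h_bar = 0.0; da_count = 0;
  };

  // mass adaptation windows over warmup
  std::vector<int> win_end;
  int collect_from = 0;
  if (adapt_mass && n_warmup >= 60) {
    const int b1 = std::max(15, n_warmup / 10);
    const int b3 = std::max(10, n_warmup / 10);
    const int mid = n_warmup - b1 - b3;
    collect_from = b1;
    win_end.push_back(b1 + mid / 3);
    win_end.push_back(b1 + mid);
  }
  std::vector<double> acc_m(D, 0.0), acc_s(D, 0.0);
  int acc_n = 0;
  auto acc_reset = [&]() { std::fill(acc_m.begin(), acc_m.end(), 0.0);
                           std::fill(acc_s.begin(), acc_s.end(), 0.0); acc_n = 0; };
  auto acc_add = [&](const std::vector<double>& x) {
    ++acc_n;
    for (int i = 0; i < D; ++i) {
      const double dlt = x[i] - acc_m[i];
      acc_m[i] += dlt / acc_n;
      acc_s[i] += dlt * (x[i] - acc_m[i]);
    }
  };

  NumericMatrix draws(n_keep, D);
  NumericVector energy(n_keep), accept_stat(n_keep);
  LogicalVector divergent(n_keep);
  IntegerVector treedepth(n_keep);
  int div_warmup = 0;

  const int total = n_warmup + n_keep;
  std::vector<double> grad(D), p(D);
  double lp = logpost_grad(d, q.data(), grad.data(), true);

  for (int it = 0; it < total; ++it) {
    for (int i = 0; i < D; ++i) p[i] = R::norm_rand() / std::sqrt(S.minv[i]);
    double kin = 0.0;
    for (int i = 0; i < D; ++i) kin += 0.5 * p[i] * p[i] * S.minv[i];
    const double H0 = lp - kin;
    const double logu = H0 - R::exp_rand();

    std::vector<double> qm = q, qp = q, pm = p, pp = p, gm = grad, gp = grad;
    std::vector<double> qcur = q;
    double lpcur = lp;
    int n_all = 1;
    bool keep_going = true, any_div = false;
    int depth = 0;
    double alpha_sum = 0.0; int nalpha_sum = 0;

    while (keep_going && depth < max_treedepth) {
      Tree t;
      const int dir = (R::unif_rand() < 0.5) ? -1 : 1;
      if (dir == -1) {
        build_tree(S, qm, pm, gm, logu, dir, depth, eps, H0, t);
        qm = t.qm; pm = t.pm; gm = t.gm;
      } else {
        build_tree(S, qp, pp, gp, logu, dir, depth, eps, H0, t);
        qp = t.qp; pp = t.pp; gp = t.gp;
      }
      alpha_sum += t.alpha; nalpha_sum += t.nalpha;
      any_div = any_div || t.divergent;
      if (t.ok && t.n > 0 &&
          R::unif_rand() < std::min(1.0, (double)t.n / (double)n_all)) {
        qcur = t.qprop; lpcur = t.lpprop;
      }
      n_all += t.n;
      keep_going = t.ok && S.no_uturn(qm, qp, pm, pp);
      ++depth;
    }
    q = qcur;
    lp = logpost_grad(d, q.data(), grad.data(), true);

    const double astat = nalpha_sum > 0 ? alpha_sum / nalpha_sum : 0.0;

    if (it < n_warmup) {
      if (any_div) ++div_warmup;
      // dual averaging
      ++da_count;
      const double frac = 1.0 / (da_count + da_t0);
      h_bar = (1.0 - frac) * h_bar + frac * (target_accept - astat);
      const double log_eps = mu_da - std::sqrt((double)da_count) / da_gamma * h_bar;
      const double w = std::pow((double)da_count, -da_kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      // mass windows
      if (!win_end.empty()) {
        if (it >= collect_from) acc_add(q);
        if (it + 1 == win_end.front()) {
          if (acc_n > 10) {
            const double w1 = (double)acc_n / (acc_n + 5.0);
            for (int i = 0; i < D; ++i) {
              const double v = acc_s[i] / std::max(acc_n - 1, 1);
              S.minv[i] = w1 * v + (1.0 - w1) * 1e-3;
              if (S.minv[i] < 1e-10) S.minv[i] = 1e-10;
            }
          }
          acc_reset();
          win_end.erase(win_end.begin());
          eps = find_epsilon(S, q);
          da_restart(eps);
        }
      }
      if (it + 1 == n_warmup) eps = std::exp(log_eps_bar);
    } else {
      const int j = it - n_warmup;
      for (int i = 0; i < D; ++i) draws(j, i) = q[i];
      double kin2 = 0.0;
      for (int i = 0; i < D; ++i) kin2 += 0.5 * p[i] * p[i] * S.minv[i];
      energy[j] = -lp + kin2;
      divergent[j] = any_div;
      treedepth[j] = depth;
      accept_stat[j] = astat;
    }
  }

  return List::create(
    _["draws"] = draws, _["energy"] = energy, _["divergent"] = divergent,
    _["treedepth"] = treedepth, _["accept_stat"] = accept_stat,
    _["stepsize"] = eps, _["inv_mass"] = NumericVector(S.minv.begin(), S.minv.end()),
    _["divergent_warmup"] = div_warmup);
}
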