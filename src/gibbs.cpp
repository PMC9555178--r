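// Gibbs samplers for the AFT illness-death model with shared frailty.
//
// Both samplers work on the augmented complete-data representation: every
// subject carries latent log times z1 (recurrence clock), z2 (direct-death
// clock) and, on the recurrence path, z3 (log sojourn).  A censored
// coordinate is drawn from its truncated-normal full conditional
// (right-censoring => truncation below at the censoring point on the
// relevant clock); given complete data every remaining block is conjugate,
// so no Metropolis step or proposal tuning is involved anywhere.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// N(mean, sd) truncated below at lo; inverse-CDF in the bulk, Robert's
// exponential rejection in the far right tail where qnorm loses accuracy
static double rtnorm_lower(double mean, double sd, double lo) {
  double a = (lo - mean) / sd;
  if (a < 4.0) {
    double plo = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = R::unif_rand();
    double p = plo + u * (1.0 - plo);
    if (p >= 1.0) p = 1.0 - 1e-16;
    return mean + sd * R::qnorm(p, 0.0, 1.0, 1, 0);
  }
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + R::exp_rand() / alpha;
    double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    if (R::unif_rand() <= rho) return mean + sd * z;
  }
}

static double rinvgamma(double shape, double rate) {
  return rate / R::rgamma(shape, 1.0);
}

// draw beta | z, gamma, sig2 with flat prior: N(bhat, sig2 * inv(X'X));
// U is the upper Cholesky factor of X'X (precomputed)
static arma::vec draw_beta(const arma::mat& X, const arma::mat& U,
                           const arma::vec& target, double sig2) {
  arma::vec bhat = arma::solve(arma::trimatu(U),
                    arma::solve(arma::trimatl(U.t()), X.t() * target));
  arma::vec eps(U.n_rows);
  for (arma::uword j = 0; j < eps.n_elem; ++j) eps(j) = R::norm_rand();
  return bhat + std::sqrt(sig2) * arma::solve(arma::trimatu(U), eps);
}

static void check_finite(const arma::vec& v, const char* block, int iter) {
  if (!v.is_finite())
    stop("non-finite full-conditional parameter in block '%s' at iteration %d",
         block, iter + 1);
}

// [[Rcpp::export(name = ".gibbs_lognormal")]]
List gibbs_lognormal_cpp(const arma::mat& X1, const arma::mat& X2,
                         const arma::mat& X3,
                         const arma::vec& lo1, const arma::vec& lo2,
                         const arma::vec& lo3,
                         const arma::ivec& obs1, const arma::ivec& obs2,
                         const arma::ivec& obs3,
                         const arma::uvec& idx3,  // 0-based recurrence rows
                         double a_theta, double b_theta,
                         const arma::vec& a_sig, const arma::vec& b_sig,
                         int n_iter, int n_burnin, int thin,
                         bool fix_theta, double theta_fixed,
                         const arma::vec& mu_init, const arma::vec& sig2_init,
                         double theta_init) {
  const int n = X1.n_rows;
  const int n3 = idx3.n_elem;
  const arma::mat X3a = n3 ? X3.rows(idx3) : arma::mat(0, X3.n_cols);
  const arma::mat U1 = arma::chol(X1.t() * X1);
  const arma::mat U2 = arma::chol(X2.t() * X2);
  arma::mat U3;
  if (n3) U3 = arma::chol(X3a.t() * X3a);

  // state
  arma::vec b1(X1.n_cols, arma::fill::zeros); b1(0) = mu_init(0);
  arma::vec b2(X2.n_cols, arma::fill::zeros); b2(0) = mu_init(1);
  arma::vec b3(X3.n_cols, arma::fill::zeros); b3(0) = mu_init(2);
  arma::vec sig2 = sig2_init;
  double theta = fix_theta ? theta_fixed : theta_init;
  arma::vec gamma(n, arma::fill::zeros);
  arma::vec z1 = lo1, z2 = lo2;
  arma::vec z3a(n3);
  for (int k = 0; k < n3; ++k) z3a(k) = lo3(idx3(k));
  arma::vec lo3a = z3a;
  arma::ivec obs3a(n3);
  for (int k = 0; k < n3; ++k) obs3a(k) = obs3(idx3(k));

  const int S = (n_iter - n_burnin) / thin;
  arma::mat out_b1(S, X1.n_cols), out_b2(S, X2.n_cols), out_b3(S, X3.n_cols);
  arma::mat out_sig2(S, 3), out_gamma(S, n);
  arma::vec out_theta(S);
  int s = 0;

  for (int it = 0; it < n_iter; ++it) {
    // (i) data augmentation for censored coordinates
    arma::vec eta1 = X1 * b1 + gamma;
    arma::vec eta2 = X2 * b2 + gamma;
    double s1 = std::sqrt(sig2(0)), s2 = std::sqrt(sig2(1)),
           s3 = std::sqrt(sig2(2));
    for (int i = 0; i < n; ++i) {
      if (!obs1(i)) z1(i) = rtnorm_lower(eta1(i), s1, lo1(i));
      if (!obs2(i)) z2(i) = rtnorm_lower(eta2(i), s2, lo2(i));
    }
    if (n3) {
      arma::vec eta3 = X3a * b3 + gamma.elem(idx3);
      for (int k = 0; k < n3; ++k)
        if (!obs3a(k)) z3a(k) = rtnorm_lower(eta3(k), s3, lo3a(k));
    }

    // (ii) conjugate regression blocks per transition
    b1 = draw_beta(X1, U1, z1 - gamma, sig2(0));
    check_finite(b1, "beta1", it);
    b2 = draw_beta(X2, U2, z2 - gamma, sig2(1));
    check_finite(b2, "beta2", it);
    if (n3) {
      b3 = draw_beta(X3a, U3, z3a - gamma.elem(idx3), sig2(2));
      check_finite(b3, "beta3", it);
    }
    arma::vec r1 = z1 - X1 * b1 - gamma;
    arma::vec r2 = z2 - X2 * b2 - gamma;
    arma::vec r3 = n3 ? arma::vec(z3a - X3a * b3 - gamma.elem(idx3))
                      : arma::vec();
    sig2(0) = rinvgamma(a_sig(0) + 0.5 * n, b_sig(0) + 0.5 * arma::dot(r1, r1));
    sig2(1) = rinvgamma(a_sig(1) + 0.5 * n, b_sig(1) + 0.5 * arma::dot(r2, r2));
    if (n3)
      sig2(2) = rinvgamma(a_sig(2) + 0.5 * n3,
                          b_sig(2) + 0.5 * arma::dot(r3, r3));
    check_finite(sig2, "sigma2", it);

    // (iii) frailties: normal full conditionals
    if (fix_theta && theta_fixed == 0.0) {
      gamma.zeros();
    } else {
      arma::vec m1 = z1 - X1 * b1, m2 = z2 - X2 * b2;
      arma::vec num = m1 / sig2(0) + m2 / sig2(1);
      arma::vec prec(n);
      prec.fill(1.0 / theta + 1.0 / sig2(0) + 1.0 / sig2(1));
      if (n3) {
        arma::vec m3 = z3a - X3a * b3;
        for (int k = 0; k < n3; ++k) {
          num(idx3(k)) += m3(k) / sig2(2);
          prec(idx3(k)) += 1.0 / sig2(2);
        }
      }
      for (int i = 0; i < n; ++i)
        gamma(i) = num(i) / prec(i) + R::norm_rand() / std::sqrt(prec(i));
      check_finite(gamma, "gamma", it);

      // (iv) frailty variance
      if (!fix_theta) {
        theta = rinvgamma(a_theta + 0.5 * n,
                          b_theta + 0.5 * arma::dot(gamma, gamma));
        if (!std::isfinite(theta))
          stop("non-finite full-conditional parameter in block 'theta' at iteration %d",
               it + 1);
      }
    }

    if (it >= n_burnin && (it - n_burnin) % thin == 0 && s < S) {
      out_b1.row(s) = b1.t();
      out_b2.row(s) = b2.t();
      out_b3.row(s) = b3.t();
      out_sig2.row(s) = sig2.t();
      out_theta(s) = theta;
      out_gamma.row(s) = gamma.t();
      ++s;
    }
  }

  return List::create(_["beta1"] = out_b1, _["beta2"] = out_b2,
                      _["beta3"] = out_b3, _["sigma2"] = out_sig2,
                      _["theta"] = out_theta, _["gamma"] = out_gamma);
}

// categorical draw from unnormalized log weights; ties and numerical
// equalities resolve to the lowest index by the cumulative-sum scan
static int draw_cat(const arma::vec& logw) {
  double mx = logw.max();
  arma::vec w = arma::exp(logw - mx);
  double tot = arma::accu(w);
  double u = R::unif_rand() * tot, c = 0.0;
  for (arma::uword r = 0; r < w.n_elem; ++r) {
    c += w(r);
    if (u <= c) return r;
  }
  return w.n_elem - 1;
}

struct DPMState {
  arma::ivec r;       // cluster assignment per active row
  arma::vec v, w;     // sticks and weights (length M)
  arma::vec muc, s2c; // cluster locations / variances
  double alpha;       // concentration
};

// one DPM sweep for a single transition error distribution given the
// residuals u = z - X b - gamma of its active rows
static void dpm_sweep(DPMState& st, const arma::vec& u, int M,
                      double kappa0, double m0, double a0, double b0,
                      double alpha_shape, double alpha_rate) {
  const int n = u.n_elem;
  // assignments
  arma::vec logw = arma::log(st.w);
  for (int i = 0; i < n; ++i) {
    arma::vec lp(M);
    for (int r = 0; r < M; ++r)
      lp(r) = logw(r) + R::dnorm(u(i), st.muc(r), std::sqrt(st.s2c(r)), 1);
    st.r(i) = draw_cat(lp);
  }
  // cluster normal-inverse-gamma updates
  arma::ivec cnt(M, arma::fill::zeros);
  arma::vec sum(M, arma::fill::zeros), ssq(M, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    cnt(st.r(i))++;
    sum(st.r(i)) += u(i);
    ssq(st.r(i)) += u(i) * u(i);
  }
  for (int r = 0; r < M; ++r) {
    double nr = cnt(r);
    double ub = nr > 0 ? sum(r) / nr : 0.0;
    double kn = kappa0 + nr;
    double mn = (kappa0 * m0 + sum(r)) / kn;
    double an = a0 + 0.5 * nr;
    double ss = ssq(r) - nr * ub * ub;  // within-cluster sum of squares
    double bn = b0 + 0.5 * ss + 0.5 * kappa0 * nr * (ub - m0) * (ub - m0) / kn;
    st.s2c(r) = rinvgamma(an, bn);
    st.muc(r) = mn + R::norm_rand() * std::sqrt(st.s2c(r) / kn);
  }
  // truncated stick-breaking weights
  arma::ivec tail(M, arma::fill::zeros);
  int acc = 0;
  for (int r = M - 1; r >= 0; --r) { tail(r) = acc; acc += cnt(r); }
  double logret = 0.0, sumlog1mv = 0.0;
  for (int r = 0; r < M; ++r) {
    if (r < M - 1) {
      double v = R::rbeta(1.0 + cnt(r), st.alpha + tail(r));
      if (v > 1.0 - 1e-12) v = 1.0 - 1e-12;
      st.v(r) = v;
      st.w(r) = std::exp(logret) * v;
      logret += std::log1p(-v);
      sumlog1mv += std::log1p(-v);
    } else {
      st.v(r) = 1.0;
      st.w(r) = std::exp(logret);
    }
  }
  // concentration: conjugate under truncated stick-breaking
  st.alpha = R::rgamma(alpha_shape + M - 1, 1.0 / (alpha_rate - sumlog1mv));
  if (st.alpha < 1e-8) st.alpha = 1e-8;
}

// [[Rcpp::export(name = ".gibbs_dpm")]]
List gibbs_dpm_cpp(const arma::mat& X1, const arma::mat& X2,
                   const arma::mat& X3,
                   const arma::vec& lo1, const arma::vec& lo2,
                   const arma::vec& lo3,
                   const arma::ivec& obs1, const arma::ivec& obs2,
                   const arma::ivec& obs3, const arma::uvec& idx3,
                   double a_theta, double b_theta,
                   int M, double alpha_shape, double alpha_rate,
                   double kappa0, const arma::vec& m0,
                   double a0, double b0,
                   int n_iter, int n_burnin, int thin,
                   bool fix_theta, double theta_fixed,
                   const arma::vec& mu_init, const arma::vec& sig2_init,
                   double theta_init) {
  const int n = X1.n_rows;
  const int n3 = idx3.n_elem;
  const arma::mat X3a = n3 ? X3.rows(idx3) : arma::mat(0, X3.n_cols);
  const int p1 = X1.n_cols, p2 = X2.n_cols, p3 = X3.n_cols;

  arma::vec b1(p1, arma::fill::zeros), b2(p2, arma::fill::zeros),
            b3(p3, arma::fill::zeros);
  double theta = fix_theta ? theta_fixed : theta_init;
  arma::vec gamma(n, arma::fill::zeros);
  arma::vec z1 = lo1, z2 = lo2;
  arma::vec z3a(n3), lo3a(n3);
  arma::ivec obs3a(n3);
  for (int k = 0; k < n3; ++k) {
    z3a(k) = lo3(idx3(k));
    lo3a(k) = z3a(k);
    obs3a(k) = obs3(idx3(k));
  }

  // mixture states: start from one effective cluster at the empirical
  // location/scale, remaining sticks near-empty
  DPMState st[3];
  const int nact[3] = {n, n, n3};
  for (int g = 0; g < 3; ++g) {
    st[g].r = arma::ivec(nact[g], arma::fill::zeros);
    st[g].v = arma::vec(M, arma::fill::value(0.5));
    st[g].w = arma::vec(M);
    double logret = 0.0;
    for (int r = 0; r < M; ++r) {
      if (r < M - 1) {
        st[g].w(r) = std::exp(logret) * 0.5;
        logret += std::log(0.5);
      } else st[g].w(r) = std::exp(logret);
    }
    st[g].v(M - 1) = 1.0;
    st[g].muc = arma::vec(M, arma::fill::value(m0(g)));
    st[g].s2c = arma::vec(M, arma::fill::value(sig2_init(g)));
    st[g].muc(0) = mu_init(g);
    st[g].alpha = 1.0;
  }

  const int S = (n_iter - n_burnin) / thin;
  arma::mat out_b1(S, p1), out_b2(S, p2), out_b3(S, p3);
  arma::mat out_gamma(S, n);
  arma::vec out_theta(S);
  arma::mat out_w[3], out_muc[3], out_s2c[3];
  arma::mat out_alpha(S, 3), out_nocc(S, 3);
  for (int g = 0; g < 3; ++g) {
    out_w[g].set_size(S, M);
    out_muc[g].set_size(S, M);
    out_s2c[g].set_size(S, M);
  }
  int s = 0;

  for (int it = 0; it < n_iter; ++it) {
    // per-row component location/scale for each transition
    arma::vec off1(n), sd1(n), off2(n), sd2(n);
    for (int i = 0; i < n; ++i) {
      off1(i) = st[0].muc(st[0].r(i)); sd1(i) = std::sqrt(st[0].s2c(st[0].r(i)));
      off2(i) = st[1].muc(st[1].r(i)); sd2(i) = std::sqrt(st[1].s2c(st[1].r(i)));
    }
    arma::vec eta1 = X1 * b1 + gamma, eta2 = X2 * b2 + gamma;
    for (int i = 0; i < n; ++i) {
      if (!obs1(i)) z1(i) = rtnorm_lower(eta1(i) + off1(i), sd1(i), lo1(i));
      if (!obs2(i)) z2(i) = rtnorm_lower(eta2(i) + off2(i), sd2(i), lo2(i));
    }
    arma::vec off3(n3), sd3(n3);
    if (n3) {
      arma::vec eta3 = X3a * b3 + gamma.elem(idx3);
      for (int k = 0; k < n3; ++k) {
        off3(k) = st[2].muc(st[2].r(k));
        sd3(k) = std::sqrt(st[2].s2c(st[2].r(k)));
        if (!obs3a(k)) z3a(k) = rtnorm_lower(eta3(k) + off3(k), sd3(k), lo3a(k));
      }
    }

    // mixture blocks on current residuals
    arma::vec u1 = z1 - X1 * b1 - gamma;
    arma::vec u2 = z2 - X2 * b2 - gamma;
    dpm_sweep(st[0], u1, M, kappa0, m0(0), a0, b0, alpha_shape, alpha_rate);
    dpm_sweep(st[1], u2, M, kappa0, m0(1), a0, b0, alpha_shape, alpha_rate);
    if (n3) {
      arma::vec u3 = z3a - X3a * b3 - gamma.elem(idx3);
      dpm_sweep(st[2], u3, M, kappa0, m0(2), a0, b0, alpha_shape, alpha_rate);
    }

    // weighted least-squares block for beta_g (flat prior)
    for (int g = 0; g < 3; ++g) {
      const arma::mat& X = g == 0 ? X1 : (g == 1 ? X2 : X3a);
      if (X.n_cols == 0 || X.n_rows == 0) continue;
      arma::vec z = g == 0 ? z1 : (g == 1 ? z2 : z3a);
      arma::vec gm = g == 2 ? arma::vec(gamma.elem(idx3)) : gamma;
      arma::vec tgt(X.n_rows), tau(X.n_rows);
      for (arma::uword i = 0; i < X.n_rows; ++i) {
        int r = st[g].r(i);
        tgt(i) = z(i) - gm(i) - st[g].muc(r);
        tau(i) = 1.0 / st[g].s2c(r);
      }
      arma::mat Xw = X.each_col() % tau;
      arma::mat A = X.t() * Xw;
      arma::vec bvec = Xw.t() * tgt;
      arma::mat U = arma::chol(A);
      arma::vec bhat = arma::solve(arma::trimatu(U),
                        arma::solve(arma::trimatl(U.t()), bvec));
      arma::vec eps(X.n_cols);
      for (arma::uword j = 0; j < eps.n_elem; ++j) eps(j) = R::norm_rand();
      arma::vec bdraw = bhat + arma::solve(arma::trimatu(U), eps);
      check_finite(bdraw, g == 0 ? "beta1" : (g == 1 ? "beta2" : "beta3"), it);
      if (g == 0) b1 = bdraw; else if (g == 1) b2 = bdraw; else b3 = bdraw;
    }

    // frailties
    if (fix_theta && theta_fixed == 0.0) {
      gamma.zeros();
    } else {
      arma::vec num(n, arma::fill::zeros), prec(n);
      prec.fill(1.0 / theta);
      arma::vec f1 = z1 - X1 * b1, f2 = z2 - X2 * b2;
      for (int i = 0; i < n; ++i) {
        double t1 = 1.0 / st[0].s2c(st[0].r(i));
        double t2 = 1.0 / st[1].s2c(st[1].r(i));
        num(i) += (f1(i) - st[0].muc(st[0].r(i))) * t1 +
                  (f2(i) - st[1].muc(st[1].r(i))) * t2;
        prec(i) += t1 + t2;
      }
      if (n3) {
        arma::vec f3 = z3a - X3a * b3;
        for (int k = 0; k < n3; ++k) {
          double t3 = 1.0 / st[2].s2c(st[2].r(k));
          num(idx3(k)) += (f3(k) - st[2].muc(st[2].r(k))) * t3;
          prec(idx3(k)) += t3;
        }
      }
      for (int i = 0; i < n; ++i)
        gamma(i) = num(i) / prec(i) + R::norm_rand() / std::sqrt(prec(i));
      check_finite(gamma, "gamma", it);
      if (!fix_theta) {
        theta = rinvgamma(a_theta + 0.5 * n,
                          b_theta + 0.5 * arma::dot(gamma, gamma));
        if (!std::isfinite(theta) || theta < 1e-12) theta = 1e-12;
      }
    }

    if (it >= n_burnin && (it - n_burnin) % thin == 0 && s < S) {
      out_b1.row(s) = b1.t();
      out_b2.row(s) = b2.t();
      out_b3.row(s) = b3.t();
      out_theta(s) = theta;
      out_gamma.row(s) = gamma.t();
      for (int g = 0; g < 3; ++g) {
        out_w[g].row(s) = st[g].w.t();
        out_muc[g].row(s) = st[g].muc.t();
        out_s2c[g].row(s) = st[g].s2c.t();
        arma::ivec cnt(M, arma::fill::zeros);
        for (arma::uword i = 0; i < st[g].r.n_elem; ++i) cnt(st[g].r(i))++;
        int occ = 0;
        for (int r = 0; r < M; ++r) if (cnt(r) > 0) ++occ;
        out_nocc(s, g) = occ;
        out_alpha(s, g) = st[g].alpha;
      }
      ++s;
    }
  }

  return List::create(_["beta1"] = out_b1, _["beta2"] = out_b2,
                      _["beta3"] = out_b3, _["theta"] = out_theta,
                      _["gamma"] = out_gamma,
                      _["w1"] = out_w[0], _["w2"] = out_w[1],
                      _["w3"] = out_w[2],
                      _["mu1"] = out_muc[0], _["mu2"] = out_muc[1],
                      _["mu3"] = out_muc[2],
                      _["s2_1"] = out_s2c[0], _["s2_2"] = out_s2c[1],
                      _["s2_3"] = out_s2c[2],
                      _["alpha"] = out_alpha, _["n_occ"] = out_nocc);
}
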