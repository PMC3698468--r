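// Penalized IRLS engine for the logit-normal-binomial mixed model.
//
// Model: y_i ~ Binomial(N_i, p_i), logit(p_i) = x_i'beta + sum_f sigma_f u_f[level_f(i)]
//        + sigma_obs u_obs[i], with u ~ N(0, I) on the spherical scale.
//
// The observation-level factor contributes a diagonal block to the penalized
// normal equations, so each IRLS step is solved by a Schur complement onto the
// small dense core (fixed effects + the grouping factors): with
// d_i = 1 + sigma_obs^2 w_i the obs block is eliminated analytically and the
// core system uses shrunken weights wt_i = w_i / d_i.  Cost per iteration is
// O(n k^2) with k = p + sum(nlev), which stays small for this model class.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double log1p_exp(double x) {
  if (x > 33.0) return x;
  if (x < -33.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// -2 * binomial loglik (without the lchoose constant) at linear predictor eta
static double neg2ll(const vec& y, const vec& size, const vec& eta) {
  double ll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i)
    ll += y[i] * eta[i] - size[i] * log1p_exp(eta[i]);
  return -2.0 * ll;
}

// When p = 0 the fixed part enters through `offset` only and the solve is
// over the random effects alone (used when beta sits in the outer
// optimizer); maxit = 0 evaluates the system and Hessian at `start` without
// iterating (used to extract SEs at the reported estimates).
// Laplace criterion at fixed (sigma, beta): PIRLS for the random-effect
// modes only (u, u_obs warm-started in place), then deviance + |u|^2 +
// log-determinant.  Lean inner kernel for the C++ Nelder-Mead below.
static double laplace_obj(const mat& X, const vec& y, const vec& size,
                          const umat& fidx, const uvec& nlev,
                          const vec& sigma_small, double sigma_obs,
                          const vec& beta, vec& u, vec& u_obs,
                          double tol, int maxit, bool& ok) {
  const uword n = y.n_elem, m = nlev.n_elem;
  const uword k = accu(nlev);
  const double so2 = sigma_obs * sigma_obs;
  vec offset = (X.n_cols > 0) ? vec(X * beta) : vec(n, fill::zeros);

  mat G(n, k, fill::zeros);
  uvec off(m);
  uword pos = 0;
  for (uword f = 0; f < m; ++f) {
    off[f] = pos;
    for (uword i = 0; i < n; ++i) G(i, pos + fidx(i, f)) = sigma_small[f];
    pos += nlev[f];
  }

  auto pdev_at = [&](const vec& uu, const vec& uo) {
    vec eta = offset + G * uu + sigma_obs * uo;
    return neg2ll(y, size, eta) + dot(uu, uu) + dot(uo, uo);
  };

  double pdev = pdev_at(u, u_obs);
  if (!std::isfinite(pdev) || pdev > pdev_at(zeros(k), zeros(n))) {
    u.zeros(); u_obs.zeros();
    pdev = pdev_at(u, u_obs);
  }

  vec w(n), wt(n), zt(n);
  mat S;
  bool conv = false;
  for (int iter = 1; iter <= maxit; ++iter) {
    vec eta = offset + G * u + sigma_obs * u_obs;
    for (uword i = 0; i < n; ++i) {
      double e = std::min(30.0, std::max(-30.0, eta[i]));
      double pi = 1.0 / (1.0 + std::exp(-e));
      double wi = size[i] * pi * (1.0 - pi);
      if (wi < 1e-10) wi = 1e-10;
      w[i] = wi;
      wt[i] = wi / (1.0 + so2 * wi);
      zt[i] = eta[i] + (y[i] - size[i] * pi) / wi - offset[i];
    }
    S = trans(G) * (G.each_col() % wt);
    S.diag() += 1.0;
    vec rhs = trans(G) * (wt % zt);
    mat R;
    mat Sreg = S;
    double ridge = 0.0;
    int tries = 0;
    while (!chol(R, Sreg) && tries < 8) {
      ridge = (ridge == 0.0) ? 1e-10 * S.diag().max() : ridge * 100.0;
      Sreg = S;
      Sreg.diag() += ridge;
      ++tries;
    }
    if (tries >= 8) { ok = false; return 1e300; }
    vec u_new = solve(trimatu(R), solve(trimatl(trans(R)), rhs));
    vec r = zt - G * u_new;
    vec uo_new = (sigma_obs * (w % r)) / (1.0 + so2 * w);

    double step = 1.0, pdev_new = datum::inf;
    vec u_try, uo_try;
    bool accepted = false;
    for (int h = 0; h < 20; ++h) {
      u_try = u + step * (u_new - u);
      uo_try = u_obs + step * (uo_new - u_obs);
      pdev_new = pdev_at(u_try, uo_try);
      if (pdev_new <= pdev + 1e-12 * (std::abs(pdev) + 1.0)) { accepted = true; break; }
      step *= 0.5;
    }
    if (!accepted) break;
    double delta = pdev - pdev_new;
    u = u_try; u_obs = uo_try;
    pdev = pdev_new;
    if (std::abs(delta) < tol * (std::abs(pdev) + 1.0)) { conv = true; break; }
  }
  (void)conv;   // maxit-exhausted evaluations still return a usable value

  // final weights, logdet
  vec eta = offset + G * u + sigma_obs * u_obs;
  double logdet = 0.0;
  for (uword i = 0; i < n; ++i) {
    double e = std::min(30.0, std::max(-30.0, eta[i]));
    double pi = 1.0 / (1.0 + std::exp(-e));
    double wi = size[i] * pi * (1.0 - pi);
    if (wi < 1e-10) wi = 1e-10;
    w[i] = wi;
    wt[i] = wi / (1.0 + so2 * wi);
    if (sigma_obs > 0.0) logdet += std::log1p(so2 * wi);
  }
  if (k > 0) {
    S = trans(G) * (G.each_col() % wt);
    S.diag() += 1.0;
    mat R;
    if (chol(R, S)) logdet += 2.0 * accu(log(R.diag()));
    else { ok = false; return 1e300; }
  }
  return neg2ll(y, size, eta) + dot(u, u) + dot(u_obs, u_obs) + logdet;
}

// Nelder-Mead over psi = (sigma_free, beta) run entirely in C++; the
// objective is the Laplace criterion with the random-effect modes solved by
// PIRLS (warm-started across evaluations).  sigma enters through |psi| — the
// criterion is even in each SD, which turns the boundary at zero into a
// smooth interior point.  free_idx (0-based) maps psi's leading entries into
// the (species, plot, obs) SD triple; fixed entries keep sigma0's values.
// [[Rcpp::export(name = ".laplace_nm")]]
Rcpp::List laplace_nm(const arma::mat& X,
                      const arma::vec& y,
                      const arma::vec& size,
                      const arma::umat& fidx,
                      const arma::uvec& nlev,
                      const arma::vec& sigma0,     // length 3: species, plot, obs
                      const arma::uvec& free_idx,  // indices into sigma0
                      const arma::vec& psi0,       // (sigma_free, beta)
                      const double inner_tol, const int inner_maxit,
                      const double reltol, const int maxit,
                      const double init_step) {
  const uword nf = free_idx.n_elem, p = X.n_cols, d = psi0.n_elem;
  vec u(accu(nlev), fill::zeros), u_obs(y.n_elem, fill::zeros);
  std::vector<double> trace;
  trace.reserve(maxit + d + 2);

  auto fn = [&](const vec& psi) {
    vec sig = sigma0;
    for (uword j = 0; j < nf; ++j)
      sig[free_idx[j]] = std::min(std::abs(psi[j]), 50.0);
    bool ok = true;
    double v = laplace_obj(X, y, size, fidx, nlev, sig.head(2), sig[2],
                           psi.tail(p), u, u_obs, inner_tol, inner_maxit, ok);
    if (!ok || !std::isfinite(v)) v = 1e300;
    trace.push_back(v);
    return v;
  };

  // simplex initialisation as in stats::optim
  mat P(d, d + 1);
  vec fv(d + 1);
  P.col(0) = psi0;
  fv[0] = fn(psi0);
  for (uword j = 0; j < d; ++j) {
    vec pj = psi0;
    double step = init_step * std::abs(pj[j]);
    if (step < init_step) step = init_step;
    pj[j] += step;
    P.col(j + 1) = pj;
    fv[j + 1] = fn(pj);
  }

  int nev = (int)(d + 1);
  const double alpha = 1.0, gammaE = 2.0, rhoC = 0.5, sigS = 0.5;
  while (nev < maxit) {
    uvec ord = sort_index(fv);
    P = P.cols(ord); fv = fv(ord);
    if (fv[d] - fv[0] <= reltol * (std::abs(fv[0]) + reltol)) break;
    vec centroid = mean(P.cols(0, d - 1), 1);
    vec xr = centroid + alpha * (centroid - P.col(d));
    double fr = fn(xr); ++nev;
    if (fr < fv[0]) {
      vec xe = centroid + gammaE * (xr - centroid);
      double fe = fn(xe); ++nev;
      if (fe < fr) { P.col(d) = xe; fv[d] = fe; }
      else { P.col(d) = xr; fv[d] = fr; }
    } else if (fr < fv[d - 1]) {
      P.col(d) = xr; fv[d] = fr;
    } else {
      bool outside = fr < fv[d];
      vec xc;
      if (outside) xc = centroid + rhoC * (xr - centroid);
      else         xc = centroid - rhoC * (centroid - P.col(d));
      double fc = fn(xc); ++nev;
      if (fc < (outside ? fr : fv[d])) { P.col(d) = xc; fv[d] = fc; }
      else {               // shrink toward the best vertex
        for (uword j = 1; j <= d; ++j) {
          P.col(j) = P.col(0) + sigS * (P.col(j) - P.col(0));
          fv[j] = fn(P.col(j)); ++nev;
        }
      }
    }
  }
  uvec ord = sort_index(fv);
  vec best = P.col(ord[0]);
  return Rcpp::List::create(
    Rcpp::Named("par") = best,
    Rcpp::Named("value") = fv[ord[0]],
    Rcpp::Named("evals") = (int)trace.size(),
    Rcpp::Named("trace") = trace,
    Rcpp::Named("u") = u,
    Rcpp::Named("u_obs") = u_obs);
}

// [[Rcpp::export(name = ".pirls_engine")]]
Rcpp::List pirls_engine(const arma::mat& X,
                        const arma::vec& y,
                        const arma::vec& size,
                        const arma::vec& offset,  // length n
                        const arma::umat& fidx,   // n x m, 0-based level codes
                        const arma::uvec& nlev,   // m
                        const arma::vec& sigma,   // m, SD scale, >= 0
                        const double sigma_obs,
                        arma::vec start,          // length k = p + sum(nlev)
                        arma::vec u_obs,          // length n
                        const double tol,
                        const int maxit,
                        const bool compute_se) {
  const uword n = X.n_rows, p = X.n_cols, m = nlev.n_elem;
  const uword k = p + accu(nlev);
  const double so2 = sigma_obs * sigma_obs;

  // dense core design: [X | indicator columns scaled by sigma_f]
  mat G(n, k, fill::zeros);
  if (p > 0) G.cols(0, p - 1) = X;
  uvec off(m);
  uword pos = p;
  for (uword f = 0; f < m; ++f) {
    off[f] = pos;
    for (uword i = 0; i < n; ++i) G(i, pos + fidx(i, f)) = sigma[f];
    pos += nlev[f];
  }

  vec pen(k, fill::ones);
  pen.head(p).zeros();          // no penalty on beta

  if (start.n_elem != k) { start.zeros(k); }
  if (u_obs.n_elem != n) { u_obs.zeros(n); }
  vec c = start;

  auto pdev_at = [&](const vec& cc, const vec& uo) {
    vec eta = offset + G * cc + sigma_obs * uo;
    double pen_u = dot(cc.tail(k - p), cc.tail(k - p)) + dot(uo, uo);
    return neg2ll(y, size, eta) + pen_u;
  };

  double pdev = pdev_at(c, u_obs);
  // guard against a divergent warm start: fall back to the origin if better
  if (maxit > 0 && (!std::isfinite(pdev) || pdev > pdev_at(zeros(k), zeros(n)))) {
    c.zeros(); u_obs.zeros();
    pdev = pdev_at(c, u_obs);
  }
  bool conv = false;
  int iter = 0;
  vec w(n), wt(n), z(n);
  mat S;

  if (maxit == 0) conv = true;   // evaluation-only mode
  for (iter = 1; iter <= maxit; ++iter) {
    vec eta = offset + G * c + sigma_obs * u_obs;
    for (uword i = 0; i < n; ++i) {
      double e = std::min(30.0, std::max(-30.0, eta[i]));
      double pi = 1.0 / (1.0 + std::exp(-e));
      double wi = size[i] * pi * (1.0 - pi);
      if (wi < 1e-10) wi = 1e-10;
      w[i] = wi;
      z[i] = eta[i] + (y[i] - size[i] * pi) / wi;
      wt[i] = wi / (1.0 + so2 * wi);
    }
    vec zt = z - offset;          // working response for the solved part
    S = trans(G) * (G.each_col() % wt);
    S.diag() += pen;
    vec rhs = trans(G) * (wt % zt);
    // Cholesky with ridge escalation: near-singular systems arise while the
    // outer optimizer explores very large sigma (indicator columns approach
    // collinearity with the intercept); a vanishing relative ridge keeps the
    // step well-defined without distorting converged solutions.
    mat R;
    mat Sreg = S;
    double ridge = 0.0;
    int tries = 0;
    while (!chol(R, Sreg) && tries < 8) {
      ridge = (ridge == 0.0) ? 1e-10 * S.diag().max() : ridge * 100.0;
      Sreg = S;
      Sreg.diag() += ridge;
      ++tries;
    }
    if (tries >= 8) Rcpp::stop("penalized normal equations not positive definite");
    vec c_new = solve(trimatu(R), solve(trimatl(trans(R)), rhs));

    // obs-level modes given the core solution
    vec r = zt - G * c_new;
    vec uo_new = (sigma_obs * (w % r)) / (1.0 + so2 * w);

    // step halving on the penalized deviance; a worse point is never accepted
    double step = 1.0, pdev_new = datum::inf;
    vec c_try, uo_try;
    bool accepted = false;
    for (int h = 0; h < 20; ++h) {
      c_try = c + step * (c_new - c);
      uo_try = u_obs + step * (uo_new - u_obs);
      pdev_new = pdev_at(c_try, uo_try);
      if (pdev_new <= pdev + 1e-12 * (std::abs(pdev) + 1.0)) { accepted = true; break; }
      step *= 0.5;
    }
    if (!accepted) break;   // numerically stalled; caller may retry cold
    double delta = pdev - pdev_new;
    c = c_try; u_obs = uo_try;
    pdev = pdev_new;
    if (std::abs(delta) < tol * (std::abs(pdev) + 1.0)) { conv = true; break; }
  }

  // final weights and system at the mode (for logdet and SEs)
  vec eta = offset + G * c + sigma_obs * u_obs;
  for (uword i = 0; i < n; ++i) {
    double e = std::min(30.0, std::max(-30.0, eta[i]));
    double pi = 1.0 / (1.0 + std::exp(-e));
    double wi = size[i] * pi * (1.0 - pi);
    if (wi < 1e-10) wi = 1e-10;
    w[i] = wi;
    wt[i] = wi / (1.0 + so2 * wi);
  }
  S = trans(G) * (G.each_col() % wt);
  S.diag() += pen;

  // log|I + Lambda' Z' W Z Lambda| via Schur: obs block first, then the
  // u-submatrix of the core system (its penalty is exactly I).
  double logdet = 0.0;
  if (sigma_obs > 0.0)
    for (uword i = 0; i < n; ++i) logdet += std::log1p(so2 * w[i]);
  if (k > p) {
    mat Suu = S.submat(p, p, k - 1, k - 1);
    mat R;
    if (chol(R, Suu)) logdet += 2.0 * accu(log(R.diag()));
    else logdet += datum::nan;
  }

  double obj = neg2ll(y, size, eta) +
    dot(c.tail(k - p), c.tail(k - p)) + dot(u_obs, u_obs) + logdet;

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("objective") = obj,
    Rcpp::Named("coef") = c.head(p),
    Rcpp::Named("u") = c.tail(k - p),
    Rcpp::Named("u_obs") = u_obs,
    Rcpp::Named("eta") = eta,
    Rcpp::Named("logdet") = logdet,
    Rcpp::Named("pdev") = pdev,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("iter") = iter);

  if (compute_se) {
    mat Sinv;
    if (!inv_sympd(Sinv, S)) Sinv = pinv(S);
    vec se_beta;
    if (p > 0) se_beta = sqrt(Sinv.submat(0, 0, p - 1, p - 1).diag());
    // conditional SDs of b = sigma u from the joint (beta, u) Hessian inverse
    vec cond_sd_u(k - p, fill::zeros);
    for (uword f = 0; f < m; ++f)
      for (uword j = 0; j < nlev[f]; ++j)
        cond_sd_u[off[f] - p + j] =
          sigma[f] * std::sqrt(Sinv(off[f] + j, off[f] + j));
    vec cond_sd_obs(n, fill::zeros);
    if (sigma_obs > 0.0) {
      for (uword i = 0; i < n; ++i) {
        double di = 1.0 + so2 * w[i];
        rowvec gi = G.row(i);
        double q = as_scalar(gi * Sinv * trans(gi));
        double vu = 1.0 / di + (so2 * w[i] * w[i] / (di * di)) * q;
        cond_sd_obs[i] = sigma_obs * std::sqrt(vu);
      }
    }
    out["se_beta"] = se_beta;
    out["cond_sd_u"] = cond_sd_u;
    out["cond_sd_obs"] = cond_sd_obs;
    if (p > 0) out["vcov_beta"] = Sinv.submat(0, 0, p - 1, p - 1);
  }
  return out;
}
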