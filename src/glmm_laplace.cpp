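#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;



// Laplace-approximate ML for a binomial-logit mixed model with independent
// (diagonal) random-effect blocks: crossed random intercepts and optional
// uncorrelated random slopes.
//
// Spherical parameterization (as in lme4): u_k = sigma_k * b_k with
// b ~ N(0, I).  The joint mode of (b, beta) is found by penalized IRLS;
// the Laplace deviance profiled over (b, beta) is
//   dev(sigma) = -2*loglik(y | eta_hat) + b_hat' b_hat + log det(U'WU + I)
// with U the sigma-scaled random-effects design.  sigma is optimized by
// Nelder-Mead on |sigma| (reflection makes the non-negativity constraint
// free; the optimum may sit exactly at a boundary, i.e. a singular fit).
//
// Column layout in the joint system: [b (q), beta (p)], so the leading
// q x q block of the Cholesky factor is chol(U'WU + I) and the trailing
// p x p block yields the fixed-effects covariance directly.

struct GlmmProblem {
  arma::vec y;       // binary response
  arma::mat X;       // n x p fixed design
  arma::mat Xt;      // p x n transpose (contiguous row access)
  arma::umat G;      // n x K 0-based group index per random term
  arma::mat Xr;      // n x K random covariate value (1 for intercepts)
  arma::uvec qk;     // number of levels per term
  arma::uvec off;    // offset of each term's block within b
  arma::uword n, p, K, q;
};

struct PirlsState {
  arma::vec beta;
  arma::vec b;
  double dev;        // Laplace deviance at current sigma
  double ll;         // conditional log-likelihood at the joint mode
  bool ok;
  arma::mat L;       // Cholesky of the penalized joint crossprod
};

// Small-matrix Cholesky and penalized-LS solve.  LAPACK's per-call
// overhead dominates the arithmetic at the sizes seen here (tens of
// columns), so these are plain loops.  The factor is stored as the upper
// triangle U (A = U'U), keeping every inner sum a contiguous column scan
// in column-major storage; failure on a non-positive pivot.
static bool chol_small(const arma::mat &A, arma::mat &U, arma::uword m) {
  U.zeros(m, m);
  for (arma::uword j = 0; j < m; ++j) {
    const double *uj = U.colptr(j);
    double d = A(j, j);
    for (arma::uword k = 0; k < j; ++k) d -= uj[k] * uj[k];
    if (d <= 0.0 || !std::isfinite(d)) return false;
    const double Ujj = std::sqrt(d);
    U(j, j) = Ujj;
    for (arma::uword i = j + 1; i < m; ++i) {
      double *ui = U.colptr(i);
      double ssum = A(j, i);  // upper triangle of A
      for (arma::uword k = 0; k < j; ++k) ssum -= uj[k] * ui[k];
      ui[j] = ssum / Ujj;
    }
  }
  return true;
}

static void chol_solve_small(const arma::mat &U, const arma::vec &r,
                             arma::vec &x, arma::uword m) {
  // forward: U' y = r (column scans)
  arma::vec yv(m);
  for (arma::uword i = 0; i < m; ++i) {
    const double *ui = U.colptr(i);
    double s = r[i];
    for (arma::uword k = 0; k < i; ++k) s -= ui[k] * yv[k];
    yv[i] = s / ui[i];
  }
  // backward: U x = y (column sweeps)
  x = yv;
  for (arma::uword ii = m; ii > 0; --ii) {
    const arma::uword i = ii - 1;
    const double *ui = U.colptr(i);
    x[i] /= ui[i];
    const double xi = x[i];
    for (arma::uword k = 0; k < i; ++k) x[k] -= ui[k] * xi;
  }
}

// exp(x) by range reduction x = (n + f) ln2, f in [-0.5, 0.5], with a
// degree-6 polynomial for 2^f (relative error ~1e-11; the likelihood and
// working weights need far less).  Roughly 5x faster than libm here.
static inline double fast_exp(double x) {
  if (x < -708.0) return 0.0;
  if (x > 708.0) return std::numeric_limits<double>::infinity();
  const double inv_ln2 = 1.4426950408889634074;
  const double ln2_hi = 0.6931471805599453094;
  double t = x * inv_ln2;
  double n = std::nearbyint(t);
  double f = x - n * ln2_hi;
  // exp(f), |f| <= 0.3466: Taylor degree 7 (error < 4e-12)
  double p = 1.0 + f * (1.0 + f * (0.5 + f * (1.0 / 6.0 + f * (1.0 / 24.0 +
             f * (1.0 / 120.0 + f * (1.0 / 720.0 + f / 5040.0))))));
  return std::ldexp(p, (int)n);
}

static inline double binom_ll(const arma::vec &y, const arma::vec &eta) {
  // log-likelihood sum(y*eta - log(1 + exp(eta))), computed stably
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double e = eta[i];
    double lse = (e > 0) ? e + std::log1p(fast_exp(-e))
                         : std::log1p(fast_exp(e));
    ll += y[i] * e - lse;
  }
  return ll;
}

// log-likelihood and logistic means in one pass; mu feeds the next
// IRLS accumulation so the weights pass needs no further exp calls
static inline double binom_ll_mu(const arma::vec &y, const arma::vec &eta,
                                 arma::vec &mu) {
  double ll = 0.0;
  mu.set_size(eta.n_elem);
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    double ee = fast_exp(-std::fabs(e));
    double lse = (e > 0) ? e + std::log1p(ee) : std::log1p(ee);
    mu[i] = (e > 0) ? 1.0 / (1.0 + ee) : ee / (1.0 + ee);
    ll += y[i] * e - lse;
  }
  return ll;
}

// Penalized IRLS at fixed sigma, warm-started from st.beta / st.b.
// The active columns of each row (K random + p fixed) are constant within
// a call, so their indices and values are cached up front.
static void pirls(const GlmmProblem &P, const arma::vec &sigma, PirlsState &st,
                  int max_iter = 60, double tol = 3e-9) {
  const arma::uword m = P.q + P.p;
  const arma::uword na = P.K + P.p;
  arma::vec coef(m);
  coef.head(P.q) = st.b;
  coef.tail(P.p) = st.beta;

  arma::mat A(m, m);
  arma::vec r(m);

  // cache per-row active columns and design values
  arma::umat cols(na, P.n);
  arma::mat vals(na, P.n);
  for (arma::uword i = 0; i < P.n; ++i) {
    for (arma::uword k = 0; k < P.K; ++k) {
      cols(k, i) = P.off[k] + P.G(i, k);
      vals(k, i) = sigma[k] * P.Xr(i, k);
    }
    for (arma::uword j = 0; j < P.p; ++j) {
      cols(P.K + j, i) = P.q + j;
      vals(P.K + j, i) = P.X(i, j);
    }
  }
  auto eta_of = [&](const arma::vec &cf) {
    arma::vec eta(P.n);
    for (arma::uword i = 0; i < P.n; ++i) {
      double e = 0.0;
      for (arma::uword a = 0; a < na; ++a) e += vals(a, i) * cf[cols(a, i)];
      eta[i] = e;
    }
    return eta;
  };

  arma::vec eta = eta_of(coef);
  arma::vec mu_v, mu_c;
  double pdev_old = -2.0 * binom_ll_mu(P.y, eta, mu_v) +
                    arma::dot(coef.head(P.q), coef.head(P.q));
  st.ok = false;

  for (int it = 0; it < max_iter; ++it) {
    A.zeros();
    r.zeros();
    for (arma::uword i = 0; i < P.n; ++i) {
      double e = eta[i];
      double mu = mu_v[i];
      double w = mu * (1.0 - mu);
      if (w < 1e-10) w = 1e-10;
      double z = e + (P.y[i] - mu) / w;
      const arma::uword *ci = cols.colptr(i);
      const double *vi = vals.colptr(i);
      for (arma::uword a = 0; a < na; ++a) {
        const double wv = w * vi[a];
        r[ci[a]] += wv * z;
        for (arma::uword c = a; c < na; ++c) {
          if (ci[a] <= ci[c]) A(ci[a], ci[c]) += wv * vi[c];
          else A(ci[c], ci[a]) += wv * vi[c];
        }
      }
    }
    // unit penalty on the b block; A holds the upper triangle
    for (arma::uword j = 0; j < P.q; ++j) A(j, j) += 1.0;

    arma::mat L;
    if (!chol_small(A, L, m)) { st.ok = false; return; }
    arma::vec newcoef;
    chol_solve_small(L, r, newcoef, m);

    // step-halving on the penalized deviance; when even small steps fail
    // to improve we are at the mode to numerical precision: stop
    double step = 1.0;
    arma::vec cand, eta_c;
    double pdev_new = R_PosInf;
    bool improved = false;
    const double slack = 1e-9 * (std::fabs(pdev_old) + 1.0);
    for (int h = 0; h < 6; ++h) {
      cand = coef + step * (newcoef - coef);
      eta_c = eta_of(cand);
      pdev_new = -2.0 * binom_ll_mu(P.y, eta_c, mu_c) +
                 arma::dot(cand.head(P.q), cand.head(P.q));
      if (std::isfinite(pdev_new) && pdev_new <= pdev_old + slack) {
        improved = true;
        break;
      }
      step *= 0.5;
    }
    st.L = L;
    if (!improved) { st.ok = true; break; }
    coef = cand;
    eta = eta_c;
    mu_v = mu_c;
    double rel = std::fabs(pdev_old - pdev_new) / (std::fabs(pdev_new) + 1.0);
    pdev_old = pdev_new;
    if (rel < tol) { st.ok = true; break; }
    if (it == max_iter - 1) st.ok = true;  // flat likelihood: accept
  }

  st.b = coef.head(P.q);
  st.beta = coef.tail(P.p);
  st.ll = binom_ll(P.y, eta);
  // log det(U'WU + I) from the leading q x q block of L
  double ldet = 0.0;
  for (arma::uword j = 0; j < P.q; ++j) ldet += 2.0 * std::log(st.L(j, j));
  st.dev = -2.0 * st.ll + arma::dot(st.b, st.b) + ldet;
  if (!std::isfinite(st.dev)) st.ok = false;
}

// Specialized penalized IRLS for the dominant model family: exactly two
// crossed random-INTERCEPT terms plus a small fixed design.  The joint
// system is [[D1, C, E1],[C', D2, E2],[E1', E2', F]] with D1, D2
// diagonal, so eliminating the first factor leaves a dense system of only
// q2 + p columns.  Same deviance and mode as the general pirls().
static void pirls2(const GlmmProblem &P, const arma::vec &sigma,
                   PirlsState &st, int max_iter = 60, double tol = 3e-9) {
  // eliminate the larger factor so the dense remainder stays small
  const arma::uword t1 = (P.qk[0] >= P.qk[1]) ? 0 : 1;
  const arma::uword t2 = 1 - t1;
  const arma::uword q1 = P.qk[t1], q2 = P.qk[t2];
  const arma::uword p = P.p, n = P.n;
  const double s1 = sigma[t1], s2 = sigma[t2];
  const arma::uword ms = q2 + p;

  const arma::uword off1 = P.off[t1], off2 = P.off[t2];
  arma::vec b1 = st.b.subvec(off1, off1 + q1 - 1);
  arma::vec b2 = st.b.subvec(off2, off2 + q2 - 1);
  arma::vec beta = st.beta;

  arma::vec sw1(q1), r1(q1);
  arma::mat Ct(q2, q1), E1t(p, q1), E2(q2, p), F(p, p);
  arma::vec sw2(q2), r2(q2), rf(p);
  arma::mat M(ms, ms), cholM;
  arma::vec rhs(ms), sol(ms);
  arma::vec eta(n), mu_v, mu_c, eta_c(n), cand;

  auto eta_fill = [&](const arma::vec &bb1, const arma::vec &bb2,
                      const arma::vec &bt, arma::vec &out) {
    for (arma::uword i = 0; i < n; ++i) {
      double e = s1 * bb1[P.G(i, t1)] + s2 * bb2[P.G(i, t2)];
      const double *xi = P.Xt.colptr(i);
      for (arma::uword j = 0; j < p; ++j) e += xi[j] * bt[j];
      out[i] = e;
    }
  };

  eta_fill(b1, b2, beta, eta);
  double pdev_old = -2.0 * binom_ll_mu(P.y, eta, mu_v) +
                    arma::dot(b1, b1) + arma::dot(b2, b2);
  st.ok = false;
  double ldet_keep = 0.0;

  for (int it = 0; it < max_iter; ++it) {
    sw1.zeros(); sw2.zeros(); r1.zeros(); r2.zeros(); rf.zeros();
    Ct.zeros(); E1t.zeros(); E2.zeros(); F.zeros();
    for (arma::uword i = 0; i < n; ++i) {
      const double mu = mu_v[i];
      double w = mu * (1.0 - mu);
      if (w < 1e-10) w = 1e-10;
      const double z = eta[i] + (P.y[i] - mu) / w;
      const double wz = w * z;
      const arma::uword g1 = P.G(i, t1), g2 = P.G(i, t2);
      sw1[g1] += w; sw2[g2] += w;
      Ct(g2, g1) += w;
      r1[g1] += wz; r2[g2] += wz;
      double *e1c = E1t.colptr(g1);
      const double *xi = P.Xt.colptr(i);
      for (arma::uword j = 0; j < p; ++j) {
        const double xj = xi[j];
        e1c[j] += w * xj;
        E2(g2, j) += w * xj;
        rf[j] += wz * xj;
        for (arma::uword k = j; k < p; ++k) F(j, k) += w * xj * xi[k];
      }
    }
    // eliminate factor 1 (diagonal d1 = s1^2 sw1 + 1)
    arma::vec d1 = s1 * s1 * sw1 + 1.0;
    arma::vec inv_d1 = 1.0 / d1;
    // T = D1^{-1} [s1 s2 C, s1 E1], rhs1 = s1 r1
    // M = [[s2^2 diag(sw2) + I - (s1 s2 C)' D1^{-1} (s1 s2 C), ...]]
    M.zeros();
    const double s12 = s1 * s2;
    for (arma::uword g = 0; g < q2; ++g) M(g, g) = s2 * s2 * sw2[g] + 1.0;
    for (arma::uword j = 0; j < p; ++j) {
      for (arma::uword k = j; k < p; ++k) M(q2 + j, q2 + k) = F(j, k);
      for (arma::uword g = 0; g < q2; ++g) M(g, q2 + j) = s2 * E2(g, j);
    }
    rhs.zeros();
    for (arma::uword g = 0; g < q2; ++g) rhs[g] = s2 * r2[g];
    for (arma::uword j = 0; j < p; ++j) rhs[q2 + j] = rf[j];
    // subtract Schur contributions of factor 1
    arma::vec vrow(ms);
    for (arma::uword g1i = 0; g1i < q1; ++g1i) {
      const double w1 = inv_d1[g1i];
      const double *ctc = Ct.colptr(g1i);
      const double *e1c = E1t.colptr(g1i);
      for (arma::uword a = 0; a < q2; ++a) vrow[a] = s12 * ctc[a];
      for (arma::uword j = 0; j < p; ++j) vrow[q2 + j] = s1 * e1c[j];
      const double rr = s1 * r1[g1i];
      for (arma::uword a = 0; a < ms; ++a) {
        const double va = vrow[a];
        if (va == 0.0) continue;
        const double vaw = va * w1;
        rhs[a] -= vaw * rr;
        double *Mcol;
        for (arma::uword c = a; c < ms; ++c) {
          Mcol = M.colptr(c);
          Mcol[a] -= vaw * vrow[c];
        }
      }
    }
    if (!chol_small(M, cholM, ms)) { st.ok = false; return; }
    chol_solve_small(cholM, rhs, sol, ms);
    arma::vec nb2 = sol.head(q2);
    arma::vec nbeta = sol.tail(p);
    // back-substitute factor 1
    arma::vec nb1(q1);
    for (arma::uword g = 0; g < q1; ++g) {
      double acc = s1 * r1[g];
      const double *ctc = Ct.colptr(g);
      const double *e1c = E1t.colptr(g);
      for (arma::uword g2i = 0; g2i < q2; ++g2i)
        acc -= s12 * ctc[g2i] * nb2[g2i];
      for (arma::uword j = 0; j < p; ++j) acc -= s1 * e1c[j] * nbeta[j];
      nb1[g] = acc * inv_d1[g];
    }
    double ldet = 0.0;
    for (arma::uword g = 0; g < q1; ++g) ldet += std::log(d1[g]);
    for (arma::uword a = 0; a < q2; ++a) ldet += 2.0 * std::log(cholM(a, a));
    ldet_keep = ldet;

    // step-halving on the penalized deviance
    double step = 1.0;
    double pdev_new = R_PosInf;
    bool improved = false;
    const double slack = 1e-9 * (std::fabs(pdev_old) + 1.0);
    arma::vec cb1, cb2, cbeta;
    for (int h = 0; h < 6; ++h) {
      cb1 = b1 + step * (nb1 - b1);
      cb2 = b2 + step * (nb2 - b2);
      cbeta = beta + step * (nbeta - beta);
      eta_fill(cb1, cb2, cbeta, eta_c);
      pdev_new = -2.0 * binom_ll_mu(P.y, eta_c, mu_c) +
                 arma::dot(cb1, cb1) + arma::dot(cb2, cb2);
      if (std::isfinite(pdev_new) && pdev_new <= pdev_old + slack) {
        improved = true;
        break;
      }
      step *= 0.5;
    }
    if (!improved) { st.ok = true; break; }
    b1 = cb1; b2 = cb2; beta = cbeta;
    eta = eta_c; mu_v = mu_c;
    double rel = std::fabs(pdev_old - pdev_new) / (std::fabs(pdev_new) + 1.0);
    pdev_old = pdev_new;
    if (rel < tol) { st.ok = true; break; }
    if (it == max_iter - 1) st.ok = true;
  }

  st.b.set_size(P.q);
  st.b.subvec(off1, off1 + q1 - 1) = b1;
  st.b.subvec(off2, off2 + q2 - 1) = b2;
  st.beta = beta;
  st.ll = binom_ll(P.y, eta);
  st.dev = -2.0 * st.ll + arma::dot(b1, b1) + arma::dot(b2, b2) + ldet_keep;
  if (!std::isfinite(st.dev)) st.ok = false;
}

// Generic Nelder-Mead minimizer over an objective with per-coordinate
// initial steps.
static arma::vec nm_generic(const std::function<double(const arma::vec &)> &fwrap,
                            arma::vec start, int max_eval, double tol,
                            const arma::vec &step0, int &evals) {
  const arma::uword K = start.n_elem;
  if (K == 0) { fwrap(start); return start; }

  std::vector<arma::vec> v(K + 1);
  arma::vec fv(K + 1);
  for (arma::uword j = 0; j <= K; ++j) {
    v[j] = start;
    if (j > 0) v[j][j - 1] += step0[j - 1];
    fv[j] = fwrap(v[j]);
  }

  const double alpha = 1.0, gamma = 2.0, rho = 0.5, srho = 0.5;
  while (evals < max_eval) {
    arma::uvec ord = arma::sort_index(fv);
    std::vector<arma::vec> vs(K + 1);
    arma::vec fs(K + 1);
    for (arma::uword j = 0; j <= K; ++j) { vs[j] = v[ord[j]]; fs[j] = fv[ord[j]]; }
    v = vs; fv = fs;

    double spread = std::fabs(fv[K] - fv[0]);
    double size = 0.0;
    for (arma::uword j = 1; j <= K; ++j)
      size = std::max(size, arma::norm(v[j] - v[0], "inf"));
    if (spread < tol * (1.0 + std::fabs(fv[0])) || size < 5e-4) break;

    arma::vec cen = arma::zeros<arma::vec>(K);
    for (arma::uword j = 0; j < K; ++j) cen += v[j];
    cen /= double(K);

    arma::vec xr = cen + alpha * (cen - v[K]);
    double fr = fwrap(xr);
    if (fr < fv[0]) {
      arma::vec xe = cen + gamma * (cen - v[K]);
      double fe = fwrap(xe);
      if (fe < fr) { v[K] = xe; fv[K] = fe; } else { v[K] = xr; fv[K] = fr; }
    } else if (fr < fv[K - 1]) {
      v[K] = xr; fv[K] = fr;
    } else {
      arma::vec xc = cen + rho * (v[K] - cen);
      double fc = fwrap(xc);
      if (fc < fv[K]) { v[K] = xc; fv[K] = fc; }
      else {
        for (arma::uword j = 1; j <= K; ++j) {
          v[j] = v[0] + srho * (v[j] - v[0]);
          fv[j] = fwrap(v[j]);
        }
      }
    }
  }
  arma::uvec ord = arma::sort_index(fv);
  return v[ord[0]];
}

// NM over sigma (reflected to |sigma|) around the profiled-PIRLS deviance.
static arma::vec nelder_mead(const GlmmProblem &P, PirlsState &st,
                             arma::vec start, int max_eval, double tol,
                             double step, int &evals) {
  auto fwrap = [&](const arma::vec &s) {
    // searching only: a loose inner solve is enough for the outer
    // optimizer; the caller runs one tight solve at the optimum
    pirls(P, arma::abs(s), st, 40, 1e-6);
    ++evals;
    return st.ok ? st.dev : R_PosInf;
  };
  arma::vec step0(start.n_elem);
  for (arma::uword j = 0; j < start.n_elem; ++j)
    step0[j] = std::max(step * start[j], 0.5 * step);
  return arma::abs(nm_generic(fwrap, start, max_eval, tol, step0, evals));
}

// PIRLS over the random effects only, with the fixed part held as an
// offset: the inner step of a full (non-profiled) Laplace fit.
static void pirls_u(const GlmmProblem &P, const arma::vec &sigma,
                    const arma::vec &beta, PirlsState &st,
                    int max_iter = 40, double tol = 1e-10) {
  arma::vec b = st.b;
  arma::vec eta0 = P.X * beta;
  arma::mat A(P.q, P.q);
  arma::vec r(P.q);

  auto eta_of = [&](const arma::vec &bb) {
    arma::vec eta = eta0;
    for (arma::uword k = 0; k < P.K; ++k) {
      const double sk = sigma[k];
      if (sk == 0.0) continue;
      for (arma::uword i = 0; i < P.n; ++i)
        eta[i] += sk * P.Xr(i, k) * bb[P.off[k] + P.G(i, k)];
    }
    return eta;
  };

  arma::vec eta = eta_of(b);
  arma::vec mu_v, mu_c;
  double pdev_old = -2.0 * binom_ll_mu(P.y, eta, mu_v) + arma::dot(b, b);
  st.ok = false;
  arma::mat L;
  for (int it = 0; it < max_iter; ++it) {
    A.zeros();
    r.zeros();
    for (arma::uword i = 0; i < P.n; ++i) {
      double e = eta[i];
      double mu = mu_v[i];
      double w = mu * (1.0 - mu);
      if (w < 1e-10) w = 1e-10;
      double z = (e - eta0[i]) + (P.y[i] - mu) / w;  // working resid, u part
      for (arma::uword k = 0; k < P.K; ++k) {
        const double vk = sigma[k] * P.Xr(i, k);
        const arma::uword ck = P.off[k] + P.G(i, k);
        const double wv = w * vk;
        r[ck] += wv * z;
        for (arma::uword k2 = k; k2 < P.K; ++k2) {
          const arma::uword c2 = P.off[k2] + P.G(i, k2);
          const double v2 = sigma[k2] * P.Xr(i, k2);
          if (ck <= c2) A(ck, c2) += wv * v2; else A(c2, ck) += wv * v2;
        }
      }
    }
    for (arma::uword j = 0; j < P.q; ++j) A(j, j) += 1.0;
    if (!chol_small(A, L, P.q)) { st.ok = false; return; }
    arma::vec bn;
    chol_solve_small(L, r, bn, P.q);
    double step = 1.0;
    arma::vec cand, eta_c;
    double pdev_new = R_PosInf;
    bool improved = false;
    const double slack = 1e-9 * (std::fabs(pdev_old) + 1.0);
    for (int h = 0; h < 6; ++h) {
      cand = b + step * (bn - b);
      eta_c = eta_of(cand);
      pdev_new = -2.0 * binom_ll_mu(P.y, eta_c, mu_c) + arma::dot(cand, cand);
      if (std::isfinite(pdev_new) && pdev_new <= pdev_old + slack) {
        improved = true;
        break;
      }
      step *= 0.5;
    }
    if (!improved) { st.ok = true; break; }
    b = cand;
    eta = eta_c;
    mu_v = mu_c;
    double rel = std::fabs(pdev_old - pdev_new) / (std::fabs(pdev_new) + 1.0);
    pdev_old = pdev_new;
    if (rel < tol) { st.ok = true; break; }
    if (it == max_iter - 1) st.ok = true;
  }
  st.b = b;
  st.beta = beta;
  st.ll = binom_ll(P.y, eta);
  double ldet = 0.0;
  for (arma::uword j = 0; j < P.q; ++j) ldet += 2.0 * std::log(L(j, j));
  st.dev = -2.0 * st.ll + arma::dot(b, b) + ldet;
  if (!std::isfinite(st.dev)) st.ok = false;
}

// Joint penalized Hessian at a solution, for fixed-effect standard errors.
static bool joint_se(const GlmmProblem &P, const arma::vec &sigma,
                     const arma::vec &beta, const arma::vec &b,
                     arma::vec &se) {
  const arma::uword m = P.q + P.p;
  arma::mat A(m, m, arma::fill::zeros);
  arma::vec eta = P.X * beta;
  for (arma::uword k = 0; k < P.K; ++k) {
    const double sk = sigma[k];
    if (sk == 0.0) continue;
    for (arma::uword i = 0; i < P.n; ++i)
      eta[i] += sk * P.Xr(i, k) * b[P.off[k] + P.G(i, k)];
  }
  arma::uvec cols(P.K + P.p);
  arma::vec vals(P.K + P.p);
  for (arma::uword i = 0; i < P.n; ++i) {
    double mu = 1.0 / (1.0 + std::exp(-eta[i]));
    double w = mu * (1.0 - mu);
    if (w < 1e-10) w = 1e-10;
    arma::uword nact = 0;
    for (arma::uword k = 0; k < P.K; ++k) {
      cols[nact] = P.off[k] + P.G(i, k);
      vals[nact] = sigma[k] * P.Xr(i, k);
      ++nact;
    }
    for (arma::uword j = 0; j < P.p; ++j) {
      cols[nact] = P.q + j;
      vals[nact] = P.X(i, j);
      ++nact;
    }
    for (arma::uword a = 0; a < nact; ++a) {
      const double wv = w * vals[a];
      for (arma::uword c = a; c < nact; ++c) {
        if (cols[a] <= cols[c]) A(cols[a], cols[c]) += wv * vals[c];
        else A(cols[c], cols[a]) += wv * vals[c];
      }
    }
  }
  A = arma::symmatu(A);
  for (arma::uword j = 0; j < P.q; ++j) A(j, j) += 1.0;
  arma::mat L;
  if (!arma::chol(L, A, "lower")) return false;
  arma::mat Lbb = L.submat(P.q, P.q, m - 1, m - 1);
  arma::mat Vi = Lbb * Lbb.t();
  arma::mat V;
  if (!arma::inv_sympd(V, Vi)) return false;
  se = arma::sqrt(V.diag());
  return se.is_finite();
}

// [[Rcpp::export]]
List glmm_fit_cpp(const arma::vec &y, const arma::mat &X,
                  const IntegerMatrix &G, const arma::mat &Xr,
                  const IntegerVector &qk, const arma::vec &sigma_init,
                  bool fix_sigma = false, int max_eval = 250,
                  double tol = 2e-6, double step = 0.3,
                  double final_tol = 1e-12) {
  GlmmProblem P;
  P.y = y;
  P.X = X;
  P.Xt = X.t();
  P.n = X.n_rows;
  P.p = X.n_cols;
  P.K = qk.size();
  P.G.set_size(P.n, P.K);
  for (arma::uword k = 0; k < P.K; ++k)
    for (arma::uword i = 0; i < P.n; ++i)
      P.G(i, k) = (arma::uword)G(i, k);
  P.Xr = Xr;
  P.qk.set_size(P.K);
  P.off.set_size(P.K);
  arma::uword q = 0;
  for (arma::uword k = 0; k < P.K; ++k) {
    P.qk[k] = (arma::uword)qk[k];
    P.off[k] = q;
    q += P.qk[k];
  }
  P.q = q;

  PirlsState st;
  st.beta = arma::zeros<arma::vec>(P.p);
  st.b = arma::zeros<arma::vec>(P.q);
  st.dev = R_PosInf;

  // two crossed intercepts (the per-bin cluster models) take the
  // block-sparse solver; anything else the general one
  const bool two_int = (P.K == 2) && P.Xr.min() == 1.0 && P.Xr.max() == 1.0;
  auto solve_at = [&](const arma::vec &sg, int mi, double tl) {
    if (two_int) pirls2(P, sg, st, mi, tl);
    else pirls(P, sg, st, mi, tl);
  };

  int evals = 0;
  arma::vec sigma = sigma_init;
  if (fix_sigma || P.K == 0) {
    solve_at(arma::abs(sigma), 60, 3e-9);
    ++evals;
    sigma = arma::abs(sigma);
  } else {
    auto fwrap = [&](const arma::vec &sg) {
      // searching only: a loose inner solve is enough for the outer
      // optimizer; a tight solve follows at the optimum
      solve_at(arma::abs(sg), 40, 1e-6);
      ++evals;
      return st.ok ? st.dev : R_PosInf;
    };
    arma::vec step0(P.K);
    for (arma::uword k = 0; k < P.K; ++k)
      step0[k] = std::max(step * sigma_init[k], 0.5 * step);
    sigma = arma::abs(nm_generic(fwrap, sigma_init, max_eval, tol, step0,
                                 evals));
    solve_at(sigma, 100, final_tol);  // tight final solve at the optimum
  }

  // fixed-effect covariance from the joint penalized Hessian at the mode
  arma::vec se(P.p, arma::fill::value(NA_REAL));
  bool se_ok = st.ok && joint_se(P, sigma, st.beta, st.b, se);

  // back-transform spherical coefficients to random effects u = sigma * b
  List u(P.K);
  for (arma::uword k = 0; k < P.K; ++k) {
    arma::vec uk = sigma[k] * st.b.subvec(P.off[k], P.off[k] + P.qk[k] - 1);
    u[k] = uk;
  }

  bool separation = arma::abs(st.beta).max() > 12.0;
  bool converged = st.ok && se_ok && !separation;

  return List::create(
      _["beta"] = st.beta, _["se"] = se, _["sigma"] = sigma,
      _["deviance"] = st.dev, _["loglik"] = st.ll, _["u"] = u,
      _["converged"] = converged, _["separation"] = separation,
      _["n_eval"] = evals);
}

// Full Laplace ML: the outer optimisation runs over (sigma, beta) jointly
// (the inner PIRLS solves only for the random-effect modes), matching the
// estimation target of lme4's default glmer.  Slower than the profiled
// variant; used where Wald-z calibration matters more than raw speed.
// [[Rcpp::export]]
List glmm_fit_full_cpp(const arma::vec &y, const arma::mat &X,
                       const IntegerMatrix &G, const arma::mat &Xr,
                       const IntegerVector &qk, const arma::vec &sigma_init,
                       int max_eval = 500, double tol = 1e-7) {
  GlmmProblem P;
  P.y = y;
  P.X = X;
  P.Xt = X.t();
  P.n = X.n_rows;
  P.p = X.n_cols;
  P.K = qk.size();
  P.G.set_size(P.n, P.K);
  for (arma::uword k = 0; k < P.K; ++k)
    for (arma::uword i = 0; i < P.n; ++i)
      P.G(i, k) = (arma::uword)G(i, k);
  P.Xr = Xr;
  P.qk.set_size(P.K);
  P.off.set_size(P.K);
  arma::uword q = 0;
  for (arma::uword k = 0; k < P.K; ++k) {
    P.qk[k] = (arma::uword)qk[k];
    P.off[k] = q;
    q += P.qk[k];
  }
  P.q = q;

  // stage 1: profiled fit for a good starting point
  PirlsState st;
  st.beta = arma::zeros<arma::vec>(P.p);
  st.b = arma::zeros<arma::vec>(P.q);
  int evals = 0;
  arma::vec sigma0 = nelder_mead(P, st, sigma_init, 150, 1e-5, 0.3, evals);
  pirls(P, sigma0, st);
  arma::vec beta0 = st.beta;

  // stage 2: joint NM over (sigma, beta) around the profiled solution
  PirlsState stu;
  stu.b = st.b;
  stu.beta = beta0;
  auto fwrap = [&](const arma::vec &par) {
    arma::vec sg = arma::abs(par.head(P.K));
    arma::vec bt = par.tail(P.p);
    pirls_u(P, sg, bt, stu, 40, 1e-6);
    ++evals;
    return stu.ok ? stu.dev : R_PosInf;
  };
  arma::vec start(P.K + P.p);
  start.head(P.K) = sigma0;
  start.tail(P.p) = beta0;
  arma::vec step0(P.K + P.p);
  for (arma::uword k = 0; k < P.K; ++k)
    step0[k] = std::max(0.15 * sigma0[k], 0.08);
  for (arma::uword j = 0; j < P.p; ++j) step0[P.K + j] = 0.1;
  arma::vec opt = nm_generic(fwrap, start, max_eval, tol, step0, evals);
  arma::vec sigma = arma::abs(opt.head(P.K));
  arma::vec beta = opt.tail(P.p);
  pirls_u(P, sigma, beta, stu, 80, 1e-12);

  arma::vec se(P.p, arma::fill::value(NA_REAL));
  bool se_ok = joint_se(P, sigma, beta, stu.b, se);

  List u(P.K);
  for (arma::uword k = 0; k < P.K; ++k)
    u[k] = arma::vec(sigma[k] * stu.b.subvec(P.off[k], P.off[k] + P.qk[k] - 1));

  bool separation = arma::abs(beta).max() > 12.0;
  bool converged = stu.ok && se_ok && !separation;
  return List::create(
      _["beta"] = beta, _["se"] = se, _["sigma"] = sigma,
      _["deviance"] = stu.dev, _["loglik"] = stu.ll, _["u"] = u,
      _["converged"] = converged, _["separation"] = separation,
      _["n_eval"] = evals);
}
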