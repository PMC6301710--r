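// Instantaneous flux optimization for the reduced metabolic network.
//
// The per-instant problem is
//     maximize   Z(v) = mu(v) / ( w * sum_j v_j^2 + (1-w) * (a'v)^2 )
//     subject to S v = 0,  lb <= v <= ub,
// with mu(v) = v[biomass] and a >= 0 the ATP-production coefficient vector.
// The numerator is linear and the denominator is a positive definite
// quadratic (w > 0), so Dinkelbach's parametric scheme applies: each
// subproblem  max  mu(v) - lambda * v'Qv  is a strictly convex QP over the
// flux polytope and the iteration converges to the global optimum of the
// ratio.
//
// The QPs are solved exactly by a primal active-set method (the problems
// are small and dense); a first feasible point, when no warm start is
// available, comes from an ADMM splitting on the minimum-norm problem.

#include <RcppArmadillo.h>
using namespace arma;

namespace {

// elementwise clamp with vector bounds
vec clampv(const vec& x, const vec& lo, const vec& hi) {
  return arma::min(arma::max(x, lo), hi);
}

// ---------------------------------------------------------------------------
// ADMM phase-1: minimize 0.5||x||^2 s.t. S x = 0, lb <= x <= ub
vec admm_feasible(const mat& S, const vec& lb, const vec& ub, const vec& x0,
                  double tol, int maxit, double* out_res) {
  const uword n = S.n_cols, m = S.n_rows;
  const double alpha = 1.6;
  double rho = 1.0;
  mat StS = S.t() * S;
  mat L = chol(eye(n, n) + rho * (StS + eye(n, n)), "lower");

  vec x = clampv(x0, lb, ub);
  vec z1(m, fill::zeros), z2 = x, u1(m, fill::zeros), u2(n, fill::zeros);
  double best_pri = datum::inf;
  int best_it = 0;
  for (int it = 0; it < maxit; ++it) {
    vec rhs = rho * (S.t() * (z1 - u1) + (z2 - u2));
    x = solve(trimatu(L.t()), solve(trimatl(L), rhs));
    vec Sx = S * x;
    vec ax1 = alpha * Sx;
    vec ax2 = alpha * x + (1.0 - alpha) * z2;
    vec z2_old = z2;
    z1.zeros();
    z2 = clampv(ax2 + u2, lb, ub);
    u1 += ax1 - z1;
    u2 += ax2 - z2;
    if (it % 25 == 24) {
      double pri = std::max(norm(Sx, "inf"), norm(x - z2, "inf"));
      double dua = rho * norm(z2 - z2_old, "inf");
      if (pri < tol && dua < tol) break;
      // stall exit: an infeasible problem never reduces the residual
      if (pri < 0.9 * best_pri) { best_pri = pri; best_it = it; }
      if (it - best_it > 700) break;
      if (pri > 10 * dua && rho < 1e6) {
        rho *= 2; u1 /= 2; u2 /= 2;
        L = chol(eye(n, n) + rho * (StS + eye(n, n)), "lower");
      } else if (dua > 10 * pri && rho > 1e-6) {
        rho /= 2; u1 *= 2; u2 *= 2;
        L = chol(eye(n, n) + rho * (StS + eye(n, n)), "lower");
      }
    }
  }
  *out_res = norm(S * x, "inf");
  return clampv(x, lb, ub);
}

// project x onto {S x = 0} along the minimum-norm correction, then repair
// box violations by a few alternating passes (cheap feasibility cleanup)
vec project_eq(const mat& S, const vec& x) {
  mat SSt = S * S.t();
  vec corr = S.t() * solve(SSt + 1e-12 * eye(S.n_rows, S.n_rows), S * x);
  return x - corr;
}

// alternating projections between {S x = 0} and the box: from a
// near-feasible seed this restores feasibility in a few iterations at a
// fraction of the cost of the ADMM splitting
bool pocs_feasible(const mat& S, const vec& lb, const vec& ub, vec& x,
                   int maxit = 60) {
  mat SSt = S * S.t();
  mat F = chol(SSt + 1e-12 * eye(S.n_rows, S.n_rows), "lower");
  double prev = datum::inf;
  for (int it = 0; it < maxit; ++it) {
    vec corr = S.t() * solve(trimatu(F.t()), solve(trimatl(F), S * x));
    x -= corr;
    double box_viol = std::max(arma::max(lb - x), arma::max(x - ub));
    if (box_viol <= 1e-12) return true;   // on the subspace and in the box
    x = clampv(x, lb, ub);
    double res = norm(S * x, "inf");
    if (res < 1e-10) return true;
    if (res > 0.97 * prev) return false;  // stalled: genuine work needed
    prev = res;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Primal active-set method for
//   minimize 0.5 x' H x - c' x   s.t.  S x = 0, lb <= x <= ub
// with H symmetric positive definite and x0 feasible.
// Variables with lb == ub are pinned and never released.
struct AsResult {
  vec x;
  int iters;
  bool converged;
};

AsResult qp_active_set(const mat& H, const vec& c, const mat& S,
                       const vec& lb, const vec& ub, vec x, int maxit = 300) {
  const uword n = H.n_cols, m = S.n_rows;
  const double tol = 1e-10, steptol = 1e-12;

  // working set: 0 free, -1 at lower, +1 at upper; 2 pinned (lb == ub)
  ivec W(n, fill::zeros);
  for (uword j = 0; j < n; ++j) {
    if (ub(j) - lb(j) < 1e-12) { W(j) = 2; x(j) = lb(j); }
    else if (x(j) - lb(j) < 1e-9) { W(j) = -1; x(j) = lb(j); }
    else if (ub(j) - x(j) < 1e-9) { W(j) = +1; x(j) = ub(j); }
  }

  int it = 0;
  for (it = 0; it < maxit; ++it) {
    // solve EQP on the current working set for the full step target x*
    uvec fixed = find(W != 0);
    uword na = fixed.n_elem;
    mat A(m + na, n, fill::zeros);
    vec b(m + na, fill::zeros);
    A.rows(0, m - 1) = S;
    for (uword k = 0; k < na; ++k) {
      A(m + k, fixed(k)) = 1.0;
      b(m + k) = (W(fixed(k)) == -1 || W(fixed(k)) == 2) ? lb(fixed(k))
                                                         : ub(fixed(k));
    }
    mat K(n + m + na, n + m + na, fill::zeros);
    K.submat(0, 0, n - 1, n - 1) = H;
    K.submat(0, n, n - 1, n + m + na - 1) = A.t();
    K.submat(n, 0, n + m + na - 1, n - 1) = A;
    // tiny dual regularization keeps K invertible under redundant rows
    for (uword k = n; k < n + m + na; ++k) K(k, k) = -1e-12;
    vec rhs = join_cols(c, b);
    vec sol;
    if (!solve(sol, K, rhs)) break;
    vec xs = sol.head(n);
    vec p = xs - x;

    if (norm(p, "inf") < tol * std::max(1.0, norm(x, "inf"))) {
      if (na == 0) {  // unconstrained stationary point: optimal
        AsResult r; r.x = x; r.iters = it + 1; r.converged = true; return r;
      }
      // KKT sign convention here: Hx - c = -A'y, so a lower-active bound is
      // optimal iff y_j <= 0 and an upper-active bound iff y_j >= 0
      vec y_bnd = sol.subvec(n + m, n + m + na - 1);
      double worst = 1e-9;  // release tolerance
      uword worst_j = n;
      for (uword k = 0; k < na; ++k) {
        uword j = fixed(k);
        if (W(j) == 2) continue;  // pinned equality, never released
        double viol = (W(j) == -1) ? y_bnd(k) : -y_bnd(k);
        if (viol > worst) { worst = viol; worst_j = j; }
      }
      if (worst_j == n) {  // all multipliers have the right sign: optimal
        AsResult r; r.x = x; r.iters = it + 1; r.converged = true; return r;
      }
      W(worst_j) = 0;  // release the worst violated multiplier
      continue;
    }

    // step length to the nearest blocking bound among free variables
    double amax = 1.0;
    uword blk = n; int blk_side = 0;
    for (uword j = 0; j < n; ++j) {
      if (W(j) != 0) continue;
      if (p(j) > steptol) {
        double a = (ub(j) - x(j)) / p(j);
        if (a < amax - 1e-14) { amax = a; blk = j; blk_side = +1; }
      } else if (p(j) < -steptol) {
        double a = (lb(j) - x(j)) / p(j);
        if (a < amax - 1e-14) { amax = a; blk = j; blk_side = -1; }
      }
    }
    x += std::max(amax, 0.0) * p;
    if (blk < n) {
      W(blk) = blk_side;
      x(blk) = (blk_side == -1) ? lb(blk) : ub(blk);
    }
  }
  AsResult r; r.x = x; r.iters = it; r.converged = false; return r;
}

double denom_val(const vec& x, double w, const vec& a) {
  double s = dot(x, x);
  double t = dot(a, x);
  return w * s + (1.0 - w) * t * t;
}

} // namespace

// [[Rcpp::export(name = ".flux_opt_cpp")]]
Rcpp::List flux_opt_cpp(const arma::mat& S, const arma::vec& lb,
                        const arma::vec& ub, int bio_idx, double w,
                        const arma::vec& a,
                        Rcpp::Nullable<Rcpp::NumericVector> warm,
                        double tol = 1e-8, int maxit_admm = 20000) {
  const uword n = S.n_cols;
  const uword bio = (uword)(bio_idx - 1);  // 1-based index from R
  vec c_mu(n, fill::zeros);
  c_mu(bio) = 1.0;
  mat Qden = 2.0 * (w * eye(n, n) + (1.0 - w) * (a * a.t()));

  // obtain a feasible starting point; a near-feasible warm start is used
  // directly when it satisfies the constraints, and otherwise still seeds
  // the phase-1 splitting
  vec xf;
  vec x_seed(n, fill::zeros);
  bool have_warm = false;
  if (warm.isNotNull()) {
    Rcpp::NumericVector wv(warm);
    if ((uword)wv.size() == n) {
      vec x0 = vec(wv.begin(), n);
      x_seed = clampv(x0, lb, ub);
      if (norm(S * x0, "inf") < 1e-7 && all(x0 >= lb - 1e-9) &&
          all(x0 <= ub + 1e-9)) {
        xf = clampv(x0, lb, ub);
        xf = project_eq(S, xf);
        have_warm = norm(S * xf, "inf") < 1e-8 &&
                    all(xf >= lb - 1e-7) && all(xf <= ub + 1e-7);
        if (have_warm) xf = clampv(xf, lb, ub);
      }
    }
  }
  int total_it = 0;
  if (!have_warm && warm.isNotNull()) {
    // cheap feasibility restoration from the invalid warm start
    vec xp = x_seed;
    if (pocs_feasible(S, lb, ub, xp)) {
      xf = clampv(xp, lb, ub);
      have_warm = norm(S * xf, "inf") < 1e-8;
    }
  }
  if (!have_warm) {
    double res;
    xf = admm_feasible(S, lb, ub, x_seed, 1e-9, maxit_admm, &res);
    xf = project_eq(S, xf);
    if (norm(S * xf, "inf") > 1e-7 || any(xf < lb - 1e-7) ||
        any(xf > ub + 1e-7)) {
      return Rcpp::List::create(Rcpp::Named("status") = "infeasible",
                                Rcpp::Named("fluxes") = xf,
                                Rcpp::Named("mu") = NA_REAL,
                                Rcpp::Named("Z") = NA_REAL,
                                Rcpp::Named("iters") = 0);
    }
    xf = clampv(xf, lb, ub);
  }

  // growth capability: max mu - eps ||v||^2.  Skipped under a warm start
  // with positive growth (the Dinkelbach loop detects vanishing growth on
  // its own through the mu < tol exit).
  vec xk;
  double lambda;
  if (have_warm && xf(bio) > 1e-9) {
    xk = xf;
    lambda = std::max(xf(bio) / denom_val(xf, w, a), 1e-12);
  } else {
    AsResult g = qp_active_set(2e-4 * eye(n, n), c_mu, S, lb, ub, xf);
    total_it += g.iters;
    double mu_max = g.x(bio);
    if (mu_max < 1e-9) {
      // Z defined as 0; minimum-norm feasible flux state
      AsResult mn = qp_active_set(eye(n, n), zeros<vec>(n), S, lb, ub, xf);
      return Rcpp::List::create(Rcpp::Named("status") = "zero_growth",
                                Rcpp::Named("fluxes") = mn.x,
                                Rcpp::Named("mu") = 0.0,
                                Rcpp::Named("Z") = 0.0,
                                Rcpp::Named("iters") = total_it + mn.iters);
    }
    xk = g.x;
    lambda = std::max(mu_max / denom_val(xk, w, a), 1e-12);
  }
  int dk = 0;
  bool converged = false;
  for (dk = 0; dk < 60; ++dk) {
    AsResult sub = qp_active_set(Qden, c_mu / lambda, S, lb, ub, xk);
    total_it += sub.iters;
    double mu = sub.x(bio);
    double den = denom_val(sub.x, w, a);
    xk = sub.x;
    if (den < 1e-14 || mu < 1e-12) { lambda = 0.0; converged = true; break; }
    double lam_new = mu / den;
    if (std::fabs(lam_new - lambda) < tol * std::max(1e-10, lambda)) {
      lambda = lam_new; converged = true; break;
    }
    lambda = lam_new;
  }

  return Rcpp::List::create(
      Rcpp::Named("status") = converged ? "optimal" : "maxit",
      Rcpp::Named("fluxes") = xk,
      Rcpp::Named("mu") = xk(bio),
      Rcpp::Named("Z") = lambda,
      Rcpp::Named("iters") = total_it);
}

// Convex QP solver used by tests and internal helpers:
// minimize 0.5 x' H x - c' x  s.t.  S x = 0, lb <= x <= ub.
// [[Rcpp::export(name = ".qp_solve_cpp")]]
Rcpp::List qp_solve_cpp(const arma::mat& H, const arma::vec& c,
                        const arma::mat& S, const arma::vec& lb,
                        const arma::vec& ub, double tol = 1e-9,
                        int maxit = 50000,
                        Rcpp::Nullable<Rcpp::NumericVector> warm = R_NilValue) {
  const uword n = H.n_cols;
  vec xf;
  bool seeded = false;
  if (warm.isNotNull()) {
    Rcpp::NumericVector wv(warm);
    if ((uword)wv.size() == n) {
      vec x0 = clampv(vec(wv.begin(), n), lb, ub);
      if (pocs_feasible(S, lb, ub, x0) || norm(S * x0, "inf") < 1e-8) {
        xf = clampv(x0, lb, ub);
        seeded = norm(S * xf, "inf") < 1e-7;
      }
    }
  }
  if (!seeded) {
    double res;
    xf = admm_feasible(S, lb, ub, zeros<vec>(n), 1e-9, maxit, &res);
    xf = clampv(project_eq(S, xf), lb, ub);
  }
  AsResult r = qp_active_set(H, c, S, lb, ub, xf, 600);
  return Rcpp::List::create(
      Rcpp::Named("x") = r.x,
      Rcpp::Named("iters") = r.iters,
      Rcpp::Named("residual") = norm(S * r.x, "inf"),
      Rcpp::Named("converged") = r.converged);
}
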