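// Linear quantile regression by an MM (iteratively reweighted least squares)
// scheme with a shrinking smoothing parameter, finished by exact
// coordinate-wise minimization of the pinball loss (each coordinate step is
// a weighted quantile, solved by a breakpoint scan). For the small design
// matrices used here (<= 4 columns) this attains the linear-programming
// optimum to numerical precision and is fast enough for dense bootstrap
// loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double pinball(const vec& r, double tau) {
  double s = 0.0;
  for (uword i = 0; i < r.n_elem; ++i) {
    s += r[i] * (tau - (r[i] < 0 ? 1.0 : 0.0));
  }
  return s;
}

// Exact minimizer over delta of sum_i rho_tau(r_i - x_i * delta):
// piecewise-linear convex; scan breakpoints z_i = r_i / x_i ordered by z.
// Crossing a breakpoint increases the right-derivative by |x_i|.
static double coord_step(const vec& r, const vec& x, double tau) {
  std::vector<std::pair<double, double>> z;  // (breakpoint, |x|)
  double g = 0.0;                            // derivative left of all z
  for (uword i = 0; i < r.n_elem; ++i) {
    double xi = x[i];
    if (std::abs(xi) < 1e-12) continue;
    z.emplace_back(r[i] / xi, std::abs(xi));
    if (xi > 0) g -= tau * xi;
    else g += (tau - 1.0) * (-xi);
  }
  if (z.empty()) return 0.0;
  std::sort(z.begin(), z.end());
  for (size_t k = 0; k < z.size(); ++k) {
    g += z[k].second;
    if (g >= 0) return z[k].first;
  }
  return z.back().first;
}

// [[Rcpp::export(name = ".qr_fit_cpp")]]
Rcpp::List qr_fit_cpp(const arma::mat& X, const arma::vec& y, double tau,
                      int mm_iter = 90, int cd_cycles = 60) {
  const uword n = X.n_rows, p = X.n_cols;
  vec beta(p, fill::zeros);

  // ridge-stabilized least-squares start
  mat XtX = X.t() * X;
  XtX.diag() += 1e-8 * (trace(XtX) / p + 1.0);
  beta = solve(XtX, X.t() * y, solve_opts::fast);

  // MM iterations: rho_tau(r) = |r|/2 + (tau - 1/2) r; majorize |r| by
  // r^2 / (2 (eps + |r_old|)) and solve the weighted normal equations
  //   (X' W X) beta = X' W y + (tau - 1/2)/2 * X' 1,  W = diag(w)/2.
  double scale = stddev(y);
  if (!std::isfinite(scale) || scale <= 0) scale = 1.0;
  double eps = 1e-2 * scale;
  vec r = y - X * beta;
  const vec xsum = sum(X, 0).t();
  for (int it = 0; it < mm_iter; ++it) {
    vec w = 1.0 / (2.0 * (eps + abs(r)));
    mat Xw = X.each_col() % w;              // W X, no dense diagonal
    mat A = X.t() * Xw;
    A.diag() += 1e-12 * (trace(A) / p + 1.0);
    vec b = Xw.t() * y + (tau - 0.5) / 2.0 * xsum;
    vec beta_new;
    bool ok = solve(beta_new, A, b, solve_opts::fast);
    if (!ok) break;
    double step = norm(beta_new - beta, 2);
    beta = beta_new;
    r = y - X * beta;
    if (step < 1e-10 * (1.0 + norm(beta, 2))) {
      if (eps <= 1e-10 * scale) break;
      eps *= 0.1;
    }
    if ((it + 1) % 10 == 0) eps = std::max(eps * 0.1, 1e-10 * scale);
  }

  // Exact polish: alternate coordinate steps with moves along the edge
  // directions of the vertex suggested by the p smallest residuals
  // (an optimal quantile-regression solution interpolates p observations;
  // a point where no coordinate or active-set edge direction improves the
  // pinball loss is a global LP optimum).
  double loss = pinball(r, tau);
  const double tol = 1e-12;
  for (int cyc = 0; cyc < cd_cycles; ++cyc) {
    bool improved = false;

    for (uword j = 0; j < p; ++j) {
      vec xj = X.col(j);
      double d = coord_step(r, xj, tau);
      if (d != 0.0) {
        vec r_new = r - xj * d;
        double loss_new = pinball(r_new, tau);
        if (loss_new < loss - tol * (1.0 + std::abs(loss))) {
          beta[j] += d; r = r_new; loss = loss_new; improved = true;
        }
      }
    }

    if (p > 1 && n >= p) {
      // active set: p rows of smallest |r| giving a nonsingular basis
      uvec ord = sort_index(abs(r));
      mat Xb(p, p, fill::zeros);
      uword got = 0;
      for (uword k = 0; k < n && got < p; ++k) {
        Xb.row(got) = X.row(ord[k]);   // design rows repeat; build a
        mat sub = Xb.rows(0, got);     // nonsingular basis greedily
        if (arma::rank(sub) == got + 1) ++got;
      }
      if (got == p && rcond(Xb) > 1e-10) {
        for (uword i = 0; i < p; ++i) {
          vec e(p, fill::zeros); e[i] = 1.0;
          vec eta;
          if (!solve(eta, Xb, e, solve_opts::fast)) continue;
          vec q = X * eta;
          double t = coord_step(r, q, tau);
          if (t != 0.0) {
            vec r_new = r - q * t;
            double loss_new = pinball(r_new, tau);
            if (loss_new < loss - tol * (1.0 + std::abs(loss))) {
              beta += eta * t; r = r_new; loss = loss_new; improved = true;
            }
          }
        }
      }
    }

    if (!improved) break;
  }

  return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                            Rcpp::Named("loss") = loss);
}
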