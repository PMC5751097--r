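// Hot loop of the center-frequency search: for each candidate frequency
// vector, build the Gaussian-RBF design on the harmonic center
// trajectory, solve the ridge least-squares problem for all channels,
// and return each channel's relative squared error. Mirrors the R path
// (harmonic_states -> place_centers -> default_sharpness -> eval_basis
// -> fit_weights); the R path remains the reference implementation used
// to build the final model at the selected frequencies.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// median, R convention (mean of middle pair for even length)
static double median_r(std::vector<double>& x) {
  std::sort(x.begin(), x.end());
  const size_t n = x.size();
  if (n == 0) return datum::nan;
  if (n % 2 == 1) return x[n / 2];
  return 0.5 * (x[n / 2 - 1] + x[n / 2]);
}

// 1 / median nearest-neighbour distance among distinct rows of C;
// NaN when fewer than 2 distinct rows exist
static double default_sharpness_cpp(const mat& C) {
  const uword m = C.n_rows, n = C.n_cols;
  mat D(m, m, fill::zeros);
  for (uword i = 0; i < m; ++i)
    for (uword j = i + 1; j < m; ++j) {
      double s = 0.0;
      for (uword k = 0; k < n; ++k) {
        const double d = C(i, k) - C(j, k);
        s += d * d;
      }
      D(i, j) = D(j, i) = std::sqrt(s);
    }
  std::vector<bool> dup(m, false);
  for (uword i = 1; i < m; ++i)
    for (uword j = 0; j < i; ++j)
      if (!dup[j] && D(i, j) == 0.0) { dup[i] = true; break; }
  std::vector<double> nn;
  for (uword i = 0; i < m; ++i) {
    if (dup[i]) continue;
    double best = datum::inf;
    for (uword j = 0; j < m; ++j)
      if (j != i && !dup[j] && D(i, j) < best) best = D(i, j);
    if (std::isfinite(best)) nn.push_back(best);
  }
  if (nn.size() < 1) return datum::nan;
  double med = median_r(nn);
  if (!(med > 0)) return datum::nan;
  return 1.0 / med;
}

// [[Rcpp::export(name = ".rel_err_grid_cpp")]]
arma::mat rel_err_grid_cpp(const arma::vec& tau, const arma::mat& Y,
                           const arma::mat& omegas, const arma::uvec& idx1,
                           bool intercept, double ridge_rel) {
  const uword K = tau.n_elem, C = Y.n_cols, ncand = omegas.n_rows;
  const uword n = omegas.n_cols, nm = idx1.n_elem;
  const uword P = nm + (intercept ? 1 : 0);
  if (Y.n_rows != K) Rcpp::stop("targets and times disagree on frame count");

  rowvec den = sum(square(Y), 0);
  if (den.min() <= 0.0) Rcpp::stop("a target channel has zero second moment");

  mat out(ncand, C);
  mat q(K, n), Ctr(nm, n), Phi(K, P), G, Gr, A, Wt;
  vec qn(K), cn(nm);
  if (intercept) Phi.col(P - 1).ones();

  for (uword c = 0; c < ncand; ++c) {
    for (uword j = 0; j < n; ++j) {
      const double w = omegas(c, j);
      double* qj = q.colptr(j);
      for (uword i = 0; i < K; ++i) qj[i] = std::sin(w * tau[i]);
    }
    for (uword i = 0; i < nm; ++i) Ctr.row(i) = q.row(idx1[i] - 1);
    const double b = default_sharpness_cpp(Ctr);
    if (!std::isfinite(b)) { out.row(c).fill(datum::inf); continue; }
    qn = sum(square(q), 1);
    cn = sum(square(Ctr), 1);
    // squared distances, then the Gaussian response, built in place
    mat d2(Phi.memptr(), K, nm, false, true);  // alias first nm columns
    d2 = q * (-2.0 * Ctr.t());
    d2.each_col() += qn;
    d2.each_row() += cn.t();
    const double s = -0.5 * b * b;
    double* ph = Phi.memptr();
    for (uword i = 0; i < K * nm; ++i)
      ph[i] = std::exp(s * (ph[i] > 0.0 ? ph[i] : 0.0));

    G = Phi.t() * Phi;
    const double lambda = ridge_rel * mean(G.diag());
    Gr = G;
    Gr.diag() += lambda;
    A = Phi.t() * Y;
    if (!solve(Wt, Gr, A, solve_opts::likely_sympd + solve_opts::no_approx)) {
      out.row(c).fill(datum::inf);
      continue;
    }
    for (uword j = 0; j < C; ++j) {
      double rss = den(j) - 2.0 * dot(A.col(j), Wt.col(j)) +
                   as_scalar(Wt.col(j).t() * G * Wt.col(j));
      if (rss < 0) rss = 0;
      out(c, j) = rss / den(j);
    }
  }
  return out;
}
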