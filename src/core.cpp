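// Compiled cores for the two hot loops: the joint-normal data-augmentation
// Gibbs sampler used for multiple imputation, and the case-resampling
// bootstrap that refits the OLS path system in every replicate. All
// randomness comes from R's RNG so set.seed() in R controls everything.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat rnorm_mat(int n, int p) {
  arma::mat z(n, p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) z(i, j) = R::norm_rand();
  return z;
}

static arma::mat safe_chol_lower(arma::mat s, double ridge) {
  arma::mat l;
  const int p = s.n_rows;
  double eps = ridge;
  for (int k = 0; k < 8; ++k) {
    if (arma::chol(l, arma::symmatu(s), "lower")) return l;
    s += eps * arma::eye(p, p);
    eps *= 10.0;
  }
  stop("Cholesky failed even after ridge regularization.");
  return l; // unreachable
}

// Sigma ~ Inverse-Wishart(df, S) via Bartlett on Sigma^{-1} ~ Wishart(df, S^{-1})
static arma::mat draw_invwishart(int df, const arma::mat& s, double ridge) {
  const int p = s.n_rows;
  arma::mat sinv;
  if (!arma::inv_sympd(sinv, arma::symmatu(s) + ridge * arma::eye(p, p))) {
    sinv = arma::pinv(arma::symmatu(s) + ridge * arma::eye(p, p));
  }
  arma::mat l = safe_chol_lower(sinv, ridge);
  arma::mat a(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) a(i, i) = std::sqrt(R::rchisq(df - i));
  for (int i = 1; i < p; ++i)
    for (int j = 0; j < i; ++j) a(i, j) = R::norm_rand();
  arma::mat la = l * a;
  arma::mat w = la * la.t();
  arma::mat sigma;
  if (!arma::inv_sympd(sigma, arma::symmatu(w) + ridge * arma::eye(p, p))) {
    sigma = arma::pinv(arma::symmatu(w) + ridge * arma::eye(p, p));
  }
  return arma::symmatu(sigma);
}

// One data-augmentation chain. `y` arrives with missing entries pre-filled
// (e.g. with observed column means); which entries are missing is encoded by
// the pattern lists (0-based row/column indices, grouped by missingness
// pattern). Alternates the I-step (draw each row's missing block from its
// conditional normal) and the P-step (draw mu, Sigma from the
// normal-inverse-Wishart posterior under a Jeffreys-style prior).
// [[Rcpp::export]]
List da_gibbs_cpp(arma::mat y, List pat_rows, List pat_mis, List pat_obs,
                  int n_iter, int monitor_every, IntegerVector save_iters,
                  arma::vec mu, arma::mat sigma, double ridge) {
  const int n = y.n_rows, p = y.n_cols;
  if (n - 1 < p) stop("Data augmentation needs n - 1 >= number of variables.");
  const int n_pat = pat_rows.size();
  std::vector<arma::uvec> rows(n_pat), mis(n_pat), obs(n_pat);
  for (int g = 0; g < n_pat; ++g) {
    rows[g] = as<arma::uvec>(pat_rows[g]);
    mis[g] = as<arma::uvec>(pat_mis[g]);
    obs[g] = as<arma::uvec>(pat_obs[g]);
  }
  std::set<int> save_set(save_iters.begin(), save_iters.end());
  List saves;
  int n_monitor = (monitor_every > 0) ? n_iter / monitor_every : 0;
  arma::mat monitor(n_monitor, 2 * p, arma::fill::zeros);
  int mrow = 0;

  bool any_missing = false;
  for (int g = 0; g < n_pat; ++g) {
    if (mis[g].n_elem > 0) { any_missing = true; break; }
  }
  for (int it = 1; it <= n_iter; ++it) {
    // I-step via the precision matrix: y_mis | y_obs is normal with
    // covariance inv(Omega_mm) and mean mu_m - inv(Omega_mm) Omega_mo
    // (y_o - mu_o); Omega_mm is small (the missing block), so its
    // factorization is cheap even with many distinct patterns.
    if (any_missing) {
      arma::mat omega;
      if (!arma::inv_sympd(omega, arma::symmatu(sigma))) {
        omega = arma::pinv(arma::symmatu(sigma) +
                           ridge * arma::eye(sigma.n_rows, sigma.n_cols));
      }
      for (int g = 0; g < n_pat; ++g) {
        const int pm = mis[g].n_elem;
        if (pm == 0) continue;
        const arma::uvec& r = rows[g];
        arma::mat a = omega.submat(mis[g], mis[g]);
        arma::mat l = safe_chol_lower(a, ridge);
        arma::mat cond_mean;
        if (obs[g].n_elem == 0) {
          cond_mean = arma::repmat(mu.elem(mis[g]).t(), r.n_elem, 1);
        } else {
          arma::mat omo = omega.submat(mis[g], obs[g]); // pm x po
          arma::mat yo = y.submat(r, obs[g]);
          yo.each_row() -= mu.elem(obs[g]).t();
          arma::mat rhs = yo * omo.t(); // n_g x pm
          // delta solves A delta' = rhs'
          arma::mat delta = arma::solve(arma::trimatu(l.t()),
                            arma::solve(arma::trimatl(l), rhs.t())).t();
          cond_mean = arma::repmat(mu.elem(mis[g]).t(), r.n_elem, 1) - delta;
        }
        // cov = inv(A) = W' W with W = inv(L)
        arma::mat w = arma::inv(arma::trimatl(l));
        y.submat(r, mis[g]) = cond_mean + rnorm_mat(r.n_elem, pm) * w;
      }
    }
    // P-step
    arma::rowvec ybar = arma::mean(y, 0);
    arma::mat c = y.each_row() - ybar;
    arma::mat s = c.t() * c;
    sigma = draw_invwishart(n - 1, s, ridge);
    arma::vec z(p);
    for (int i = 0; i < p; ++i) z(i) = R::norm_rand();
    mu = ybar.t() + safe_chol_lower(sigma, ridge) * z / std::sqrt((double)n);

    if (monitor_every > 0 && it % monitor_every == 0 && mrow < n_monitor) {
      monitor.row(mrow).cols(0, p - 1) = mu.t();
      monitor.row(mrow).cols(p, 2 * p - 1) = sigma.diag().t();
      ++mrow;
    }
    if (save_set.count(it)) saves.push_back(wrap(y));
  }
  return List::create(
    _["monitor"] = monitor, _["saves"] = saves,
    _["mu"] = mu, _["sigma"] = sigma
  );
}

static arma::vec ols_beta(const arma::mat& x, const arma::vec& y) {
  arma::mat xtx = x.t() * x;
  arma::vec beta;
  if (!arma::solve(beta, xtx, x.t() * y,
                   arma::solve_opts::no_approx + arma::solve_opts::likely_sympd)) {
    stop("rank-deficient design");
  }
  return beta;
}

// Case-resampling bootstrap of an OLS equation system. `eqs` is a list of
// equations, each a list with elements `cols` (1-based data columns of the
// regressors, intercept added automatically), `ycol` (1-based response
// column), and `take` (1-based positions in the coefficient vector,
// position 1 = intercept, to report). Returns B x sum(take lengths); a
// replicate whose design is rank-deficient is redrawn (total redraws capped).
// [[Rcpp::export]]
List boot_paths_cpp(const arma::mat& data, List eqs, int n_boot,
                    int max_redraws) {
  const int n = data.n_rows;
  const int n_eq = eqs.size();
  std::vector<arma::uvec> cols(n_eq), take(n_eq);
  std::vector<int> ycol(n_eq);
  int n_out = 0;
  for (int e = 0; e < n_eq; ++e) {
    List eq = eqs[e];
    cols[e] = as<arma::uvec>(eq["cols"]) - 1;
    take[e] = as<arma::uvec>(eq["take"]) - 1;
    ycol[e] = as<int>(eq["ycol"]) - 1;
    n_out += take[e].n_elem;
  }
  arma::mat out(n_boot, n_out);
  int redraws = 0;
  for (int b = 0; b < n_boot; ++b) {
    bool ok = false;
    while (!ok) {
      arma::uvec idx(n);
      for (int i = 0; i < n; ++i) {
        int k = (int)std::floor(R::unif_rand() * n);
        idx(i) = (k >= n) ? n - 1 : k;
      }
      arma::mat d = data.rows(idx);
      int pos = 0;
      ok = true;
      try {
        for (int e = 0; e < n_eq; ++e) {
          arma::mat x(n, cols[e].n_elem + 1);
          x.col(0).ones();
          x.cols(1, cols[e].n_elem) = d.cols(cols[e]);
          arma::vec beta = ols_beta(x, d.col(ycol[e]));
          for (arma::uword t = 0; t < take[e].n_elem; ++t)
            out(b, pos + t) = beta(take[e](t));
          pos += take[e].n_elem;
        }
      } catch (...) {
        ok = false;
        if (++redraws > max_redraws)
          stop("Too many rank-deficient bootstrap replicates (redraw cap hit).");
      }
    }
  }
  return List::create(_["draws"] = out, _["redraws"] = redraws);
}
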