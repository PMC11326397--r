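// Gibbs sampler for the low-rank summary-statistics Bayesian mixture model.
//
// Model, per LD block b:  w_b = Q_b beta_b + eps_b,  eps_b ~ N(0, I sigma_e2),
// with beta_j ~ sum_k pi_jk N(0, gamma_k sigma_g2) and gamma_1 = 0 (point mass).
// The point-normal model (K = 2, gamma = (0, 1)) makes sigma_g2 the slab
// variance; the multi-component model uses prespecified ascending gammas and,
// optionally, per-SNP mixture priors driven by annotations through a
// sequential probit construction.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double trunc_norm(double mean, bool positive) {
  // one draw from N(mean, 1) truncated to (0, inf) or (-inf, 0)
  double p0 = R::pnorm(-mean, 0.0, 1.0, 1, 0);  // P(z + mean < 0)
  p0 = std::min(std::max(p0, 1e-12), 1.0 - 1e-12);
  double u = unif_rand();
  double q = positive ? (p0 + u * (1.0 - p0)) : (u * p0);
  q = std::min(std::max(q, 1e-12), 1.0 - 1e-12);
  return mean + R::qnorm(q, 0.0, 1.0, 1, 0);
}

static arma::vec rdirichlet(const arma::vec& alpha) {
  arma::vec g(alpha.n_elem);
  for (arma::uword i = 0; i < alpha.n_elem; ++i)
    g[i] = R::rgamma(alpha[i], 1.0);
  double s = arma::accu(g);
  if (s <= 0) g.fill(1.0 / alpha.n_elem); else g /= s;
  return g;
}

// Recompute per-SNP mixture priors from the sequential probit sticks:
// P(delta > k | delta >= k) = Phi(eta_k),  eta_k = mu_k + A alpha_k.
static void probit_pi(const arma::mat& W, const arma::mat& theta,
                      arma::mat& pi_mat) {
  const arma::uword m = W.n_rows;
  const arma::uword K = theta.n_cols + 1;
  arma::vec carry(m, arma::fill::ones);  // P(delta >= k)
  for (arma::uword k = 0; k + 1 < K; ++k) {
    arma::vec eta = W * theta.col(k);
    arma::vec phi(m);
    for (arma::uword j = 0; j < m; ++j)
      phi[j] = R::pnorm(eta[j], 0.0, 1.0, 1, 0);
    pi_mat.col(k) = carry % (1.0 - phi);
    carry %= phi;
  }
  pi_mat.col(K - 1) = carry;
}

// [[Rcpp::export]]
List gibbs_gbmm_cpp(const List& w_list, const List& Q_list,
                    const NumericVector& n_block,
                    const NumericVector& gamma_in,
                    const NumericVector& pi_init,
                    const arma::mat& A, bool use_annot,
                    int n_iter, int burn_in, int thin,
                    bool auto_prune, int prune_every,
                    bool fixed_hyper,
                    double sigma_e2_init, double sigma_g2_init,
                    double nu, double sigma_e2_floor,
                    bool random_order) {
  const int B = w_list.size();
  std::vector<arma::vec> w(B), eps(B);
  std::vector<arma::mat> Q(B);
  int m = 0, q_total = 0;
  for (int b = 0; b < B; ++b) {
    w[b] = as<arma::vec>(w_list[b]);
    Q[b] = as<arma::mat>(Q_list[b]);
    eps[b] = w[b];
    m += Q[b].n_cols;
    q_total += Q[b].n_rows;
  }
  // global SNP index -> (block, column), and Q_j'Q_j
  arma::ivec blk_of(m), col_of(m);
  arma::vec qtq(m);
  {
    int j = 0;
    for (int b = 0; b < B; ++b)
      for (arma::uword c = 0; c < Q[b].n_cols; ++c, ++j) {
        blk_of[j] = b; col_of[j] = c;
        qtq[j] = arma::dot(Q[b].col(c), Q[b].col(c));
        if (qtq[j] <= 0) qtq[j] = n_block[b];  // degenerate column guard
      }
  }

  arma::vec gamma = as<arma::vec>(gamma_in);
  int K = gamma.n_elem;
  arma::vec pi = as<arma::vec>(pi_init);
  arma::vec beta(m, arma::fill::zeros);
  arma::ivec delta(m, arma::fill::zeros);  // 0 = null
  double sigma_e2 = sigma_e2_init, sigma_g2 = sigma_g2_init;
  const double S_e0 = sigma_e2_init, S_g0 = sigma_g2_init;

  arma::mat W_ann, theta, pi_mat;
  if (use_annot) {
    W_ann = arma::join_rows(arma::ones(m), A);
    theta.zeros(W_ann.n_cols, K - 1);
    pi_mat.set_size(m, K);
    // initialize sticks so the implied priors match pi_init
    double carry = 1.0;
    for (int k = 0; k + 1 < K; ++k) {
      double cond = (carry > 1e-12) ? 1.0 - pi[k] / carry : 0.5;
      cond = std::min(std::max(cond, 1e-6), 1.0 - 1e-6);
      theta(0, k) = R::qnorm(cond, 0.0, 1.0, 1, 0);
      carry *= cond;
    }
    probit_pi(W_ann, theta, pi_mat);
  }

  const int n_keep = n_iter - burn_in;
  int burn_end = burn_in;
  bool prune_active = auto_prune && K > 2;
  arma::vec prune_win(K, arma::fill::zeros);  // windowed variance by comp
  int prune_win_n = 0;
  std::vector<int> prune_iter;
  std::vector<double> prune_gamma;

  // accumulators
  arma::vec pip_count(m, arma::fill::zeros), beta_sum(m, arma::fill::zeros);
  std::vector<double> h2_draws, se2_draws, sg2_draws;
  h2_draws.reserve(n_keep); se2_draws.reserve(n_keep); sg2_draws.reserve(n_keep);
  arma::mat pi_draws(n_keep, K, arma::fill::zeros);
  arma::mat comp_count(m, K, arma::fill::zeros);
  const int n_thin_max = (n_keep + thin - 1) / thin;
  arma::mat beta_draws(n_thin_max, m, arma::fill::zeros);
  arma::mat theta_draws;
  if (use_annot) theta_draws.zeros(n_thin_max, W_ann.n_cols * (K - 1));
  int n_ret = 0, n_thin = 0;

  arma::vec logp(K), prob(K);
  arma::uvec order(m);
  for (int j = 0; j < m; ++j) order[j] = j;

  int iter = 0;
  const int total_cap = burn_in * 20 + n_iter;  // safety against prune loops
  while (n_ret < n_keep && iter < total_cap) {
    ++iter;
    if (random_order) order = arma::shuffle(order);

    // --- sweep over SNPs ---
    for (int jj = 0; jj < m; ++jj) {
      const int j = order[jj];
      const int b = blk_of[j], c = col_of[j];
      const double r = arma::dot(Q[b].col(c), eps[b]) + qtq[j] * beta[j];
      const double pi0 = use_annot ? pi_mat(j, 0) : pi[0];
      logp[0] = (pi0 > 0) ? std::log(pi0) : -1e300;
      for (int k = 1; k < K; ++k) {
        const double pik = use_annot ? pi_mat(j, k) : pi[k];
        if (pik <= 0 || sigma_g2 <= 0) { logp[k] = -1e300; continue; }
        const double lam = sigma_e2 / (gamma[k] * sigma_g2);
        const double Ck = qtq[j] + lam;
        logp[k] = std::log(pik) + 0.5 * std::log(lam) - 0.5 * std::log(Ck) +
                  r * r / (2.0 * Ck * sigma_e2);
      }
      const double mx = logp.max();
      double tot = 0;
      for (int k = 0; k < K; ++k) { prob[k] = std::exp(logp[k] - mx); tot += prob[k]; }
      double u = unif_rand() * tot;
      int k_new = 0;
      for (; k_new < K - 1; ++k_new) { u -= prob[k_new]; if (u <= 0) break; }
      double beta_new = 0.0;
      if (k_new > 0) {
        const double lam = sigma_e2 / (gamma[k_new] * sigma_g2);
        const double Ck = qtq[j] + lam;
        beta_new = r / Ck + norm_rand() * std::sqrt(sigma_e2 / Ck);
      }
      if (beta[j] != beta_new)
        eps[b] += Q[b].col(c) * (beta[j] - beta_new);
      beta[j] = beta_new;
      delta[j] = k_new;
    }

    // --- hyperparameter updates ---
    arma::vec counts(K, arma::fill::zeros), varexp(K, arma::fill::zeros);
    double ssq_g = 0.0;
    for (int j = 0; j < m; ++j) {
      counts[delta[j]] += 1.0;
      if (delta[j] > 0) {
        ssq_g += beta[j] * beta[j] / gamma[delta[j]];
        varexp[delta[j]] += beta[j] * beta[j];
      }
    }
    if (!fixed_hyper) {
      if (use_annot) {
        // Albert-Chib update of each stick's probit regression
        for (int k = 0; k + 1 < K; ++k) {
          std::vector<arma::uword> idx;
          idx.reserve(m);
          for (int j = 0; j < m; ++j)
            if (delta[j] >= k) idx.push_back(j);
          if (idx.empty()) continue;
          arma::uvec uidx(idx);
          arma::mat Wk = W_ann.rows(uidx);
          arma::vec eta = Wk * theta.col(k);
          arma::vec z(uidx.n_elem);
          for (arma::uword t = 0; t < uidx.n_elem; ++t)
            z[t] = trunc_norm(eta[t], delta[uidx[t]] > k);
          arma::mat WtW = Wk.t() * Wk;
          WtW.diag() += 1e-6;
          arma::vec mu = arma::solve(WtW, Wk.t() * z,
                                     arma::solve_opts::likely_sympd);
          arma::mat Rch = arma::chol(WtW);
          arma::vec e(mu.n_elem);
          for (arma::uword t = 0; t < e.n_elem; ++t) e[t] = norm_rand();
          theta.col(k) = mu + arma::solve(arma::trimatu(Rch), e);
        }
        probit_pi(W_ann, theta, pi_mat);
        for (int k = 0; k < K; ++k) pi[k] = arma::mean(pi_mat.col(k));
      } else {
        pi = rdirichlet(counts + 1.0);
      }
      const double m_nn = m - counts[0];
      sigma_g2 = (nu * S_g0 + ssq_g) / R::rchisq(nu + m_nn);
      double sse = 0.0;
      for (int b = 0; b < B; ++b) sse += arma::dot(eps[b], eps[b]);
      sigma_e2 = (nu * S_e0 + sse) / R::rchisq(nu + q_total);
      if (sigma_e2 < sigma_e2_floor) sigma_e2 = sigma_e2_floor;
    }

    // --- automatic component pruning ---
    if (prune_active) {
      prune_win += varexp;
      ++prune_win_n;
      if (iter % prune_every == 0) {
        const double v1 = prune_win[1] / prune_win_n;   // smallest gamma
        const double v2 = prune_win[2] / prune_win_n;   // second smallest
        if (v1 < 0.5 * v2 && K > 2) {
          prune_iter.push_back(iter);
          prune_gamma.push_back(gamma[1]);
          for (int j = 0; j < m; ++j) {
            if (delta[j] == 1) {
              const int b = blk_of[j], c = col_of[j];
              if (beta[j] != 0.0) eps[b] += Q[b].col(c) * beta[j];
              beta[j] = 0.0; delta[j] = 0;
            } else if (delta[j] > 1) {
              delta[j] -= 1;
            }
          }
          gamma.shed_row(1);
          pi.shed_row(1);
          pi /= arma::accu(pi);
          K -= 1;
          if (use_annot) {
            theta.zeros(W_ann.n_cols, K - 1);
            pi_mat.set_size(m, K);
            for (int k = 0; k + 1 < K; ++k)
              theta(0, k) = R::qnorm(1.0 - 1.0 / (K - k), 0.0, 1.0, 1, 0);
            probit_pi(W_ann, theta, pi_mat);
            theta_draws.zeros(n_thin_max, W_ann.n_cols * (K - 1));
          }
          pi_draws.set_size(n_keep, K);
          comp_count.zeros(m, K);
          logp.set_size(K); prob.set_size(K);
          prune_win.zeros(K);
          prune_win_n = 0;
          burn_end = iter + burn_in;  // restart burn-in
          if (K == 2) prune_active = false;
        } else {
          prune_active = false;  // checkpoint with no removal: stop checking
        }
        prune_win.zeros(); prune_win_n = 0;
      }
    }

    // --- retention ---
    if (iter > burn_end) {
      double var_g = 0.0;
      for (int b = 0; b < B; ++b) {
        arma::vec qb = w[b] - eps[b];        // = Q_b beta_b
        var_g += arma::dot(qb, qb) / n_block[b];
      }
      for (int j = 0; j < m; ++j) {
        if (delta[j] > 0) pip_count[j] += 1.0;
        comp_count(j, delta[j]) += 1.0;
      }
      beta_sum += beta;
      // b_std is on the standardized-phenotype scale (var(y) = 1), so the
      // genetic variance beta' R beta is itself the SNP-heritability draw.
      // sigma_e2 is a nuisance absorbing cross-block genetic variance and
      // summary-data heterogeneity; var_g/(var_g + sigma_e2) would be
      // biased downward whenever the genome is split into many blocks.
      h2_draws.push_back(std::min(var_g, 1.0));
      se2_draws.push_back(sigma_e2);
      sg2_draws.push_back(sigma_g2);
      pi_draws.row(n_ret) = pi.t();
      if (n_ret % thin == 0) {
        beta_draws.row(n_thin) = beta.t();
        if (use_annot)
          theta_draws.row(n_thin) =
            arma::vectorise(theta).t();
        ++n_thin;
      }
      ++n_ret;
    }
  }

  beta_draws.resize(n_thin, m);
  if (use_annot) theta_draws.resize(n_thin, theta_draws.n_cols);
  return List::create(
    _["pip"] = pip_count / std::max(n_ret, 1),
    _["beta_mean"] = beta_sum / std::max(n_ret, 1),
    _["beta_draws"] = beta_draws,
    _["h2_draws"] = h2_draws,
    _["sigma_e2_draws"] = se2_draws,
    _["sigma_g2_draws"] = sg2_draws,
    _["pi_draws"] = pi_draws,
    _["comp_post"] = comp_count / std::max(n_ret, 1),
    _["theta_draws"] = theta_draws,
    _["gamma_final"] = gamma,
    _["prune_iter"] = prune_iter,
    _["prune_gamma"] = prune_gamma,
    _["n_retained"] = n_ret,
    _["total_iter"] = iter);
}
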