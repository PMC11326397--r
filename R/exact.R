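#' Exact posterior inclusion probabilities for a small system
#'
#' Computes PIPs by exhaustive enumeration of all 2^m causal configurations
#' under the point-normal model with fixed hyperparameters. For a
#' configuration S, the projected data `w` are multivariate normal,
#' \deqn{w \mid S \sim N(0, \sigma_e^2 I + \sigma_\beta^2 Q_S Q_S'),}
#' with prior `pi^{|S|} (1-pi)^{m-|S|}`, and
#' `PIP_j = sum over configurations containing j of the posterior
#' configuration probability`. Intended as an independent reference for the
#' MCMC sampler on systems of up to a dozen SNPs; it shares no code path
#' with the sampler.
#'
#' @param b_std standardized marginal effects (length m <= 12).
#' @param R LD correlation matrix (m x m).
#' @param n sample size.
#' @param pi prior probability that a SNP is causal.
#' @param sigma_b2 slab (causal-effect) variance.
#' @param sigma_e2 residual variance on the standardized scale.
#' @return list with `pip` (length m), `config_prob` (2^m posterior
#'   probabilities) and `configs` (logical matrix of configurations).
#' @export
exact_posterior_small <- function(b_std, R, n, pi, sigma_b2, sigma_e2) {
  m <- length(b_std)
  if (m > 12) stop("exhaustive enumeration limited to m <= 12 SNPs")
  stopifnot(nrow(R) == m, ncol(R) == m, pi > 0, pi < 1,
            sigma_b2 > 0, sigma_e2 > 0, n > 1)

  # projection onto the positive eigenspace of R (direct, not via the
  # package's pseudo-data builder)
  eig <- eigen((R + t(R)) / 2, symmetric = TRUE)
  keep <- eig$values > 1e-10
  lam <- eig$values[keep]
  U <- eig$vectors[, keep, drop = FALSE]
  w <- sqrt(n) * drop(crossprod(U, b_std)) / sqrt(lam)
  Q <- sqrt(n) * (sqrt(lam) * t(U))
  q <- length(w)

  n_cfg <- 2^m
  configs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  colnames(configs) <- NULL
  log_post <- numeric(n_cfg)
  for (i in seq_len(n_cfg)) {
    S <- which(configs[i, ])
    V <- diag(sigma_e2, q)
    if (length(S) > 0) {
      QS <- Q[, S, drop = FALSE]
      V <- V + sigma_b2 * tcrossprod(QS)
    }
    ch <- chol(V)
    log_det <- 2 * sum(log(diag(ch)))
    quad <- sum(backsolve(ch, w, transpose = TRUE)^2)
    log_lik <- -0.5 * (log_det + quad)
    log_prior <- length(S) * log(pi) + (m - length(S)) * log(1 - pi)
    log_post[i] <- log_lik + log_prior
  }
  post <- exp(log_post - max(log_post))
  post <- post / sum(post)
  pip <- colSums(post * configs)
  list(pip = pip, config_prob = post, configs = configs)
}
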