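#' Conditional component-membership probabilities for one SNP
#'
#' The full-conditional probability that a SNP's effect belongs to each
#' mixture component, given its adjusted projected correlation `r` (the
#' SNP's own contribution plus the residual projection, `r = Q_j' eps +
#' n beta_j`). With `lambda_k = sigma_e2 / (gamma_k sigma_g2)` and
#' `C_k = n + lambda_k`, the non-null components have probability
#' proportional to
#' \deqn{\pi_k\, \lambda_k^{1/2} C_k^{-1/2}
#'       \exp\{r^2 / (2 C_k \sigma_e^2)\},}
#' and the null component to `pi_1`. Computed in log space with
#' max-subtraction, so it is overflow-free.
#'
#' @param r adjusted projected correlation for the focal SNP.
#' @param n sample size.
#' @param sigma_e2 residual variance.
#' @param sigma_g2 genetic-variance scale (slab variance when
#'   `gammas = c(0, 1)`).
#' @param pi mixture proportions for this SNP (length K, sums to 1).
#' @param gammas variance-scaling coefficients (first entry 0, ascending).
#' @return list with `comp_prob` (length K, sums to 1), `lambda` and `c_k`
#'   (per non-null component, with `NA` for the null slot), and the
#'   conditional posterior `mean` and `var` of the effect per component.
#' @export
snp_component_probs <- function(r, n, sigma_e2, sigma_g2, pi, gammas) {
  if (!is.finite(r)) stop("r must be finite")
  K <- length(gammas)
  stopifnot(length(pi) == K, gammas[1] == 0)
  if (any(pi[-1] > 0) && sigma_g2 <= 0) {
    stop("sigma_g2 must be positive when non-null components have mass")
  }
  lambda <- c(NA_real_, sigma_e2 / (gammas[-1] * sigma_g2))
  c_k <- c(NA_real_, n + lambda[-1])
  logp <- numeric(K)
  logp[1] <- if (pi[1] > 0) log(pi[1]) else -Inf
  for (k in seq(2, length.out = K - 1)) {
    logp[k] <- if (pi[k] > 0) {
      log(pi[k]) + 0.5 * log(lambda[k]) - 0.5 * log(c_k[k]) +
        r^2 / (2 * c_k[k] * sigma_e2)
    } else -Inf
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  list(comp_prob = p, lambda = lambda, c_k = c_k,
       mean = c(0, r / c_k[-1]), var = c(0, sigma_e2 / c_k[-1]))
}

#' Per-SNP mixture priors from sequential-probit annotation effects
#'
#' Maps annotation values to SNP-specific component-membership priors via a
#' stick-breaking probit construction: for rank `k = 1..K-1`,
#' `P(delta > k | delta >= k) = pnorm(mu_k + A alpha_k)`, so a positive
#' annotation effect on the first stick increases a SNP's non-null prior
#' mass. The resulting rows are non-negative and sum to one.
#'
#' @param A annotation matrix (m x C), no intercept column.
#' @param mu numeric vector of K-1 stick intercepts (probit scale).
#' @param alpha C x (K-1) matrix of annotation effects (probit scale).
#' @return m x K matrix of per-SNP mixture proportions, column 1 the null.
#' @export
probit_mixture_priors <- function(A, mu, alpha) {
  A <- as.matrix(A)
  alpha <- as.matrix(alpha)
  stopifnot(length(mu) == ncol(alpha), nrow(alpha) == ncol(A))
  m <- nrow(A)
  K <- length(mu) + 1
  pi_mat <- matrix(0, m, K)
  carry <- rep(1, m)
  for (k in seq_len(K - 1)) {
    phi <- stats::pnorm(mu[k] + drop(A %*% alpha[, k]))
    pi_mat[, k] <- carry * (1 - phi)
    carry <- carry * phi
  }
  pi_mat[, K] <- carry
  pi_mat
}

#' Automatic pruning rule for mixture components
#'
#' Applies the checkpoint rule used during MCMC: the smallest (by `gamma`)
#' non-null component is removed when the genetic variance it explains is
#' less than half of that explained by the second smallest; a spec already
#' at two components is never reduced further. The comparison is strict,
#' so a component explaining exactly half is retained.
#'
#' @param gammas current variance-scaling coefficients (first entry 0).
#' @param var_shares genetic variance explained per component, aligned to
#'   `gammas` (the null entry is ignored).
#' @param pi optional mixture proportions to carry along (renormalized on
#'   removal).
#' @return list with `gammas`, `pi`, and `removed` (the dropped gamma, or
#'   `NULL` if no removal).
#' @export
auto_prune_components <- function(gammas, var_shares, pi = NULL) {
  K <- length(gammas)
  stopifnot(length(var_shares) == K, gammas[1] == 0)
  if (K <= 2) return(list(gammas = gammas, pi = pi, removed = NULL))
  if (var_shares[2] < 0.5 * var_shares[3]) {
    removed <- gammas[2]
    gammas <- gammas[-2]
    if (!is.null(pi)) {
      pi <- pi[-2]
      pi <- pi / sum(pi)
    }
    return(list(gammas = gammas, pi = pi, removed = removed))
  }
  list(gammas = gammas, pi = pi, removed = NULL)
}
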