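#' Genetic architecture for power prediction
#'
#' Bundles the fitted mixture description of a trait — mixture proportions,
#' variance-scaling coefficients, genetic-variance scale, heritability,
#' residual variance and SNP count — the sufficient input for predicting
#' fine-mapping power at prospective sample sizes. Usually extracted from a
#' [gbmm()] fit, but can be built by hand.
#'
#' @param x a `gbmm_fit`, or a list with elements `pi`, `gammas`,
#'   `sigma_g2`, `h2`, `M` (and optionally `sigma_e2`, default `1 - h2`).
#' @return object of class `genetic_arch`.
#' @export
genetic_architecture <- function(x) {
  if (inherits(x, "gbmm_fit")) {
    p <- x$par_res
    arch <- list(pi = p$pi, gammas = p$gammas, sigma_g2 = p$sigma_g2,
                 h2 = p$h2, M = p$m, sigma_e2 = p$sigma_e2)
  } else {
    arch <- x
    if (is.null(arch$sigma_e2)) arch$sigma_e2 <- 1 - arch$h2
  }
  stopifnot(abs(sum(arch$pi) - 1) < 1e-6, arch$h2 >= 0, arch$h2 <= 1,
            arch$M >= 1, length(arch$pi) == length(arch$gammas),
            arch$gammas[1] == 0, arch$sigma_e2 > 0)
  structure(arch, class = "genetic_arch")
}

#' @export
print.genetic_arch <- function(x, ...) {
  cat(sprintf("<genetic_arch> M = %d, h2 = %.3f, pi_nonnull = %.4g, K = %d\n",
              x$M, x$h2, 1 - x$pi[1], length(x$pi)))
  invisible(x)
}

# total genetic variance implied by the architecture
arch_vg <- function(arch) arch$M * sum(arch$pi * arch$gammas) * arch$sigma_g2

# PIP transform of the noncentral chi-square variate:
# PIP = 1 - 1 / (1 + sum_k A_k exp(B_k Z)),
# A_k = (pi_k/pi_1) sqrt(lambda_k / C_k),  B_k = n / (2 C_k),
# lambda_k = sigma_e2 / (gamma_k sigma_g2), C_k = n + lambda_k,
# Z = r^2 / (n sigma_e2) ~ chi2_1(n v / sigma_e2).
pip_of_z <- function(z, n, arch) {
  if (arch$pi[1] <= 0) stop("null proportion must be positive")
  K <- length(arch$pi)
  s <- numeric(length(z))
  for (k in seq(2, length.out = K - 1)) {
    if (arch$pi[k] <= 0) next
    lam <- arch$sigma_e2 / (arch$gammas[k] * arch$sigma_g2)
    Ck <- n + lam
    A <- (arch$pi[k] / arch$pi[1]) * sqrt(lam / Ck)
    B <- n / (2 * Ck)
    s <- s + A * exp(B * z)
  }
  1 - 1 / (1 + s)
}

#' Sample from the PIP law of a causal variant
#'
#' Draws from the sampling distribution of the PIP of an isolated causal
#' variant explaining variance `v`, at sample size `n`, under the fitted
#' mixture architecture: the adjusted association statistic follows a
#' noncentral chi-square with one degree of freedom and noncentrality
#' `n v / sigma_e2`, mapped to a PIP through the mixture odds.
#'
#' @param v variance explained by the causal variant (standardized scale).
#' @param n GWAS sample size.
#' @param arch a [genetic_architecture()].
#' @param n_draws number of Monte Carlo draws (default 1e4).
#' @return vector of PIP draws in \[0, 1\].
#' @export
sample_pip_law <- function(v, n, arch, n_draws = 1e4) {
  stopifnot(inherits(arch, "genetic_arch"), v >= 0, n >= 1)
  if (arch$sigma_e2 <= 0) stop("sigma_e2 must be positive")
  z <- stats::rchisq(n_draws, df = 1, ncp = n * v / arch$sigma_e2)
  pip_of_z(z, n, arch)
}

#' Power to detect a causal variant of given size
#'
#' Monte Carlo estimate of `Pr(PIP > alpha | v)` under the PIP law;
#' monotone non-decreasing in `v` and `n` up to Monte Carlo error.
#'
#' @inheritParams sample_pip_law
#' @param alpha PIP threshold in (0, 1).
#' @return probability.
#' @export
power_given_v <- function(v, n, alpha, arch, n_draws = 1e4) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  mean(sample_pip_law(v, n, arch, n_draws) > alpha)
}

#' Predict fine-mapping power and variance explained at a sample size
#'
#' Integrates the single-variant power over the fitted effect-size
#' distribution by Monte Carlo: causal effects are drawn from the non-null
#' mixture components, each contributing variance `v = beta^2`, and each
#' draw's association statistic is sampled from its noncentral chi-square
#' law. Returns the expected fraction of causal variants detected at the
#' PIP threshold (`power`), the expected number of causal variants
#' identified (`expected_ncv`), and the expected proportion of genetic
#' variance explained by the identified variants (`expected_phe`).
#'
#' @param arch a [genetic_architecture()].
#' @param n prospective GWAS sample size.
#' @param alpha PIP threshold (default 0.9).
#' @param n_mc number of Monte Carlo architecture draws (default 1e5).
#' @return list with `power`, `expected_ncv`, `expected_phe`, `n`, `alpha`.
#' @export
predict_power_phe <- function(arch, n, alpha = 0.9, n_mc = 1e5) {
  stopifnot(inherits(arch, "genetic_arch"), n_mc >= 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  pi_nn <- arch$pi[-1]
  m_nn <- arch$M * (1 - arch$pi[1])
  if (sum(pi_nn) <= 0 || m_nn <= 0) {
    return(list(power = 0, expected_ncv = 0, expected_phe = 0,
                n = n, alpha = alpha))
  }
  comp <- sample.int(length(pi_nn), n_mc, replace = TRUE,
                     prob = pi_nn / sum(pi_nn)) + 1L
  beta <- stats::rnorm(n_mc, 0, sqrt(arch$gammas[comp] * arch$sigma_g2))
  v <- beta^2
  z <- stats::rchisq(n_mc, df = 1, ncp = n * v / arch$sigma_e2)
  hit <- pip_of_z(z, n, arch) > alpha
  power <- mean(hit)
  vg <- arch_vg(arch)
  list(power = power,
       expected_ncv = m_nn * power,
       expected_phe = min(m_nn * mean(hit * v) / vg, 1),
       n = n, alpha = alpha)
}

#' Sample size required to reach a fine-mapping target
#'
#' Inverts [predict_power_phe()] by bisection on log sample size for a
#' target `power` or `expected_phe`. Common random numbers are used across
#' evaluations so the predicted metric is monotone along the search.
#'
#' @param arch a [genetic_architecture()].
#' @param target `"power"` or `"phe"`.
#' @param value target value in (0, 1).
#' @param alpha PIP threshold (default 0.9).
#' @param n_range search range for n (default 1e3 to 1e9).
#' @param tol absolute tolerance on the metric (default 0.005).
#' @param n_mc Monte Carlo draws per evaluation (default 5e4).
#' @param seed seed for the common random numbers (default 1).
#' @return list with `n` (smallest sample size meeting the target, or `NA`),
#'   `reachable`, `achieved`, and `asymptote` (metric at the upper range
#'   end).
#' @export
required_sample_size <- function(arch, target = c("power", "phe"), value,
                                 alpha = 0.9, n_range = c(1e3, 1e9),
                                 tol = 0.005, n_mc = 5e4, seed = 1) {
  target <- match.arg(target)
  stopifnot(value > 0, value < 1)
  metric <- function(n) {
    set.seed(seed)  # common random numbers
    p <- predict_power_phe(arch, n, alpha, n_mc)
    if (target == "power") p$power else p$expected_phe
  }
  hi_val <- metric(n_range[2])
  if (hi_val < value) {
    return(list(n = NA_real_, reachable = FALSE, achieved = NA_real_,
                asymptote = hi_val))
  }
  lo <- log(n_range[1]); hi <- log(n_range[2])
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (metric(exp(mid)) >= value - tol) hi <- mid else lo <- mid
  }
  n_star <- ceiling(exp(hi))
  list(n = n_star, reachable = TRUE, achieved = metric(n_star),
       asymptote = hi_val)
}
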