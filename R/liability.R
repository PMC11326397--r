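#' Equivalent quantitative-trait sample size on the liability scale
#'
#' Converts a case-control study's sample size to the sample size of a
#' quantitative-trait GWAS with equivalent power under the liability
#' threshold model:
#' \deqn{N_{eq} = \frac{i^2\, v (1 - v)\, N_{01}}{(1 - K)^2},}
#' where `K` is the population prevalence, `v` the sample case proportion,
#' `N01` the total number of cases and controls, and `i = h/K` the mean
#' liability of cases, with `h` the standard normal density at the
#' truncation point `t = qnorm(1 - K)`.
#'
#' @param k_prev population prevalence, in (0, 1).
#' @param n_cases,n_controls case and control counts (alternatively give
#'   `v_prev` and `n01`).
#' @param v_prev sample case proportion, in (0, 1).
#' @param n01 total sample size (cases + controls).
#' @return equivalent quantitative-trait sample size (individuals).
#' @export
equivalent_n <- function(k_prev, n_cases = NULL, n_controls = NULL,
                         v_prev = NULL, n01 = NULL) {
  if (!is.numeric(k_prev) || k_prev <= 0 || k_prev >= 1) {
    stop("k_prev must be in (0, 1)")
  }
  if (!is.null(n_cases) && !is.null(n_controls)) {
    n01 <- n_cases + n_controls
    v_prev <- n_cases / n01
  }
  if (is.null(v_prev) || is.null(n01)) {
    stop("give either n_cases/n_controls or v_prev/n01")
  }
  if (v_prev <= 0 || v_prev >= 1) stop("v_prev must be in (0, 1)")
  i <- mean_liability(k_prev)
  i^2 * v_prev * (1 - v_prev) * n01 / (1 - k_prev)^2
}

# mean liability of cases: i = phi(t)/K at threshold t = qnorm(1 - K)
mean_liability <- function(k_prev) {
  t <- stats::qnorm(1 - k_prev)
  stats::dnorm(t) / k_prev
}

#' Convert z-scores to liability-scale effect and standard error
#'
#' Given the z-score and allele frequency of a SNP and the equivalent
#' sample size from [equivalent_n()], computes the marginal effect and
#' standard error on the liability scale:
#' \deqn{SE = \frac{1}{\sqrt{2 p (1-p) (N_{eq} + z^2)}}, \qquad b = z\,SE.}
#' The construction preserves `z = b/se` (and hence p-values) exactly.
#'
#' @param z marginal z-statistic(s).
#' @param freq effect-allele frequency in (0, 1).
#' @param neq equivalent sample size.
#' @return list with vectors `b` and `se`.
#' @export
convert_to_liability <- function(z, freq, neq) {
  if (any(freq <= 0 | freq >= 1)) stop("freq must be in (0, 1)")
  se <- 1 / sqrt(2 * freq * (1 - freq) * (neq + z^2))
  list(b = z * se, se = se)
}

#' Number of cases required for a target equivalent sample size
#'
#' Inverts [equivalent_n()]: the number of cases needed in a prospective
#' case-control study (with case proportion `v_prev`, default a balanced
#' design) to achieve the given equivalent quantitative-trait sample size.
#' The total sample is `n01 = (1 - K)^2 Neq / (i^2 v (1 - v))` and the case
#' count is `v * n01`; at `v = 0.5` this reduces to
#' `0.5 (1 - K)^2 Neq / (i^2 v (1 - v))`.
#'
#' @param neq target equivalent sample size.
#' @param k_prev population prevalence in (0, 1).
#' @param v_prev sample case proportion (default 0.5, balanced design).
#' @return number of cases.
#' @export
cases_required <- function(neq, k_prev, v_prev = 0.5) {
  if (k_prev <= 0 || k_prev >= 1) stop("k_prev must be in (0, 1)")
  if (v_prev <= 0 || v_prev >= 1) stop("v_prev must be in (0, 1)")
  i <- mean_liability(k_prev)
  n01 <- (1 - k_prev)^2 * neq / (i^2 * v_prev * (1 - v_prev))
  v_prev * n01
}

#' Rewrite case-control summary statistics on the liability scale
#'
#' Applies [equivalent_n()] and [convert_to_liability()] to a summary-
#' statistics table: `b` and `se` are replaced by their liability-scale
#' values and `N` by the equivalent sample size, so the result can be fed
#' to [gbmm()] like a quantitative-trait GWAS.
#'
#' @param sumstats data.frame from [read_ma()].
#' @param k_prev population prevalence.
#' @param n_cases,n_controls study case/control counts; if omitted, `n` is
#'   taken as the total and `v_prev` must be given.
#' @param v_prev sample case proportion (used when counts are not given).
#' @return the converted summary-statistics data.frame.
#' @export
liability_sumstats <- function(sumstats, k_prev, n_cases = NULL,
                               n_controls = NULL, v_prev = NULL) {
  if (!is.null(n_cases) && !is.null(n_controls)) {
    neq <- equivalent_n(k_prev, n_cases, n_controls)
  } else {
    neq <- equivalent_n(k_prev, v_prev = v_prev, n01 = sumstats$n)
  }
  conv <- convert_to_liability(sumstats$z, sumstats$freq, neq)
  out <- sumstats
  out$b <- conv$b
  out$se <- conv$se
  out$n <- round(neq)
  out$z <- out$b / out$se
  out
}
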