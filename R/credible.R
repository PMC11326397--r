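#' Construct LD-based local credible sets
#'
#' Builds alpha-level local credible sets (LCS): starting from the SNP with
#' the largest PIP, each "free" SNP (not yet in any set) seeds a candidate
#' set of free SNPs in high LD with it (`r^2 > r2_threshold`, within its LD
#' block); members are added in decreasing PIP order until the summed PIP
#' reaches `alpha`. A candidate set that reaches `alpha` consumes its
#' members; it is reported only if its posterior heritability-enrichment
#' probability (PEP) exceeds `pep_threshold`, i.e. if it explains more
#' SNP-based heritability than a random SNP set of the same size in more
#' than that fraction of posterior draws. Candidate sets that never reach
#' `alpha` release their members. Singleton sets are allowed.
#'
#' @param fit a [gbmm()] fit (supplies PIPs, effect draws and block LD).
#' @param alpha target coverage in (0, 1); default 0.9.
#' @param r2_threshold LD threshold defining the candidate set (default 0.5).
#' @param pep_threshold minimum PEP for reporting (default 0.7).
#' @param seed seed for the PEP random-set draws.
#' @return data.frame of reported sets with columns `set_id, block_id,
#'   n_snps, pip_sum, pep, phe, members` (comma-joined SNP ids), plus
#'   attribute `"sets"`: a list with the member indices of every reported
#'   set.
#' @export
build_lcs <- function(fit, alpha = 0.9, r2_threshold = 0.5,
                      pep_threshold = 0.7, seed = NULL) {
  stopifnot(inherits(fit, "gbmm_fit"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))

  pip <- fit$snp_res$pip
  pos <- fit$snp_res$pos
  m <- length(pip)
  beta_draws <- fit$samples$beta

  # block membership and within-block r2 (eigen-reconstructed)
  block_of <- integer(m)
  r2_mats <- vector("list", length(fit$ld$blocks))
  offset <- 0L
  for (i in seq_along(fit$ld$blocks)) {
    mb <- fit$ld$blocks[[i]]$basis$m_block
    block_of[offset + seq_len(mb)] <- i
    r2_mats[[i]] <- block_r2(fit$ld$blocks[[i]]$basis)
    offset <- offset + mb
  }
  block_start <- c(0L, cumsum(vapply(fit$ld$blocks,
                                     function(b) b$basis$m_block,
                                     integer(1))))

  free <- rep(TRUE, m)
  ord <- order(-pip, pos)
  out <- list()
  sets <- list()
  for (j in ord) {
    if (!free[j] || pip[j] <= 0) next
    b <- block_of[j]
    local <- j - block_start[b]
    cand_local <- which(r2_mats[[b]][local, ] > r2_threshold)
    cand <- cand_local + block_start[b]
    cand <- cand[free[cand]]
    cand <- cand[order(-pip[cand], pos[cand])]
    cum <- cumsum(pip[cand])
    if (cum[length(cum)] < alpha) next       # sub-threshold: release members
    members <- cand[seq_len(which(cum >= alpha)[1])]
    free[members] <- FALSE                    # consumed even if PEP fails
    pep <- compute_pep(members, beta_draws)
    if (pep <= pep_threshold) next
    phe <- estimate_phe(members, beta_draws)
    sets[[length(sets) + 1L]] <- members
    out[[length(out) + 1L]] <- data.frame(
      set_id = length(out) + 1L,
      block_id = fit$ld$blocks[[b]]$block_id,
      n_snps = length(members),
      pip_sum = sum(pip[members]),
      pep = pep,
      phe = phe,
      members = paste(fit$snp_res$snp[members], collapse = ","))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(set_id = integer(0), block_id = character(0),
               n_snps = integer(0), pip_sum = numeric(0), pep = numeric(0),
               phe = numeric(0), members = character(0))
  attr(res, "sets") <- sets
  res
}

#' Posterior heritability-enrichment probability of a SNP set
#'
#' For each retained posterior draw, compares the summed squared
#' standardized effects of the focal set against a freshly drawn uniform
#' random set of the same size; the PEP is the fraction of draws in which
#' the focal set strictly exceeds the random one.
#'
#' @param members SNP indices of the focal set.
#' @param beta_draws matrix of stored effect draws (draws x SNPs).
#' @return probability in \[0, 1\].
#' @export
compute_pep <- function(members, beta_draws) {
  m <- ncol(beta_draws)
  if (length(members) > m) stop("set larger than the SNP panel")
  n_draws <- nrow(beta_draws)
  focal <- rowSums(beta_draws[, members, drop = FALSE]^2)
  wins <- logical(n_draws)
  for (r in seq_len(n_draws)) {
    rnd <- sample.int(m, length(members))
    wins[r] <- focal[r] > sum(beta_draws[r, rnd]^2)
  }
  mean(wins)
}

#' Proportion of SNP-based heritability explained by a SNP set
#'
#' Per retained draw, the ratio of the set's summed squared standardized
#' effects to the genome-wide sum; the estimate is the mean over draws.
#' Draws with zero total genetic variance contribute 0.
#'
#' @inheritParams compute_pep
#' @return ratio in \[0, 1\].
#' @export
estimate_phe <- function(members, beta_draws) {
  if (length(members) == 0) return(0)
  total <- rowSums(beta_draws^2)
  focal <- rowSums(beta_draws[, members, drop = FALSE]^2)
  ratio <- ifelse(total > 0, focal / total, 0)
  mean(ratio)
}

#' Construct the global credible set
#'
#' The alpha-GCS is the smallest prefix of PIP-ranked SNPs whose cumulative
#' PIP reaches `alpha` times the estimated number of causal variants; it is
#' expected to contain that fraction of all causal variants. If the total
#' PIP mass falls short, all SNPs with positive PIP are returned and the
#' achieved coverage recorded.
#'
#' @param pip vector of PIPs (a `gbmm_fit` may be given instead).
#' @param m_c_hat estimated number of causal variants (defaults to the
#'   fit's `m_c` when a fit is supplied).
#' @param alpha target coverage.
#' @return list with `members` (SNP indices in rank order), `pip_sum`,
#'   `achieved_coverage`, `alpha`, `m_c_hat`.
#' @export
build_gcs <- function(pip, m_c_hat = NULL, alpha = 0.9) {
  if (inherits(pip, "gbmm_fit")) {
    if (is.null(m_c_hat)) m_c_hat <- pip$par_res$m_c
    pip <- pip$snp_res$pip
  }
  if (is.null(m_c_hat) || m_c_hat < 1) stop("m_c_hat must be >= 1")
  ord <- order(-pip)
  ord <- ord[pip[ord] > 0]
  cum <- cumsum(pip[ord])
  target <- alpha * m_c_hat
  if (length(cum) == 0 || cum[length(cum)] < target) {
    members <- ord
    achieved <- if (length(cum)) cum[length(cum)] / m_c_hat else 0
  } else {
    members <- ord[seq_len(which(cum >= target)[1])]
    achieved <- alpha
  }
  list(members = members, pip_sum = sum(pip[members]),
       achieved_coverage = achieved, alpha = alpha, m_c_hat = m_c_hat)
}

#' Estimate the true positive rate at a PIP threshold from the data
#'
#' The expected fraction of all causal variants discovered at PIP threshold
#' `alpha`: the summed PIPs of SNPs passing the threshold divided by the
#' expected causal count `M * pi_nonnull`.
#'
#' @param pip vector of PIPs.
#' @param alpha PIP threshold in (0, 1).
#' @param M number of SNPs in the panel.
#' @param pi_nonnull estimated proportion of SNPs with nonzero effects.
#' @return estimated TPR, clipped to \[0, 1\].
#' @export
estimate_tpr_given_data <- function(pip, alpha, M, pi_nonnull) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  denom <- M * pi_nonnull
  if (!is.finite(denom) || denom <= 0) {
    stop("M * pi_nonnull must be positive")
  }
  min(max(sum(pip[pip >= alpha]) / denom, 0), 1)
}
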