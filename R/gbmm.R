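#' Fit a genome-wide Bayesian mixture model to GWAS summary statistics
#'
#' Fits the low-rank summary-statistics mixture model by Gibbs sampling
#' within quasi-independent LD blocks. Two priors are available:
#'
#' * `"sbayesc"` — point-normal: `beta_j ~ pi N(0, sigma_b^2) + (1 - pi) d0`,
#'   with a free slab variance under a scaled inverse chi-squared prior and
#'   `pi ~ Uniform(0, 1)`.
#' * `"sbayesrc"` — multi-component: `beta_j ~ sum_k pi_k N(0, gamma_k
#'   sigma_g^2)` with prespecified ascending `gamma` (default
#'   `0, 1e-5, 1e-4, 1e-3, 1e-2`), optional per-SNP priors driven by
#'   functional annotations through a sequential probit link, and automatic
#'   pruning of superfluous small-effect components at MCMC checkpoints.
#'
#' Each retained draw records the component label of every SNP; the
#' posterior inclusion probability (PIP) of a SNP is the frequency of
#' non-null labels across retained draws.
#'
#' @param sumstats summary statistics from [read_ma()] (allele-scale marginal
#'   effects; aligned and standardized internally against `ld`).
#' @param ld an `ld_store` from [ld_store_from_genotypes()] /
#'   [ld_store_from_correlations()] / [load_ld_store()].
#' @param model `"sbayesc"` or `"sbayesrc"`.
#' @param annotations optional data.frame: first column SNP id, remaining
#'   columns annotation values (binary or continuous; continuous columns are
#'   standardized). Only used by `"sbayesrc"`.
#' @param gammas variance-scaling coefficients; first entry must be 0 and the
#'   rest strictly increasing. Defaults depend on `model`.
#' @param n_iter,burn_in,thin MCMC chain controls (defaults 10000 / 2000 /
#'   10; `thin` applies to stored effect draws only — PIPs and posterior
#'   means use every retained iteration).
#' @param seed integer seed for reproducibility.
#' @param auto_prune prune small-effect components at checkpoints (default:
#'   only for `"sbayesrc"`).
#' @param prune_check_every checkpoint interval in iterations (default 500).
#' @param random_order update SNPs in random order each sweep instead of
#'   genomic order.
#' @param fixed list to freeze hyperparameters (elements `pi`, `sigma_g2`,
#'   `sigma_e2`); used for oracle comparisons and power-law validation.
#' @return An object of class `gbmm_fit`; see Details.
#'
#' @details The returned object contains `snp_res` (per-SNP table: id,
#' position, alleles, PIP, posterior-mean effects on the standardized and
#' allele scales, component posterior probabilities), `par_res` (posterior
#' means of `pi`, `h2`, `sigma_g2`, `sigma_e2` and the estimated number of
#' causal variants `m_c`), `samples` (thinned standardized effect draws and
#' per-draw hyperparameters), the pruning history, and the LD store
#' reference used for credible-set construction.
#' @seealso [build_lcs()], [build_gcs()], [genetic_architecture()],
#'   [predict_power_phe()]
#' @export
gbmm <- function(sumstats, ld, model = c("sbayesc", "sbayesrc"),
                 annotations = NULL, gammas = NULL,
                 n_iter = 10000, burn_in = 2000, thin = 10, seed = NULL,
                 auto_prune = NULL, prune_check_every = 500,
                 random_order = FALSE, fixed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(ld, "ld_store"))
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (thin < 1) stop("thin must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (is.null(gammas)) {
    gammas <- if (model == "sbayesc") c(0, 1)
              else c(0, 1e-5, 1e-4, 1e-3, 1e-2)
  }
  if (gammas[1] != 0 || any(diff(gammas) <= 0)) {
    stop("gammas must start at 0 and be strictly increasing")
  }
  K <- length(gammas)
  if (is.null(auto_prune)) auto_prune <- model == "sbayesrc" && K > 2

  aligned <- standardize_effects(sumstats, ld$snps)
  if (nrow(aligned) < nrow(ld$snps)) {
    stop("summary statistics missing for ",
         nrow(ld$snps) - nrow(aligned), " LD-store SNPs; ",
         "fit requires complete alignment")
  }

  # per-block pseudo-data; n_block = median per-SNP n within block
  blocks <- ld$blocks
  w_list <- vector("list", length(blocks))
  Q_list <- vector("list", length(blocks))
  n_blk <- numeric(length(blocks))
  offset <- 0L
  for (i in seq_along(blocks)) {
    mb <- blocks[[i]]$basis$m_block
    rows <- offset + seq_len(mb)
    n_blk[i] <- stats::median(aligned$n[rows])
    pd <- build_pseudo_data(aligned$b_std[rows], n_blk[i], blocks[[i]]$basis)
    w_list[[i]] <- pd$w
    Q_list[[i]] <- pd$q_mat
    offset <- offset + mb
  }
  m <- offset

  use_annot <- model == "sbayesrc" && !is.null(annotations)
  A <- matrix(0, 0, 0)
  annot_names <- character(0)
  if (use_annot) {
    idx <- match(aligned$snp, as.character(annotations[[1]]))
    if (anyNA(idx)) stop("annotations missing for some model SNPs")
    A <- as.matrix(annotations[idx, -1, drop = FALSE])
    if (anyNA(A)) stop("annotations contain missing values")
    annot_names <- colnames(A)
    # standardize continuous columns; leave 0/1 indicators as they are
    for (cc in seq_len(ncol(A))) {
      v <- A[, cc]
      if (!all(v %in% c(0, 1)) && stats::sd(v) > 0) A[, cc] <- scale(v)[, 1]
    }
  }

  fixed_hyper <- !is.null(fixed)
  if (fixed_hyper) {
    stopifnot(all(c("pi", "sigma_g2", "sigma_e2") %in% names(fixed)))
    pi_init <- fixed$pi
    if (length(pi_init) != K) stop("fixed$pi must have length(gammas) entries")
    sigma_g2_init <- fixed$sigma_g2
    sigma_e2_init <- fixed$sigma_e2
    auto_prune <- FALSE
  } else {
    pi_init <- c(0.99, rep(0.01 / (K - 1), K - 1))
    sigma_e2_init <- 1
    # plug-in genetic-variance scale from the mean chi-square inflation
    h2_plug <- plugin_h2(aligned$z, aligned$n, m)
    sigma_g2_init <- if (model == "sbayesc") {
      max(h2_plug, 0.1) / max(0.01 * m, 1)   # slab variance scale
    } else {
      max(h2_plug, 0.1)
    }
  }

  res <- gibbs_gbmm_cpp(w_list, Q_list, n_blk, gammas, pi_init,
                        A, use_annot,
                        as.integer(n_iter), as.integer(burn_in),
                        as.integer(thin),
                        auto_prune, as.integer(prune_check_every),
                        fixed_hyper, sigma_e2_init, sigma_g2_init,
                        4.0, 1e-6, random_order)

  pip <- drop(res$pip)
  beta_std <- drop(res$beta_mean)
  # allele scale: beta_allele = beta_std / sd(x_j), sd(x_j) = sqrt(2 p (1-p))
  sd_x <- sqrt(2 * aligned$freq * (1 - aligned$freq))
  snp_res <- data.frame(
    snp = aligned$snp, chrom = ld$snps$chrom, pos = ld$snps$pos,
    a1 = aligned$a1, a2 = aligned$a2, freq = aligned$freq, n = aligned$n,
    pip = pip, beta_mean_std = beta_std, beta_mean_allele = beta_std / sd_x)
  comp_post <- res$comp_post
  colnames(comp_post) <- paste0("comp", seq_len(ncol(comp_post)))

  pi_hat <- colMeans(res$pi_draws)
  h2_hat <- mean(res$h2_draws)
  par_res <- list(
    model = model,
    pi = pi_hat,
    gammas = drop(res$gamma_final),
    sigma_g2 = mean(res$sigma_g2_draws),
    sigma_e2 = mean(res$sigma_e2_draws),
    h2 = h2_hat,
    m = m,
    m_c = round(m * (1 - pi_hat[1])),
    prune_history = data.frame(iteration = unlist(res$prune_iter),
                               gamma_removed = unlist(res$prune_gamma)))

  annot_eff <- NULL
  if (use_annot && nrow(res$theta_draws) > 0) {
    K_fin <- length(par_res$gammas)
    th <- array(t(res$theta_draws), dim = c(ncol(A) + 1, K_fin - 1,
                                            nrow(res$theta_draws)))
    mu <- apply(th, c(1, 2), mean)
    dimnames(mu) <- list(c("(Intercept)", annot_names),
                         paste0("stick", seq_len(K_fin - 1)))
    annot_eff <- list(mean = mu, draws = th)
  }

  structure(list(
    snp_res = snp_res,
    comp_post = comp_post,
    par_res = par_res,
    samples = list(beta = res$beta_draws,
                   h2 = drop(res$h2_draws),
                   sigma_e2 = drop(res$sigma_e2_draws),
                   sigma_g2 = drop(res$sigma_g2_draws),
                   pi = res$pi_draws),
    annotation_effects = annot_eff,
    ld = ld,
    config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                  seed = seed, n_retained = res$n_retained,
                  total_iter = res$total_iter)
  ), class = "gbmm_fit")
}

# Crude SNP-heritability plug-in from the mean chi-square inflation,
# E[chi2] ~ 1 + n h2 / m under polygenicity (no LD-score regression; LD is
# ignored). Used only to scale the sampler's initial state; burn-in absorbs it.
plugin_h2 <- function(z, n, m) {
  h2 <- (mean(z^2) - 1) / mean(n) * m
  min(max(h2, 0.01), 0.9)
}

#' @export
print.gbmm_fit <- function(x, ...) {
  p <- x$par_res
  cat(sprintf("<gbmm_fit> %s, %d SNPs, %d retained draws\n",
              toupper(p$model), p$m, x$config$n_retained))
  cat(sprintf("  h2 = %.3f, pi_nonnull = %.4g, m_c = %d\n",
              p$h2, 1 - p$pi[1], p$m_c))
  invisible(x)
}

#' @export
summary.gbmm_fit <- function(object, pip_threshold = 0.9, ...) {
  p <- object$par_res
  top <- object$snp_res[object$snp_res$pip >= pip_threshold, , drop = FALSE]
  top <- top[order(-top$pip), ]
  out <- list(model = p$model,
              m = p$m,
              h2 = p$h2,
              h2_sd = stats::sd(object$samples$h2),
              pi = p$pi,
              gammas = p$gammas,
              sigma_e2 = p$sigma_e2,
              m_c = p$m_c,
              pip_threshold = pip_threshold,
              n_significant = nrow(top),
              top_snps = utils::head(top, 10),
              prune_history = p$prune_history)
  class(out) <- "summary.gbmm_fit"
  out
}

#' @export
print.summary.gbmm_fit <- function(x, ...) {
  cat(sprintf("Genome-wide Bayesian mixture model (%s)\n", toupper(x$model)))
  cat(sprintf("  SNPs fitted:          %d\n", x$m))
  cat(sprintf("  SNP-heritability:     %.3f (posterior sd %.3f)\n",
              x$h2, x$h2_sd))
  cat(sprintf("  Non-null proportion:  %.4g\n", 1 - x$pi[1]))
  cat(sprintf("  Estimated causal SNPs: %d\n", x$m_c))
  cat(sprintf("  SNPs with PIP >= %.2f: %d\n", x$pip_threshold,
              x$n_significant))
  if (nrow(x$prune_history) > 0) {
    cat("  Pruned components (gamma):",
        paste(signif(x$prune_history$gamma_removed, 2), collapse = ", "), "\n")
  }
  if (nrow(x$top_snps) > 0) {
    cat("  Top SNPs:\n")
    print(x$top_snps[, c("snp", "chrom", "pos", "pip", "beta_mean_std")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Posterior-mean SNP effects
#'
#' @param object a `gbmm_fit`.
#' @param scale `"std"` (standardized genotype and phenotype) or `"allele"`
#'   (per effect-allele copy).
#' @param ... unused.
#' @return named numeric vector of posterior-mean joint effects.
#' @export
coef.gbmm_fit <- function(object, scale = c("std", "allele"), ...) {
  scale <- match.arg(scale)
  b <- if (scale == "std") object$snp_res$beta_mean_std
       else object$snp_res$beta_mean_allele
  stats::setNames(b, object$snp_res$snp)
}

#' Polygenic score prediction from a fitted model
#'
#' Scores genotypes with the posterior-mean allele-scale effects of SNPs
#' passing a PIP threshold.
#'
#' @param object a `gbmm_fit`.
#' @param newdata genotype matrix (individuals x SNPs, allele counts);
#'   columns either named by SNP id or aligned to the fit's SNP order.
#' @param pip_threshold only SNPs with `PIP >= pip_threshold` contribute
#'   (default 0 = all SNPs).
#' @param ... unused.
#' @return numeric vector of polygenic scores.
#' @export
predict.gbmm_fit <- function(object, newdata, pip_threshold = 0, ...) {
  beta <- object$snp_res$beta_mean_allele
  beta[object$snp_res$pip < pip_threshold] <- 0
  if (!is.null(colnames(newdata))) {
    idx <- match(object$snp_res$snp, colnames(newdata))
    if (anyNA(idx)) stop("newdata is missing some model SNPs")
    newdata <- newdata[, idx, drop = FALSE]
  } else if (ncol(newdata) != nrow(object$snp_res)) {
    stop("newdata has ", ncol(newdata), " columns; expected ",
         nrow(object$snp_res))
  }
  drop(as.matrix(newdata) %*% beta)
}

#' Plot PIPs along the genome
#'
#' @param x a `gbmm_fit`.
#' @param threshold horizontal reference line (default 0.9).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gbmm_fit <- function(x, threshold = 0.9, ...) {
  sr <- x$snp_res
  graphics::plot(seq_len(nrow(sr)), sr$pip, pch = 16, cex = 0.4,
                 xlab = "SNP index (genomic order)",
                 ylab = "Posterior inclusion probability",
                 ylim = c(0, 1), ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  invisible(x)
}
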