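test_that("snp_component_probs reduces to the prior and handles r = 0", {
  gam <- c(0, 1e-4, 1e-2)
  out <- snp_component_probs(r = 3, n = 1e4, sigma_e2 = 1, sigma_g2 = 0.5,
                             pi = c(1, 0, 0), gammas = gam)
  expect_equal(out$comp_prob, c(1, 0, 0))

  out0 <- snp_component_probs(r = 0, n = 1e4, sigma_e2 = 1, sigma_g2 = 0.5,
                              pi = c(0.9, 0.05, 0.05), gammas = gam)
  expect_equal(sum(out0$comp_prob), 1)
  expect_gt(out0$comp_prob[1], 0.9)   # null favored at r = 0
  expect_error(snp_component_probs(NaN, 1e4, 1, 0.5, c(0.9, 0.1), c(0, 1)),
               "finite")
})

test_that("component probability matches the closed-form single-SNP posterior", {
  # K = 2, m = 1, full rank: exact Bernoulli posterior from marginal likelihoods
  n <- 5000; se2 <- 0.8; sb2 <- 0.002; pi1 <- 0.9
  for (b_std in c(0, 0.01, 0.04, -0.06)) {
    w <- sqrt(n) * b_std
    f0 <- stats::dnorm(w, 0, sqrt(se2))
    f1 <- stats::dnorm(w, 0, sqrt(se2 + n * sb2))
    exact <- (1 - pi1) * f1 / ((1 - pi1) * f1 + pi1 * f0)
    r <- n * b_std
    got <- snp_component_probs(r, n, se2, sb2, c(pi1, 1 - pi1), c(0, 1))
    expect_lt(abs(got$comp_prob[2] - exact), 1e-10)
  }
})

test_that("MCMC PIPs agree with the exhaustive-enumeration oracle", {
  set.seed(7)
  R <- matrix(c(1, .6, .3, .6, 1, .5, .3, .5, 1), 3, 3)
  n <- 5000; pi0 <- 0.1; sb2 <- 0.001
  b_std <- c(0.04, 0.035, 0.01)
  ex <- exact_posterior_small(b_std, R, n, pi0, sb2, 1)
  expect_equal(sum(ex$config_prob), 1, tolerance = 1e-12)
  ss <- ma_from_bstd(b_std, n)
  ld <- one_block_store(R)
  fit <- gbmm(ss, ld, model = "sbayesc", n_iter = 52000, burn_in = 2000,
              seed = 9, fixed = list(pi = c(1 - pi0, pi0), sigma_g2 = sb2,
                                     sigma_e2 = 1))
  expect_lt(max(abs(ex$pip - fit$snp_res$pip)), 0.02)
})

test_that("exact posterior is symmetric for identical columns and null-favoring", {
  # m = 2 identical columns: PIPs equal by exchangeability
  R <- matrix(c(1, 1, 1, 1), 2, 2)
  ex <- exact_posterior_small(c(0.05, 0.05), R, 4000, 0.05, 0.002, 1)
  expect_equal(ex$pip[1], ex$pip[2], tolerance = 1e-12)
  # m = 1, b = 0, large n: data favor the null, PIP < prior
  ex1 <- exact_posterior_small(0, matrix(1), 50000, 0.2, 0.002, 1)
  expect_lt(ex1$pip, 0.2)
  expect_error(exact_posterior_small(rep(0, 13), diag(13), 100, .1, .1, 1),
               "m <= 12")
})

test_that("the sampler is deterministic given a seed", {
  run <- small_sparse_run()
  fit2 <- gbmm(run$sim$sumstats, run$sim$ld, model = "sbayesc",
               n_iter = 4000, burn_in = 1000, seed = 72)
  expect_identical(fit2$snp_res$pip, run$fit$snp_res$pip)
  expect_identical(fit2$samples$beta, run$fit$samples$beta)
})

test_that("pure-noise phenotype yields near-null PIPs and tiny h2", {
  cfg <- sim_config(m = 500, n = 4000, block_size = 50, h2 = 0, seed = 55)
  sim <- simulate_gwas(cfg, keep_genotypes = FALSE)
  fit <- gbmm(sim$sumstats, sim$ld, model = "sbayesc",
              n_iter = 3000, burn_in = 1000, seed = 56)
  expect_lt(mean(fit$snp_res$pip), 2 * (1 - fit$par_res$pi[1]) + 0.01)
  expect_lt(fit$par_res$h2, 0.05)
})

test_that("duplicated-SNP block keeps exactly one of the pair non-null per draw", {
  set.seed(91)
  # strong causal among two perfectly correlated SNPs; fixed hyperparameters
  n <- 10000; b_std <- c(0.08, 0.08)
  ss <- ma_from_bstd(b_std, n)
  ld <- one_block_store(matrix(1, 2, 2))
  fit <- gbmm(ss, ld, model = "sbayesc", n_iter = 6000, burn_in = 1000,
              seed = 92, thin = 1,
              fixed = list(pi = c(0.99, 0.01), sigma_g2 = 0.005,
                           sigma_e2 = 1))
  draws <- fit$samples$beta != 0
  n_active <- rowSums(draws)
  expect_gt(mean(n_active == 1), 0.9)   # one of the pair in most draws
  expect_lt(mean(n_active == 2), 0.1)   # rarely both
  # with thin = 1 the PIP running count and the stored draws coincide
  expect_equal(sum(fit$snp_res$pip), mean(n_active), tolerance = 1e-9)
})

test_that("mixture config validation and chain bookkeeping", {
  run <- small_sparse_run()
  expect_error(gbmm(run$sim$sumstats, run$sim$ld, n_iter = 100,
                    burn_in = 200), "burn_in")
  expect_error(gbmm(run$sim$sumstats, run$sim$ld, gammas = c(0.1, 1)),
               "gammas")
  # PIP bounded, h2 draws bounded, retained count as configured
  expect_true(all(run$fit$snp_res$pip >= 0 & run$fit$snp_res$pip <= 1))
  expect_true(all(run$fit$samples$h2 >= 0 & run$fit$samples$h2 <= 1))
  expect_equal(run$fit$config$n_retained, 3000)
})

test_that("auto-pruning drops a spurious small-effect component", {
  # rule on given variance shares
  dec <- auto_prune_components(c(0, 1e-5, 1e-4, 1e-3, 1e-2),
                               c(0, 0.004, 0.010, 0.30, 0.50))
  expect_equal(dec$removed, 1e-5)
  # boundary: exactly half is retained (strict rule)
  dec2 <- auto_prune_components(c(0, 1e-4, 1e-3), c(0, 0.005, 0.010))
  expect_null(dec2$removed)
  # comparable shares: unchanged
  dec3 <- auto_prune_components(c(0, 1e-4, 1e-3), c(0, 0.3, 0.35))
  expect_null(dec3$removed)
  # K = 2 never reduced
  dec4 <- auto_prune_components(c(0, 1e-2), c(0, 0.001))
  expect_null(dec4$removed)

  # in the sampler: well-powered single-scale data fitted with five
  # components sheds superfluous small-gamma components at checkpoints
  cfg <- sim_config(m = 1000, n = 10000, block_size = 50,
                    prop_causal = 0.005, h2 = 0.4, seed = 81)
  sim <- simulate_gwas(cfg, keep_genotypes = FALSE)
  fit_rc <- gbmm(sim$sumstats, sim$ld, model = "sbayesrc",
                 n_iter = 3000, burn_in = 1000, seed = 82)
  expect_lt(length(fit_rc$par_res$gammas), 5)
  expect_gt(nrow(fit_rc$par_res$prune_history), 0)
  # burn-in restarted after the last removal
  last_prune <- max(fit_rc$par_res$prune_history$iteration)
  expect_gte(fit_rc$config$total_iter, last_prune + 1000 + 2000)
})

test_that("annotation-aware fit recovers an enrichment and behaves monotonically", {
  # probit stick monotonicity: larger annotation value with positive alpha
  # never lowers the non-null prior mass
  A <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  pi_mat <- probit_mixture_priors(A, mu = c(-1, 0), alpha = rbind(c(0.8, 0)))
  expect_true(all(diff(1 - pi_mat[, 1]) > 0))
  expect_equal(rowSums(pi_mat), rep(1, 9))
  # alpha = 0: identical priors across SNPs
  pi0 <- probit_mixture_priors(A, mu = c(-1, 0), alpha = rbind(c(0, 0)))
  expect_equal(max(apply(pi0, 2, stats::sd)), 0)

  # enrichment recovery: causals concentrated in an annotated quarter
  set.seed(61)
  m <- 2000; n <- 6000
  cfg <- sim_config(m = m, n = n, block_size = 50, prop_causal = 0.02,
                    h2 = 0.4, seed = 62)
  g <- simulate_genotypes(cfg)
  annot_set <- sort(sample.int(m, m / 4))
  causal <- sort(c(sample(annot_set, 32), sample(setdiff(1:m, annot_set), 8)))
  beta <- numeric(m); beta[causal] <- stats::rnorm(40, 0, sqrt(0.4 / 40))
  gval <- drop(scale(g$X[, causal]) %*% beta[causal])
  y <- gval + stats::rnorm(n, 0, sqrt(stats::var(gval) * (1 / 0.4 - 1)))
  ss <- run_gwas(g, y)
  ld <- ld_store_from_genotypes(g$X, g$snps, g$blocks)
  annot <- data.frame(snp = g$snps$snp,
                      in_set = as.integer(seq_len(m) %in% annot_set))
  fit <- gbmm(ss, ld, model = "sbayesrc", annotations = annot,
              gammas = c(0, 1e-3, 1e-2), auto_prune = FALSE,
              n_iter = 4000, burn_in = 1000, seed = 63)
  a_draws <- fit$annotation_effects$draws[2, 1, ]  # annotation, first stick
  expect_gt(mean(a_draws > 0), 0.9)
})
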