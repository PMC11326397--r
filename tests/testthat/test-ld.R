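test_that("eigendecompose_block handles identity, rank-1 and trace cases", {
  b <- eigendecompose_block(diag(3), variance_fraction = 1)
  expect_equal(b$values, rep(1, 3))
  expect_equal(b$q, 3L)

  R <- matrix(c(1, 1, 1, 1), 2, 2)
  b1 <- eigendecompose_block(R, variance_fraction = 0.5)
  b2 <- eigendecompose_block(R, variance_fraction = 1)
  expect_equal(b1$q, 1L)
  expect_equal(b2$q, 1L)           # rank-1: q = 1 for any fraction <= 1
  expect_equal(b2$values, 2)

  set.seed(3)
  X <- matrix(rnorm(200 * 5), 200, 5)
  R5 <- stats::cor(X %*% matrix(rnorm(25), 5, 5))
  b5 <- eigendecompose_block(R5, variance_fraction = 0.9)
  expect_equal(sum(b5$all_values), 5, tolerance = 1e-8)  # trace conserved
  expect_equal(crossprod(b5$vectors), diag(b5$q), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("eigendecompose_block validates its input", {
  M <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(eigendecompose_block(M), "symmetric")
  D <- diag(c(1, 2))
  expect_error(eigendecompose_block(D), "unit diagonal")
  expect_error(eigendecompose_block(diag(2), variance_fraction = 0), "variance_fraction")
})

test_that("build_pseudo_data validates and handles trivial blocks", {
  basis <- eigendecompose_block(diag(1), 1)
  pd <- build_pseudo_data(0, 100, basis)
  expect_equal(pd$w, 0)
  expect_error(build_pseudo_data(c(0, 0), 100, basis), "does not match")
  expect_error(build_pseudo_data(0, 1, basis), "n_block")
  # zero retained eigenvalue refuses to invert
  b2 <- eigendecompose_block(matrix(c(1, 1, 1, 1), 2, 2), 1)
  b2$values <- c(2, 0); b2$vectors <- cbind(b2$vectors, c(1, -1) / sqrt(2))
  b2$q <- 2L
  expect_error(build_pseudo_data(c(0.1, 0.1), 100, b2), "eigenvalue")
})

test_that("pseudo-data matches the individual-level projection at full rank", {
  set.seed(9)
  n <- 3000; mb <- 8
  cfg <- sim_config(m = mb, n = n, block_size = mb, ld_rho = 0.6,
                    h2 = 0.3, prop_causal = 2 / mb, seed = 13)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  ss <- run_gwas(g, ph$y)
  Xs <- scale(g$X)
  ys <- drop(scale(ph$y))
  R <- stats::cor(g$X)
  basis <- eigendecompose_block(R, variance_fraction = 1)
  b_std <- ss$z / sqrt(ss$z^2 + n - 2)
  pd <- build_pseudo_data(b_std, n, basis)
  # oracle: w = Lambda^{-1/2} U' Xs' ys / sqrt(n); sample correlations carry
  # an n/(n-1) convention factor relative to the crossproduct
  w_direct <- drop(crossprod(basis$vectors, crossprod(Xs, ys)) /
                     sqrt(basis$values)) / sqrt(n) * (n / (n - 1))
  expect_lt(max(abs(pd$w - w_direct)), 1e-6)
  # Q'Q reconstructs n R on the retained basis
  expect_lt(max(abs(crossprod(pd$q_mat) - n * R)), 1e-6)
})

test_that("truncated reconstruction error is bounded by the discarded mass", {
  set.seed(10)
  cfg <- sim_config(m = 30, n = 800, block_size = 30, ld_rho = 0.9,
                    prop_causal = 1 / 30, seed = 21)
  g <- simulate_genotypes(cfg)
  R <- stats::cor(g$X)
  basis <- eigendecompose_block(R, variance_fraction = 0.9)
  pd <- build_pseudo_data(rep(0.01, 30), 800, basis)
  frob_rel <- norm(crossprod(pd$q_mat) - 800 * R, "F") / norm(800 * R, "F")
  expect_lt(frob_rel, (1 - basis$variance_fraction_kept) + 1e-8)
})

test_that("projection contract: residual sd matches the model residual", {
  # with variance_fraction 1 on full-rank blocks, w = Q beta_true + eps with
  # per-element var(eps) ~ residual variance on the standardized-y scale
  mse <- vapply(1:20, function(s) {
    cfg <- sim_config(m = 40, n = 2000, block_size = 40, ld_rho = 0.5,
                      h2 = 0.2, prop_causal = 0.1, seed = 100 + s)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotype(g, cfg)
    ss <- run_gwas(g, ph$y)
    basis <- eigendecompose_block(stats::cor(g$X), 1)
    b_std <- ss$z / sqrt(ss$z^2 + cfg$n - 2)
    pd <- build_pseudo_data(b_std, cfg$n, basis)
    bt <- ph$truth$beta_std / stats::sd(ph$y)   # std-y scale truth
    eps <- pd$w - drop(pd$q_mat %*% bt)
    mean(eps^2)
  }, numeric(1))
  expect_lt(abs(mean(mse) - 0.8), 0.1 * 0.8 + 2 * stats::sd(mse) / sqrt(20))
})

test_that("ld store assembles blocks, saves and loads", {
  cfg <- sim_config(m = 60, n = 400, block_size = 20, seed = 31)
  g <- simulate_genotypes(cfg)
  store <- ld_store_from_genotypes(g$X, g$snps, g$blocks)
  expect_s3_class(store, "ld_store")
  expect_length(store$blocks, 3)
  expect_equal(nrow(store$snps), 60)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ld_store(store, path)
  back <- load_ld_store(path)
  expect_equal(back$blocks[[2]]$basis$values, store$blocks[[2]]$basis$values)
})
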