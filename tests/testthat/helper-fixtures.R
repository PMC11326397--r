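# Shared fixtures, all generated in code. Heavy objects are memoized in
# `.fixture_cache` so multiple test files can reuse one simulation/fit.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# summary-statistics data.frame with a given standardized effect vector
ma_from_bstd <- function(b_std, n, snp = sprintf("s%d", seq_along(b_std)),
                         freq = rep(0.3, length(b_std))) {
  z <- b_std * sqrt((n - 2) / pmax(1 - b_std^2, 1e-12))
  data.frame(snp = snp, a1 = "A", a2 = "G", freq = freq, b = z, se = 1,
             p = pmax(2 * stats::pnorm(-abs(z)), 1e-300), n = n, z = z)
}

one_block_store <- function(R, variance_fraction = 1,
                            snp = sprintf("s%d", seq_len(nrow(R)))) {
  snps <- data.frame(snp = snp, chrom = "1", pos = seq_len(nrow(R)) * 1000,
                     a1 = "A", a2 = "G")
  ld_store_from_correlations(list(R), list(snps), variance_fraction)
}

# moderate sparse simulation + SBayesC fit, shared across test files
small_sparse_run <- function() {
  memo("small_sparse", {
    cfg <- sim_config(m = 1000, n = 4000, block_size = 50,
                      prop_causal = 0.01, seed = 71)
    sim <- simulate_gwas(cfg)
    fit <- gbmm(sim$sumstats, sim$ld, model = "sbayesc",
                n_iter = 4000, burn_in = 1000, seed = 72)
    list(cfg = cfg, sim = sim, fit = fit)
  })
}

# full desk-scale sparse replicates (generator defaults) fitted with SBayesC;
# shared by the parameter-recovery, calibration, coverage and TPR checks
sparse_recovery_runs <- function(n_seeds = 5) {
  memo(paste0("sparse_recovery_", n_seeds), {
    lapply(seq_len(n_seeds), function(s) {
      cfg <- sim_config(seed = 1000 + s)
      sim <- simulate_gwas(cfg, keep_genotypes = FALSE)
      fit <- gbmm(sim$sumstats, sim$ld, model = "sbayesc", seed = 2000 + s)
      list(truth = sim$truth, fit = fit, m = cfg$m)
    })
  })
}

# perfect-LD pair replicate: two duplicated-column SNPs, the first causal
# (v = 0.005 at n = 10,000), on a null background; random-order scan avoids
# the sequential sweep's labelling advantage under exact collinearity
pair_pip <- function(seed, n = 10000, m_bg = 100, v = 0.005) {
  set.seed(seed)
  cfg <- sim_config(m = m_bg, n = n, block_size = 50, h2 = 0, seed = seed)
  g <- simulate_genotypes(cfg)
  x <- stats::rbinom(n, 1, 0.3) + stats::rbinom(n, 1, 0.3)
  X <- cbind(x, x, g$X)
  snps <- rbind(data.frame(snp = c("dup1", "dup2"), chrom = "1",
                           pos = c(100, 200), a1 = "A", a2 = "G", maf = 0.3),
                transform(g$snps, pos = pos + 1000))
  blocks <- rbind(data.frame(block_id = "blk_pair", chrom = "1",
                             start_bp = 1, end_bp = 999),
                  transform(g$blocks, start_bp = start_bp + 1000,
                            end_bp = end_bp + 1000))
  y <- drop(scale(x)) * sqrt(v) + stats::rnorm(n, 0, sqrt(1 - v))
  geno <- list(X = X, snps = snps, blocks = blocks)
  ss <- run_gwas(geno, y)
  ld <- ld_store_from_genotypes(X, snps, blocks)
  fit <- gbmm(ss, ld, model = "sbayesc", seed = seed, random_order = TRUE)
  fit$snp_res$pip[1:2]
}
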