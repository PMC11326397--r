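#' Simulation configuration for blockwise-LD GWAS data
#'
#' Defines the generative conditions for the package's synthetic cohorts:
#' blockwise-LD genotypes with a MAF spectrum, a complex-trait phenotype
#' under one of three genetic architectures, and marginal-regression GWAS
#' summary statistics.
#'
#' Architectures:
#' * `"sparse"` — a fraction `prop_causal` of SNPs is causal, with effects
#'   `N(0, h2/m_c)` on the standardized-genotype scale.
#' * `"large_effects"` — `n_large` designated SNPs carry effects
#'   `N(0, var_large/n_large)` (jointly contributing `var_large` of
#'   phenotypic variance) and the remaining causal SNPs carry
#'   `N(0, (h2 - var_large)/(m_c - n_large))`.
#' * `"ldms"` — as sparse, but causal variants are drawn only from the
#'   high-LD, high-MAF quartile group (median splits of within-block LD
#'   score and MAF).
#'
#' The residual variance is set to `var(g) (1/h2 - 1)` so the genetic
#' variance share equals `h2` in expectation.
#'
#' @param m number of SNPs (default 5000).
#' @param n number of individuals (default 10000).
#' @param block_size SNPs per LD block (default 100).
#' @param ld_rho AR(1) adjacent-SNP latent correlation; a single value, or a
#'   range from which each block's level is drawn (default `c(0.5, 0.95)`).
#' @param maf_range per-SNP MAF is drawn uniformly from this range (default
#'   `c(0.01, 0.5)`).
#' @param architecture `"sparse"`, `"large_effects"` or `"ldms"`.
#' @param h2 target SNP-based heritability (default 0.5).
#' @param prop_causal causal fraction (default 0.01).
#' @param n_large number of designated large-effect SNPs (default 10).
#' @param var_large phenotypic-variance share of the large-effect set
#'   (default `0.2 * h2`).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m = 5000, n = 10000, block_size = 100,
                       ld_rho = c(0.5, 0.95), maf_range = c(0.01, 0.5),
                       architecture = c("sparse", "large_effects", "ldms"),
                       h2 = 0.5, prop_causal = 0.01, n_large = 10,
                       var_large = 0.2 * h2, seed = NULL) {
  architecture <- match.arg(architecture)
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5] with min <= max")
  }
  m_c <- round(prop_causal * m)
  if (h2 > 0 && m_c < 1) stop("prop_causal * m must be >= 1")
  if (architecture == "large_effects") {
    if (m_c <= n_large) stop("need more causal SNPs than large-effect SNPs")
    if (var_large >= h2) stop("var_large must be below h2")
  }
  structure(list(m = m, n = n, block_size = block_size, ld_rho = ld_rho,
                 maf_range = maf_range, architecture = architecture,
                 h2 = h2, prop_causal = prop_causal, m_c = m_c,
                 n_large = n_large, var_large = var_large, seed = seed),
            class = "sim_config")
}

#' Simulate blockwise-LD genotypes
#'
#' Generates 0/1/2 genotypes with AR(1)-decaying LD inside independent
#' blocks: per block, each individual receives two latent AR(1) Gaussian
#' haplotypes, thresholded at `qnorm(maf_j)` and summed, so the allele
#' frequency of the counted allele equals the configured MAF and adjacent-
#' SNP correlation follows the (tetrachorically attenuated) AR(1) level.
#'
#' @param config a [sim_config()].
#' @return list with `X` (n x m genotype matrix), `snps` (SNP metadata:
#'   `snp, chrom, pos, a1, a2, maf`), `blocks` (block definition table),
#'   and `block_rho` (the per-block AR(1) level used).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- config$m; n <- config$n; bs <- config$block_size
  n_blocks <- ceiling(m / bs)
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  rho <- if (length(config$ld_rho) == 2) {
    stats::runif(n_blocks, config$ld_rho[1], config$ld_rho[2])
  } else rep(config$ld_rho, n_blocks)

  X <- matrix(0L, n, m)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1) * bs + 1):min(b * bs, m)
    mb <- length(cols)
    thr <- stats::qnorm(maf[cols])
    G <- matrix(0L, n, mb)
    for (hap in 1:2) {
      Z <- matrix(stats::rnorm(n * mb), n, mb)
      if (mb > 1) {
        for (j in 2:mb) {
          Z[, j] <- rho[b] * Z[, j - 1] + sqrt(1 - rho[b]^2) * Z[, j]
        }
      }
      G <- G + (Z < rep(thr, each = n))
    }
    X[, cols] <- G
  }
  pos <- seq_len(m) * 1000L
  snps <- data.frame(snp = sprintf("rs%06d", seq_len(m)),
                     chrom = "1", pos = pos,
                     a1 = "A", a2 = "G", maf = maf)
  blocks <- data.frame(
    block_id = sprintf("blk_%03d", seq_len(n_blocks)),
    chrom = "1",
    start_bp = (seq_len(n_blocks) - 1) * bs * 1000L + 1000L,
    end_bp = pmin(seq_len(n_blocks) * bs, m) * 1000L)
  list(X = X, snps = snps, blocks = blocks, block_rho = rho)
}

#' Simulate a complex-trait phenotype
#'
#' Draws causal variants and standardized-scale effects under the
#' configured architecture and returns the phenotype along with the ground
#' truth used by the evaluation metrics.
#'
#' @param geno output of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `y` (phenotype vector) and `truth`: a list holding
#'   `causal_idx`, `beta_std` (standardized-scale effects, full length),
#'   `large_idx` (large-effects architecture only), `architecture`,
#'   `realized_h2`, and `var_share_large` (realized phenotypic-variance
#'   share of the designated large-effect set).
#' @export
simulate_phenotype <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m; n <- config$n
  X <- geno$X
  beta <- numeric(m)
  large_idx <- integer(0)

  if (config$h2 == 0) {
    y <- stats::rnorm(n)
    truth <- list(causal_idx = integer(0), beta_std = beta,
                  large_idx = large_idx,
                  architecture = config$architecture,
                  realized_h2 = 0, var_share_large = 0)
    return(list(y = y, truth = truth))
  }

  m_c <- config$m_c
  if (config$architecture == "ldms") {
    grp <- ldms_groups(geno)
    eligible <- which(grp$high_ld & grp$high_maf)
    if (length(eligible) < m_c) {
      stop("fewer eligible high-LD/high-MAF SNPs than causal count")
    }
    causal <- sort(sample(eligible, m_c))
    beta[causal] <- stats::rnorm(m_c, 0, sqrt(config$h2 / m_c))
  } else if (config$architecture == "large_effects") {
    causal <- sort(sample.int(m, m_c))
    large_idx <- sort(sample(causal, config$n_large))
    small_idx <- setdiff(causal, large_idx)
    beta[large_idx] <- stats::rnorm(config$n_large, 0,
                                    sqrt(config$var_large / config$n_large))
    beta[small_idx] <- stats::rnorm(length(small_idx), 0,
                                    sqrt((config$h2 - config$var_large) /
                                           length(small_idx)))
    causal <- sort(causal)
  } else {
    causal <- sort(sample.int(m, m_c))
    beta[causal] <- stats::rnorm(m_c, 0, sqrt(config$h2 / m_c))
  }

  Xc <- scale(X[, causal, drop = FALSE])
  bad <- !is.finite(colSums(Xc))
  if (any(bad)) Xc[, bad] <- 0  # monomorphic guard
  g <- drop(Xc %*% beta[causal])
  var_g <- stats::var(g)
  e <- stats::rnorm(n, 0, sqrt(var_g * (1 / config$h2 - 1)))
  y <- g + e

  var_share_large <- if (length(large_idx) > 0) {
    gl <- drop(scale(X[, large_idx, drop = FALSE]) %*% beta[large_idx])
    stats::var(gl) / stats::var(y)
  } else 0

  truth <- list(causal_idx = causal, beta_std = beta, large_idx = large_idx,
                architecture = config$architecture,
                realized_h2 = var_g / stats::var(y),
                var_share_large = var_share_large)
  list(y = y, truth = truth)
}

#' Marginal-regression GWAS on simulated data
#'
#' Runs the standard per-SNP simple linear regression of the (centered)
#' phenotype on each (centered) genotype and emits summary statistics in
#' ".ma" layout. Monomorphic SNPs get a variance floor and are flagged in
#' the `monomorphic` attribute.
#'
#' @param geno output of [simulate_genotypes()].
#' @param y phenotype vector.
#' @return summary-statistics data.frame (`snp, a1, a2, freq, b, se, p, n,
#'   z`), directly writable with [write_ma()].
#' @export
run_gwas <- function(geno, y) {
  X <- geno$X
  n <- nrow(X)
  stopifnot(length(y) == n)
  yc <- y - mean(y)
  xm <- colMeans(X)
  sxx <- colSums(X^2) - n * xm^2
  mono <- sxx < .Machine$double.eps
  sxx_f <- pmax(sxx, 1e-8)                     # variance floor
  sxy <- drop(crossprod(X, yc))                # colSums already centered in y
  b <- sxy / sxx_f
  sse <- pmax(sum(yc^2) - b^2 * sxx_f, 0)
  se <- sqrt(sse / (n - 2) / sxx_f)
  se[mono] <- sqrt(sum(yc^2) / (n - 2) / 1e-8)
  b[mono] <- 0
  z <- b / se
  out <- data.frame(snp = geno$snps$snp, a1 = geno$snps$a1,
                    a2 = geno$snps$a2, freq = xm / 2,
                    b = b, se = se,
                    p = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
                    n = n, z = z)
  attr(out, "monomorphic") <- which(mono)
  out
}

# Within-block LD score (sum of r^2 to all block members, self included)
# and MAF, median-split into a 2x2 group indicator.
ldms_groups <- function(geno) {
  m <- ncol(geno$X)
  ld_score <- numeric(m)
  for (b in unique(geno$blocks$block_id)) {
    brow <- geno$blocks[geno$blocks$block_id == b, ]
    cols <- which(geno$snps$pos >= brow$start_bp &
                  geno$snps$pos <= brow$end_bp &
                  geno$snps$chrom == brow$chrom)
    R <- block_cor(geno$X[, cols, drop = FALSE])
    ld_score[cols] <- rowSums(R^2)
  }
  maf <- pmin(colMeans(geno$X) / 2, 1 - colMeans(geno$X) / 2)
  list(ld_score = ld_score, maf = maf,
       high_ld = ld_score > stats::median(ld_score),
       high_maf = maf > stats::median(maf))
}

#' LD/MAF group annotations
#'
#' Partitions SNPs into the four LD-score-by-MAF groups defined by median
#' splits (LD score summed within block) and returns binary indicator
#' annotations, one column per group; every SNP falls in exactly one group.
#'
#' @param geno output of [simulate_genotypes()].
#' @return data.frame: first column `snp`, then indicator columns
#'   `lowLD_lowMAF, lowLD_highMAF, highLD_lowMAF, highLD_highMAF`.
#' @export
make_ldms_annotations <- function(geno) {
  grp <- ldms_groups(geno)
  data.frame(snp = geno$snps$snp,
             lowLD_lowMAF = as.integer(!grp$high_ld & !grp$high_maf),
             lowLD_highMAF = as.integer(!grp$high_ld & grp$high_maf),
             highLD_lowMAF = as.integer(grp$high_ld & !grp$high_maf),
             highLD_highMAF = as.integer(grp$high_ld & grp$high_maf))
}

#' One-call synthetic GWAS: genotypes, phenotype, summary stats, LD store
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_phenotype()], [run_gwas()] and [ld_store_from_genotypes()].
#'
#' @param config a [sim_config()].
#' @param variance_fraction eigenbasis truncation for the LD store.
#' @param keep_genotypes keep the genotype matrix in the result (default
#'   TRUE; set FALSE to save memory).
#' @return list with `sumstats`, `ld`, `truth`, `y`, `config`, and
#'   optionally `geno`.
#' @export
simulate_gwas <- function(config, variance_fraction = 0.995,
                          keep_genotypes = TRUE) {
  geno <- simulate_genotypes(config)
  ph <- simulate_phenotype(geno, config)
  ss <- run_gwas(geno, ph$y)
  ld <- ld_store_from_genotypes(geno$X, geno$snps, geno$blocks,
                                variance_fraction)
  out <- list(sumstats = ss, ld = ld, truth = ph$truth, y = ph$y,
              config = config)
  if (keep_genotypes) out$geno <- geno
  out
}
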