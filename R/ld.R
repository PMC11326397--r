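#' Low-rank eigendecomposition of an LD correlation matrix
#'
#' Decomposes a within-block LD correlation matrix `R = U diag(L) U'` and
#' retains the smallest number of leading eigenpairs whose cumulative
#' eigenvalue sum reaches `variance_fraction` of the trace (the trace of a
#' correlation matrix equals the SNP count). Negative eigenvalues, which can
#' arise from sampling noise in an LD reference, are clamped to zero before
#' selection.
#'
#' @param R symmetric correlation matrix with unit diagonal (tolerance 1e-6).
#' @param variance_fraction fraction of LD variation to retain, in (0, 1].
#'   The default 0.995 follows the low-rank summary-statistics model lineage
#'   and is robust to reference noise.
#' @return An object of class `eigen_basis`: list with `values` (retained
#'   eigenvalues, descending), `vectors` (m x q orthonormal columns),
#'   `variance_fraction_kept` (achieved fraction), `m_block`, `q`, and
#'   `all_values` (full clamped spectrum, for trace checks).
#' @export
eigendecompose_block <- function(R, variance_fraction = 0.995) {
  R <- as.matrix(R)
  m <- nrow(R)
  if (ncol(R) != m) stop("R must be square")
  if (max(abs(R - t(R))) > 1e-6) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-6) stop("R must have unit diagonal")
  if (!is.numeric(variance_fraction) || variance_fraction <= 0 ||
      variance_fraction > 1) {
    stop("variance_fraction must be in (0, 1]")
  }
  eig <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  cum <- cumsum(vals)
  q <- which(cum >= variance_fraction * m - 1e-12)[1]
  if (is.na(q)) q <- m  # numerical shortfall; keep everything
  structure(list(
    values = vals[seq_len(q)],
    vectors = eig$vectors[, seq_len(q), drop = FALSE],
    variance_fraction_kept = cum[q] / m,
    m_block = m,
    q = q,
    all_values = vals
  ), class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("<eigen_basis> %d SNPs, rank %d (%.2f%% of LD variation)\n",
              x$m_block, x$q, 100 * x$variance_fraction_kept))
  invisible(x)
}

#' Build the low-rank pseudo-data (w, Q) for one LD block
#'
#' Projects standardized marginal effects onto the retained eigenbasis of the
#' block's LD matrix, producing the data the mixture sampler consumes:
#' \deqn{w = \sqrt{n}\,\Lambda^{-1/2} U' b_{std}, \qquad
#'       Q = \sqrt{n}\,\Lambda^{1/2} U',}
#' so that `w = Q beta + eps` with `var(eps) = I sigma_e^2` on the
#' standardized scale, and `Q'Q` reconstructs `n R` restricted to the
#' retained basis.
#'
#' @param b_std standardized marginal effects, aligned to the block's SNP
#'   order.
#' @param n_block effective sample size for the block (> 1).
#' @param basis an [eigendecompose_block()] result.
#' @return An object of class `pseudo_data`: list with `w` (length q),
#'   `q_mat` (q x m), `n_block`.
#' @export
build_pseudo_data <- function(b_std, n_block, basis) {
  stopifnot(inherits(basis, "eigen_basis"))
  if (length(b_std) != basis$m_block) {
    stop("length(b_std) [", length(b_std), "] does not match block size [",
         basis$m_block, "]")
  }
  if (!is.finite(n_block) || n_block <= 1) stop("n_block must be > 1")
  if (any(basis$values <= 0)) {
    stop("retained eigenvalues must be strictly positive (cannot invert); ",
         "lower variance_fraction or drop the degenerate block")
  }
  lam <- basis$values
  Ut_b <- crossprod(basis$vectors, b_std)  # q x 1
  w <- sqrt(n_block) * drop(Ut_b) / sqrt(lam)
  q_mat <- sqrt(n_block) * (sqrt(lam) * t(basis$vectors))
  structure(list(w = w, q_mat = q_mat, n_block = n_block),
            class = "pseudo_data")
}

#' Read a plain-text LD block definition file
#'
#' Whitespace-delimited with header `block_id chrom start end`; intervals are
#' 1-based inclusive. Blocks must not overlap within a chromosome.
#'
#' @param path file path.
#' @return data.frame with columns `block_id, chrom, start_bp, end_bp`.
#' @export
read_ld_blocks <- function(path) {
  dat <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("block_id", "chrom", "start", "end")
  if (!all(required %in% names(dat))) {
    stop("block file must have columns: ", paste(required, collapse = " "))
  }
  out <- data.frame(block_id = as.character(dat$block_id),
                    chrom = as.character(dat$chrom),
                    start_bp = as.integer(dat$start),
                    end_bp = as.integer(dat$end))
  if (any(out$end_bp < out$start_bp)) stop("block end before start")
  out
}

#' Build an LD store from genotypes and block definitions
#'
#' Computes the within-block LD correlation matrices from a genotype matrix,
#' eigendecomposes each, and packages the result with SNP metadata. Blocks
#' are treated as mutually independent (cross-block LD = 0). SNPs are
#' assigned to blocks by position; SNPs falling in no block are dropped.
#'
#' @param X genotype matrix (n individuals x m SNPs, allele counts 0/1/2).
#' @param snps data.frame with columns `snp, chrom, pos, a1, a2` aligned to
#'   the columns of `X`.
#' @param blocks data.frame as from [read_ld_blocks()]; if `NULL`, a single
#'   block spanning each chromosome is used.
#' @param variance_fraction passed to [eigendecompose_block()].
#' @return An object of class `ld_store`: list of per-block entries
#'   (`block_id`, `snps`, `basis`, `snp_index`) plus a genome-wide `snps`
#'   table.
#' @export
ld_store_from_genotypes <- function(X, snps, blocks = NULL,
                                    variance_fraction = 0.995) {
  stopifnot(ncol(X) == nrow(snps))
  if (is.null(blocks)) {
    blocks <- do.call(rbind, lapply(unique(snps$chrom), function(ch) {
      data.frame(block_id = paste0("blk_", ch), chrom = ch,
                 start_bp = min(snps$pos[snps$chrom == ch]),
                 end_bp = max(snps$pos[snps$chrom == ch]))
    }))
  }
  entries <- vector("list", nrow(blocks))
  kept <- integer(0)
  for (i in seq_len(nrow(blocks))) {
    in_blk <- which(snps$chrom == blocks$chrom[i] &
                    snps$pos >= blocks$start_bp[i] &
                    snps$pos <= blocks$end_bp[i])
    in_blk <- in_blk[order(snps$pos[in_blk])]
    if (length(in_blk) == 0L) next
    if (any(in_blk %in% kept)) stop("blocks overlap: SNP assigned twice")
    kept <- c(kept, in_blk)
    R <- block_cor(X[, in_blk, drop = FALSE])
    entries[[i]] <- list(block_id = as.character(blocks$block_id[i]),
                         snps = snps[in_blk, , drop = FALSE],
                         basis = eigendecompose_block(R, variance_fraction),
                         snp_index = in_blk)
    rownames(entries[[i]]$snps) <- NULL
  }
  entries <- entries[!vapply(entries, is.null, logical(1))]
  genome_snps <- do.call(rbind, lapply(entries, `[[`, "snps"))
  rownames(genome_snps) <- NULL
  structure(list(blocks = entries, snps = genome_snps,
                 variance_fraction = variance_fraction),
            class = "ld_store")
}

#' Build an LD store from precomputed correlation matrices
#'
#' @param R_list list of per-block correlation matrices.
#' @param snps_list list of per-block SNP tables (`snp, chrom, pos, a1, a2`).
#' @param variance_fraction passed to [eigendecompose_block()].
#' @return An `ld_store` object; see [ld_store_from_genotypes()].
#' @export
ld_store_from_correlations <- function(R_list, snps_list,
                                       variance_fraction = 0.995) {
  stopifnot(length(R_list) == length(snps_list))
  entries <- vector("list", length(R_list))
  offset <- 0L
  for (i in seq_along(R_list)) {
    sn <- snps_list[[i]]
    entries[[i]] <- list(block_id = paste0("blk_", i),
                         snps = sn,
                         basis = eigendecompose_block(R_list[[i]],
                                                      variance_fraction),
                         snp_index = offset + seq_len(nrow(sn)))
    offset <- offset + nrow(sn)
  }
  genome_snps <- do.call(rbind, snps_list)
  rownames(genome_snps) <- NULL
  structure(list(blocks = entries, snps = genome_snps,
                 variance_fraction = variance_fraction),
            class = "ld_store")
}

#' @export
print.ld_store <- function(x, ...) {
  q_tot <- sum(vapply(x$blocks, function(b) b$basis$q, integer(1)))
  cat(sprintf("<ld_store> %d blocks, %d SNPs, total retained rank %d\n",
              length(x$blocks), nrow(x$snps), q_tot))
  invisible(x)
}

#' Save / load an LD store
#'
#' The store is serialized with R's native format; decompositions are
#' computed once and reused across fits.
#'
#' @param store an `ld_store`.
#' @param path file path (conventionally `.ldstore.rds`).
#' @return `path` (save) or the `ld_store` (load).
#' @export
save_ld_store <- function(store, path) {
  stopifnot(inherits(store, "ld_store"))
  saveRDS(store, path)
  invisible(path)
}

#' @rdname save_ld_store
#' @export
load_ld_store <- function(path) {
  store <- readRDS(path)
  if (!inherits(store, "ld_store")) stop("'", path, "' is not an LD store")
  store
}

# Within-block correlation of genotype columns; monomorphic columns get zero
# correlation to everything and unit self-correlation.
block_cor <- function(Xb) {
  Xb <- scale(Xb, center = TRUE, scale = FALSE)
  sd0 <- apply(Xb, 2, stats::sd)
  bad <- sd0 < .Machine$double.eps
  if (any(bad)) Xb[, bad] <- 0
  R <- suppressWarnings(stats::cor(Xb))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R
}

# Reconstructed within-block LD r^2 from the retained eigenbasis.
block_r2 <- function(basis) {
  R <- basis$vectors %*% (basis$values * t(basis$vectors))
  d <- sqrt(pmax(diag(R), .Machine$double.eps))
  (R / outer(d, d))^2
}
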