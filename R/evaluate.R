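#' PIP calibration curve
#'
#' Bins SNPs into equal-width PIP bins and compares each bin's mean PIP to
#' its true discovery rate (the fraction of SNPs in the bin that are truly
#' causal). Well-calibrated PIPs track the TDR across the full range.
#'
#' @param pip vector of PIPs.
#' @param truth logical (or 0/1) vector: is the SNP truly causal?
#' @param n_bins number of equal-width bins on \[0, 1\] (default 100).
#' @param min_count bins with fewer SNPs are flagged and excluded from the
#'   summary deviation (default 10).
#' @return data.frame of class `calibration_curve` with columns
#'   `bin, lower, upper, mean_pip, tdr, count, flagged`; attribute
#'   `mean_abs_dev` holds the mean |TDR - mean PIP| over populated bins.
#' @export
calibration_curve <- function(pip, truth, n_bins = 100, min_count = 10) {
  if (length(pip) == 0) stop("empty input")
  stopifnot(length(pip) == length(truth))
  truth <- as.logical(truth)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(pip, edges, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(bin = seq_len(n_bins),
                    lower = edges[-(n_bins + 1)], upper = edges[-1])
  out$mean_pip <- vapply(seq_len(n_bins),
                         function(k) mean(pip[bin == k]), numeric(1))
  out$tdr <- vapply(seq_len(n_bins),
                    function(k) mean(truth[bin == k]), numeric(1))
  out$count <- tabulate(bin, n_bins)
  out$flagged <- out$count < min_count
  populated <- !out$flagged & out$count > 0
  mad <- if (any(populated)) {
    mean(abs(out$tdr[populated] - out$mean_pip[populated]))
  } else NA_real_
  attr(out, "mean_abs_dev") <- mad
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d bins, %d populated; mean |TDR - PIP| = %.4f\n",
              nrow(x), sum(!x$flagged & x$count > 0),
              attr(x, "mean_abs_dev")))
  invisible(x)
}

#' Mapping precision: distance to the nearest causal variant
#'
#' @param identified_pos base-pair positions of identified SNPs.
#' @param causal_pos base-pair positions of true causal variants.
#' @return list with `distances` (per identified SNP), `frac_zero`
#'   (fraction identifying the causal variant itself) and `q99` (99th
#'   percentile distance). Empty `identified_pos` gives an empty result.
#' @export
mapping_precision <- function(identified_pos, causal_pos) {
  if (length(identified_pos) == 0) {
    return(list(distances = numeric(0), frac_zero = NA_real_,
                q99 = NA_real_))
  }
  if (length(causal_pos) == 0) stop("no causal positions supplied")
  d <- vapply(identified_pos,
              function(p) min(abs(p - causal_pos)), numeric(1))
  list(distances = d, frac_zero = mean(d == 0),
       q99 = unname(stats::quantile(d, 0.99)))
}

#' Replication rate of fine-mapped SNPs in an independent sample
#'
#' For SNPs discovered at `PIP >= discovery_alpha` in the discovery fit,
#' the fraction whose replication-sample PIP reaches each threshold.
#'
#' @param pip_discovery,pip_replication PIP vectors over the same SNP set
#'   from fits on disjoint samples.
#' @param discovery_alpha discovery threshold (default 0.9).
#' @param thresholds replication thresholds (default 0.1 to 0.9 by 0.1).
#' @return data.frame with `threshold` and `rate`; attribute
#'   `n_discoveries`. With no discoveries, rates are `NA`.
#' @export
replication_rate <- function(pip_discovery, pip_replication,
                             discovery_alpha = 0.9,
                             thresholds = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(length(pip_discovery) == length(pip_replication))
  disc <- which(pip_discovery >= discovery_alpha)
  rate <- if (length(disc) == 0) {
    rep(NA_real_, length(thresholds))
  } else {
    vapply(thresholds,
           function(t) mean(pip_replication[disc] >= t), numeric(1))
  }
  out <- data.frame(threshold = thresholds, rate = rate)
  attr(out, "n_discoveries") <- length(disc)
  out
}

#' Out-of-sample polygenic prediction from fine-mapped SNPs
#'
#' Scores a validation cohort with posterior-mean allele-scale effects of
#' SNPs passing a PIP threshold and reports the squared correlation with
#' the validation phenotype.
#'
#' @param beta_allele posterior-mean effects on the allele scale.
#' @param pip PIPs aligned to `beta_allele`.
#' @param pip_threshold only SNPs at or above this PIP are scored.
#' @param X_val validation genotype matrix (individuals x SNPs, allele
#'   counts, aligned to `beta_allele`).
#' @param y_val validation phenotype.
#' @return list with `r2`, `n_snps` (SNPs scored), `score` (the PGS).
#' @export
pgs_predict <- function(beta_allele, pip, pip_threshold, X_val, y_val) {
  stopifnot(length(beta_allele) == length(pip),
            ncol(X_val) == length(beta_allele),
            nrow(X_val) == length(y_val))
  use <- pip >= pip_threshold & beta_allele != 0
  if (!any(use)) {
    return(list(r2 = 0, n_snps = 0L, score = rep(0, length(y_val))))
  }
  score <- drop(as.matrix(X_val[, use, drop = FALSE]) %*% beta_allele[use])
  r2 <- if (stats::sd(score) > 0) stats::cor(score, y_val)^2 else 0
  list(r2 = r2, n_snps = sum(use), score = score)
}
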