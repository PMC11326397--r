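#' Read GWAS summary statistics in COJO ".ma" format
#'
#' Parses a whitespace-delimited summary-statistics file with the header
#' `SNP A1 A2 freq b se p N` (the de-facto input dialect of the GCTB family
#' of tools). `A1` is the effect allele, `b` the per-allele marginal effect,
#' `se` its standard error, `freq` the effect-allele frequency and `N` the
#' per-SNP sample size. The z-statistic `z = b/se` is added on read.
#'
#' Rows violating the basic invariants (`se <= 0`, `freq` outside (0,1),
#' missing fields, `p` outside (0,1]) are dropped; the number dropped is
#' reported via a message and stored in the `"n_dropped"` attribute.
#'
#' @param path path to the summary-statistics file.
#' @return A `data.frame` with columns `snp, a1, a2, freq, b, se, p, n, z`
#'   and attribute `n_dropped`.
#' @export
read_ma <- function(path) {
  dat <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop("cannot read summary statistics file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(dat) == 0L) stop("summary statistics file '", path, "' is empty")
  required <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  hit <- match(toupper(required), toupper(names(dat)))
  if (anyNA(hit)) {
    stop("missing required column(s) in '", path, "': ",
         paste(required[is.na(hit)], collapse = ", "))
  }
  dat <- dat[, hit]
  names(dat) <- c("snp", "a1", "a2", "freq", "b", "se", "p", "n")
  dat$snp <- as.character(dat$snp)
  dat$a1 <- toupper(as.character(dat$a1))
  dat$a2 <- toupper(as.character(dat$a2))
  for (col in c("freq", "b", "se", "p", "n")) dat[[col]] <- as.numeric(dat[[col]])

  ok <- stats::complete.cases(dat) &
    dat$se > 0 &
    dat$freq > 0 & dat$freq < 1 &
    dat$p > 0 & dat$p <= 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(n_dropped, " of ", nrow(dat),
            " rows dropped (non-positive se, freq outside (0,1), ",
            "invalid p, or missing fields)")
  }
  dat <- dat[ok, , drop = FALSE]
  rownames(dat) <- NULL
  dat$z <- dat$b / dat$se
  attr(dat, "n_dropped") <- n_dropped
  dat
}

#' Write summary statistics in ".ma" format
#'
#' @param sumstats data.frame as returned by [read_ma()] (columns
#'   `snp, a1, a2, freq, b, se, p, n`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ma <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$snp, A1 = sumstats$a1, A2 = sumstats$a2,
                    freq = sumstats$freq, b = sumstats$b, se = sumstats$se,
                    p = sumstats$p, N = sumstats$n)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

# Strand-ambiguous (palindromic) allele pair: complement equals swap, so a
# strand flip cannot be distinguished from an allele swap.
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align summary statistics to LD reference alleles and standardize effects
#'
#' Matches each record to a reference SNP by id, resolves allele orientation
#' (direct match keeps the sign, a1/a2 swap negates it), and computes the
#' marginal effect on the standardized-genotype, standardized-phenotype scale
#' via the t-statistic-to-correlation identity
#' \deqn{b_{std} = z / \sqrt{z^2 + n - 2}.}
#' This is the scale on which the low-rank model and the mixture prior are
#' defined. Records with no reference match, with allele pairs that neither
#' match nor swap, or that are strand-ambiguous (A/T, C/G) are excluded and
#' counted.
#'
#' @param sumstats data.frame from [read_ma()].
#' @param reference data.frame with columns `snp, a1, a2` giving reference
#'   ids and allele orientation (e.g. the SNP table of an LD store).
#' @return The matched rows, reordered to the reference order, with extra
#'   columns `b_std` and `flipped`; attribute `n_excluded` counts exclusions.
#' @export
standardize_effects <- function(sumstats, reference) {
  stopifnot(all(c("snp", "a1", "a2") %in% names(reference)))
  idx <- match(reference$snp, sumstats$snp)
  keep_ref <- which(!is.na(idx))
  ss <- sumstats[idx[keep_ref], , drop = FALSE]
  ref <- reference[keep_ref, , drop = FALSE]

  direct <- ss$a1 == toupper(ref$a1) & ss$a2 == toupper(ref$a2)
  swapped <- ss$a1 == toupper(ref$a2) & ss$a2 == toupper(ref$a1)
  ambiguous <- is_palindromic(ss$a1, ss$a2)
  usable <- (direct | swapped) & !ambiguous

  n_excluded <- (nrow(reference) - length(keep_ref)) + sum(!usable)
  if (n_excluded > 0L) {
    message(n_excluded, " SNPs excluded at allele alignment ",
            "(unmatched, incompatible, or strand-ambiguous)")
  }
  ss <- ss[usable, , drop = FALSE]
  flip <- swapped[usable]
  ss$z <- ifelse(flip, -ss$z, ss$z)
  ss$b <- ifelse(flip, -ss$b, ss$b)
  ss$freq <- ifelse(flip, 1 - ss$freq, ss$freq)
  tmp <- ss$a1[flip]
  ss$a1[flip] <- ss$a2[flip]
  ss$a2[flip] <- tmp
  ss$flipped <- flip
  ss$b_std <- ss$z / sqrt(ss$z^2 + ss$n - 2)
  rownames(ss) <- NULL
  attr(ss, "n_excluded") <- n_excluded
  ss
}
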