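# GWAS summary statistics: per-SNP marginal regression on standardized
# dosages, and the whitespace-delimited sumstats text format.

#' Run a marginal GWAS
#'
#' For each SNP independently, simple linear regression (with intercept) of
#' the trait on the variance-normalized dosage. Effects are therefore on
#' the standardized scale, matching the effect model used by the
#' simulator and the likelihood of the estimator. Standard errors use the
#' conventional n-2 OLS residual formula; Z statistics are capped at
#' `+/- sqrt(n - 2)` (with a warning) so degenerate perfectly-correlated
#' columns report a finite statistic.
#'
#' All per-SNP regressions are computed from column moments of the raw
#' dosage matrix, so no standardized copy is materialized.
#'
#' @param data A [genotype_dataset()] with `n >= 30` and no monomorphic
#'   SNPs.
#' @param phen A `phenotype_set` from [simulate_phenotypes()] (or any list
#'   with a numeric `values` field of length n).
#' @return A `sumstats` data frame with columns `snp`, `a1`, `a2`, `af`,
#'   `n`, `beta`, `se`, `z` and a `population` attribute.
#' @export
run_gwas <- function(data, phen) {
  stopifnot(inherits(data, "genotype_dataset"))
  y <- phen$values
  n <- nrow(data$dosages)
  if (n < 30L) stop("GWAS requires n >= 30", call. = FALSE)
  if (length(y) != n) stop("phenotype length mismatch", call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite phenotype value", call. = FALSE)
  f <- data$freqs
  if (any(f <= 0 | f >= 1))
    stop("zero-variance (monomorphic) SNP in GWAS input", call. = FALSE)
  D <- data$dosages
  xm <- colMeans(D)
  sxx <- colSums(D * D) - n * xm^2            # raw-dosage Sxx
  yc <- y - mean(y)
  sxy <- as.vector(crossprod(D, yc))
  syy <- sum(yc^2)
  sig <- sqrt(2 * f * (1 - f))
  b_raw <- sxy / sxx
  rss <- pmax(syy - b_raw * sxy, 0)
  se_raw <- sqrt(rss / ((n - 2) * sxx))
  beta <- b_raw * sig                          # standardized-dosage scale
  se <- se_raw * sig
  zmax <- sqrt(n - 2)
  z <- ifelse(se > 0, beta / se, Inf * sign(beta))
  if (any(abs(z) > zmax)) {
    warning("capping ", sum(abs(z) > zmax), " |Z| statistic(s) at sqrt(n-2)",
            call. = FALSE)
    z <- pmin(pmax(z, -zmax), zmax)
    se <- ifelse(is.finite(se) & se > 0, se, beta / z)
  }
  out <- data.frame(snp = data$snp_ids, a1 = "A", a2 = "G", af = f, n = n,
                    beta = beta, se = se, z = z,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "population") <- data$population
  class(out) <- c("sumstats", "data.frame")
  out
}

sumstats_cols <- c("SNP", "A1", "A2", "af", "N", "beta", "SE")

#' Write / read GWAS summary statistics
#'
#' Whitespace-delimited text with header `SNP A1 A2 af N beta SE`; the
#' coded (dosage-counted) allele is `A1`. Reading is gzip-transparent and
#' recomputes `z = beta / SE`. Numeric fields round-trip to 6 significant
#' digits.
#'
#' @param stats A `sumstats` data frame from [run_gwas()].
#' @param path File path (may be `.gz` for reading).
#' @return `write_sumstats()` returns `path` invisibly; `read_sumstats()`
#'   returns a `sumstats` data frame.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "data.frame"))
  out <- data.frame(SNP = stats$snp, A1 = stats$a1, A2 = stats$a2,
                    af = signif(stats$af, 6), N = stats$n,
                    beta = signif(stats$beta, 6), SE = signif(stats$se, 6))
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_sumstats
#' @param population Population label to attach on read.
#' @export
read_sumstats <- function(path, population = NA_character_) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(sumstats_cols, names(tab))
  if (length(missing) > 0L)
    stop(paste(missing, collapse = ", "), " column absent from ", path,
         call. = FALSE)
  if (any(!is.finite(tab$SE) | tab$SE <= 0))
    stop("summary statistics contain non-positive SE values", call. = FALSE)
  out <- data.frame(snp = tab$SNP, a1 = tab$A1, a2 = tab$A2, af = tab$af,
                    n = tab$N, beta = tab$beta, se = tab$SE,
                    z = tab$beta / tab$SE,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "population") <- population
  class(out) <- c("sumstats", "data.frame")
  out
}
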