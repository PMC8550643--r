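# Approximate weighted likelihood estimator for SNP heritability and
# trans-ancestral genetic correlation, with block-jackknife standard
# errors.
#
# Model: under an (approximately) infinitesimal architecture the observed
# Z statistics are normal with
#   Var(z_ki)      = 1 + N_k h_k^2 ell_k,i / M          (k = 1, 2)
#   Cov(z_1i, z_2i) = sqrt(N1 N2) rho sqrt(h1^2 h2^2) ellx_i / M
# The per-SNP independent likelihood is weighted by 1/max(ell, 1) to
# down-weight signal double-counted through LD.

#' Likelihood configuration
#'
#' @param mode Cross-score mode used for the correlation stage: `"impact"`
#'   (allele-variance-normalized effects) or `"effect"` (per-allele
#'   effects).
#' @param weights `"inverse_ld"` (default; weight `1/max(ell, 1)`) or
#'   `"uniform"`.
#' @param h_bounds,rho_bounds Box constraints for the two stages.
#' @param optimizer_tol Convergence tolerance of the bounded 1-D search.
#' @param jackknife_blocks Number of contiguous SNP blocks for the
#'   delete-one-block jackknife (>= 2).
#' @return A `likelihood_config` object.
#' @export
likelihood_config <- function(mode = c("impact", "effect"),
                              weights = c("inverse_ld", "uniform"),
                              h_bounds = c(0, 1), rho_bounds = c(-1, 1),
                              optimizer_tol = 1e-6, jackknife_blocks = 20) {
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  stopifnot(optimizer_tol > 0, jackknife_blocks >= 2,
            length(h_bounds) == 2L, length(rho_bounds) == 2L,
            h_bounds[1] < h_bounds[2], rho_bounds[1] < rho_bounds[2])
  structure(list(mode = mode, weights = weights, h_bounds = h_bounds,
                 rho_bounds = rho_bounds, optimizer_tol = optimizer_tol,
                 jackknife_blocks = as.integer(jackknife_blocks)),
            class = "likelihood_config")
}

snp_weights <- function(ell, config) {
  if (config$weights == "inverse_ld") 1 / pmax(ell, 1) else
    rep(1, length(ell))
}

# Bounded 1-D maximization: optimize() never evaluates the endpoints, so
# compare its interior candidate against both bounds explicitly (boundary
# maxima at h^2 = 0 or rho = +/-1 are real use cases).
maximize_1d <- function(negll, bounds, tol) {
  opt <- optimize(negll, bounds, tol = tol)
  cand <- c(opt$minimum, bounds)
  val <- c(opt$objective, negll(bounds[1]), negll(bounds[2]))
  best <- which.min(val)
  list(par = cand[best], value = val[best])
}

h_negll <- function(z, N, ell, M, w) {
  force(z); force(N); force(ell); force(M); force(w)
  function(h2) {
    v <- 1 + N * h2 * ell / M
    -sum(w * dnorm(z, 0, sqrt(v), log = TRUE))
  }
}

#' Fit heritability from Z statistics and LD scores
#'
#' Maximizes the weighted per-SNP normal likelihood of the Z statistics
#' with variance `1 + N h^2 ell_i / M` over `h^2` in `h_bounds`.
#'
#' @param stats A `sumstats` data frame.
#' @param ell Within-population LD scores aligned with `stats`.
#' @param M Analysis SNP count (the denominator of the per-SNP variance;
#'   kept fixed under jackknife subsetting).
#' @param config A [likelihood_config()].
#' @return List with `h_sq`, `loglik`, `converged`.
#' @export
fit_heritability <- function(stats, ell, M = length(ell),
                             config = likelihood_config()) {
  z <- stats$z
  stopifnot(length(z) == length(ell), M >= 50)
  if (any(!is.finite(z))) stop("non-finite Z statistic", call. = FALSE)
  N <- stats$n[1L]
  w <- snp_weights(ell, config)
  fit <- maximize_1d(h_negll(z, N, ell, M, w), config$h_bounds,
                     config$optimizer_tol)
  list(h_sq = fit$par, loglik = -fit$value, converged = is.finite(fit$value))
}

rho_negll <- function(z1, z2, N1, N2, h1, h2, ell1, ell2, ellx, M, w) {
  v1 <- 1 + N1 * h1 * ell1 / M
  v2 <- 1 + N2 * h2 * ell2 / M
  amp <- sqrt(N1 * N2 * h1 * h2) * ellx / M
  zz11 <- z1^2
  zz22 <- z2^2
  zz12 <- z1 * z2
  function(rho) {
    cv <- rho * amp
    det <- v1 * v2 - cv^2
    if (any(det <= 0)) return(1e10)  # rho rejected: Sigma not PD
    q <- (v2 * zz11 - 2 * cv * zz12 + v1 * zz22) / det
    -sum(w * (-0.5 * (log(det) + q) - log(2 * pi)))
  }
}

#' Fit the genetic correlation with heritabilities fixed
#'
#' Second stage of the two-stage fit: maximizes the weighted per-SNP
#' bivariate-normal likelihood of `(z1, z2)` over `rho`, with the
#' population heritabilities held at the supplied first-stage estimates.
#' Proposals making any per-SNP covariance non-positive-definite are
#' rejected inside the bounded search.
#'
#' @param stats1,stats2 `sumstats` data frames aligned on SNP ids.
#' @param scores An `ld_scores` table aligned with the stats.
#' @param h1_sq,h2_sq First-stage heritability estimates in `[0, 1]`.
#' @param M Analysis SNP count.
#' @param config A [likelihood_config()]; `config$mode` selects the cross
#'   score column.
#' @return List with `rho`, `loglik`, `converged`, `degenerate` (TRUE when
#'   a zero heritability short-circuits the correlation to 0).
#' @export
fit_correlation <- function(stats1, stats2, scores, h1_sq, h2_sq,
                            M = nrow(scores), config = likelihood_config()) {
  stopifnot(nrow(stats1) == nrow(scores), nrow(stats2) == nrow(scores),
            h1_sq >= 0, h1_sq <= 1, h2_sq >= 0, h2_sq <= 1)
  if (!identical(as.character(stats1$snp), as.character(scores$snp)) ||
      !identical(as.character(stats2$snp), as.character(scores$snp)))
    stop("summary statistics and LD scores are not aligned on SNP ids",
         call. = FALSE)
  if (h1_sq < 1e-8 || h2_sq < 1e-8)
    return(list(rho = 0, loglik = NA_real_, converged = TRUE,
                degenerate = TRUE))
  ellx <- if (config$mode == "impact") scores$ellx_impact else
    scores$ellx_effect
  w <- snp_weights((scores$ell1 + scores$ell2) / 2, config)
  negll <- rho_negll(stats1$z, stats2$z, stats1$n[1L], stats2$n[1L],
                     h1_sq, h2_sq, scores$ell1, scores$ell2, ellx, M, w)
  fit <- maximize_1d(negll, config$rho_bounds, config$optimizer_tol)
  if (fit$value >= 1e10)
    stop("all proposed correlation values rejected (covariance never ",
         "positive definite)", call. = FALSE)
  list(rho = fit$par, loglik = -fit$value, converged = is.finite(fit$value),
       degenerate = FALSE)
}

# one full (h1, h2, rho) estimate on a SNP index subset; M stays fixed
fit_point <- function(stats1, stats2, scores, M, config, idx = NULL) {
  if (!is.null(idx)) {
    stats1 <- stats1[idx, , drop = FALSE]
    stats2 <- stats2[idx, , drop = FALSE]
    scores <- scores[idx, , drop = FALSE]
  }
  f1 <- fit_heritability(stats1, scores$ell1, M, config)
  f2 <- fit_heritability(stats2, scores$ell2, M, config)
  fr <- fit_correlation(stats1, stats2, scores, f1$h_sq, f2$h_sq, M, config)
  list(h1 = f1, h2 = f2, rho = fr)
}

#' Block-jackknife standard errors
#'
#' Partitions the SNPs into `config$jackknife_blocks` contiguous blocks,
#' re-estimates (h1^2, h2^2, rho) deleting one block at a time, and
#' returns `SE = sqrt((b - 1)/b * sum((theta_(-j) - theta_bar)^2))`.
#' Contiguous blocks respect local LD dependence; `M` is held at the full
#' analysis count throughout.
#'
#' @inheritParams fit_correlation
#' @return Named numeric vector `c(se_h1, se_h2, se_rho)`.
#' @export
jackknife_se <- function(stats1, stats2, scores, M = nrow(scores),
                         config = likelihood_config()) {
  m <- nrow(scores)
  b <- config$jackknife_blocks
  block <- ceiling(seq_len(m) / (m / b))
  sizes <- tabulate(block, b)
  if (any(sizes < 2L))
    stop("jackknife block with fewer than 2 SNPs; reduce the block count",
         call. = FALSE)
  theta <- matrix(NA_real_, b, 3L,
                  dimnames = list(NULL, c("h1", "h2", "rho")))
  for (j in seq_len(b)) {
    keep <- which(block != j)
    fit <- fit_point(stats1, stats2, scores, M, config, idx = keep)
    theta[j, ] <- c(fit$h1$h_sq, fit$h2$h_sq, fit$rho$rho)
  }
  centered <- sweep(theta, 2L, colMeans(theta))
  se <- sqrt((b - 1) / b * colSums(centered^2))
  c(se_h1 = se[[1L]], se_h2 = se[[2L]], se_rho = se[[3L]])
}

#' Full two-stage fit with jackknife standard errors
#'
#' Orchestrates the two marginal heritability fits, the correlation fit
#' with heritabilities fixed, and the block jackknife.
#'
#' @inheritParams fit_correlation
#' @return A `fit_result` object: point estimates `h1_sq_hat`, `h2_sq_hat`,
#'   `rho_hat`; jackknife SEs `se_h1`, `se_h2`, `se_rho`; `mode`, `loglik`
#'   (correlation stage), `converged`, `degenerate`, `n_snps_used`.
#' @export
full_fit <- function(stats1, stats2, scores, M = nrow(scores),
                     config = likelihood_config()) {
  fit <- tryCatch(fit_point(stats1, stats2, scores, M, config),
                  error = function(e)
                    stop("fit stage failed: ", conditionMessage(e),
                         call. = FALSE))
  se <- tryCatch(jackknife_se(stats1, stats2, scores, M, config),
                 error = function(e)
                   stop("jackknife stage failed: ", conditionMessage(e),
                        call. = FALSE))
  structure(list(h1_sq_hat = fit$h1$h_sq, h2_sq_hat = fit$h2$h_sq,
                 rho_hat = fit$rho$rho,
                 se_h1 = se[["se_h1"]], se_h2 = se[["se_h2"]],
                 se_rho = se[["se_rho"]],
                 mode = config$mode, loglik = fit$rho$loglik,
                 converged = fit$h1$converged && fit$h2$converged &&
                   fit$rho$converged,
                 degenerate = isTRUE(fit$rho$degenerate),
                 n_snps_used = nrow(scores)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("<fit_result> mode=%s  h1^2=%.4f (SE %.4f)  ",
                     "h2^2=%.4f (SE %.4f)  rho=%.4f (SE %.4f)  [M=%d]\n"),
              x$mode, x$h1_sq_hat, x$se_h1, x$h2_sq_hat, x$se_h2,
              x$rho_hat, x$se_rho, x$n_snps_used))
  invisible(x)
}

#' Serialize / deserialize a fit result as JSON
#'
#' @param fit A `fit_result`.
#' @param path JSON file path.
#' @return `write_fit_json()` returns `path` invisibly; `read_fit_json()`
#'   returns a `fit_result`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "fit_result")
}
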