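# Genetic architecture: bivariate spike-and-slab effect sizes, allelic
# impact weights, realized effect/impact correlations, genotype
# normalization and additive phenotypes.

#' Architecture parameters for the bivariate spike-and-slab model
#'
#' Per SNP, with probability `p_causal` the effect pair (beta1, beta2) is
#' drawn from a bivariate normal whose covariance encodes the two
#' heritabilities and the target genetic correlation `rho_ge`; otherwise
#' both effects are exactly zero. The slab variance is inflated by
#' `1/p_causal` so the expected total genetic variance is preserved under
#' the spike.
#'
#' Two effect-scale conventions are supported. `"standardized"` draws
#' effects that multiply variance-normalized genotypes, making the expected
#' genetic variance exactly `h^2` by construction. `"per_allele"` draws
#' per-allele effects whose slab variance is `h^2 / (p * sum(sigma^2))` per
#' population, so realized heritability still targets `h^2` despite the
#' frequency-dependent allelic impact.
#'
#' @param h1_sq,h2_sq Heritabilities in `[0, 1]`.
#' @param rho_ge Target genetic correlation in `[-1, 1]`.
#' @param p_causal Slab probability in (0, 1].
#' @param m_snps Number of SNPs M.
#' @param effect_scale `"standardized"` (default) or `"per_allele"`.
#' @return An `arch_params` object.
#' @export
arch_params <- function(h1_sq, h2_sq, rho_ge, p_causal = 0.99, m_snps,
                        effect_scale = c("standardized", "per_allele")) {
  effect_scale <- match.arg(effect_scale)
  if (abs(rho_ge) > 1)
    stop("|rho_ge| must not exceed 1", call. = FALSE)
  stopifnot(h1_sq >= 0, h1_sq <= 1, h2_sq >= 0, h2_sq <= 1,
            p_causal > 0, p_causal <= 1, m_snps >= 1)
  structure(list(h1_sq = h1_sq, h2_sq = h2_sq, rho_ge = rho_ge,
                 p_causal = p_causal, m_snps = as.integer(m_snps),
                 effect_scale = effect_scale),
            class = "arch_params")
}

#' Allelic impact weights
#'
#' Elementwise `sigma = sqrt(2 f (1 - f))`, the per-allele standard
#' deviation of a Hardy-Weinberg genotype; symmetric in `f` vs `1 - f`.
#'
#' @param f1,f2 Allele-frequency vectors, strictly inside (0, 1).
#' @return An `impact_weights` object with fields `sigma1`, `sigma2`.
#' @export
impact_weights <- function(f1, f2) {
  for (f in list(f1, f2))
    if (any(!is.finite(f) | f <= 0 | f >= 1))
      stop("allele frequencies must lie strictly inside (0, 1) (zero ",
           "variance at 0 or 1)", call. = FALSE)
  stopifnot(length(f1) == length(f2))
  structure(list(sigma1 = sqrt(2 * f1 * (1 - f1)),
                 sigma2 = sqrt(2 * f2 * (1 - f2))),
            class = "impact_weights")
}

#' Draw spike-and-slab effect sizes
#'
#' @param params An [arch_params()] object.
#' @param weights An [impact_weights()] object; required when
#'   `effect_scale = "per_allele"` (the slab variance depends on the
#'   allelic impacts), ignored otherwise.
#' @param seed Integer seed.
#' @return An `effect_sizes` object with fields `beta1`, `beta2`,
#'   `causal_mask`, `scale`.
#' @export
draw_effects <- function(params, weights = NULL, seed = NULL) {
  stopifnot(inherits(params, "arch_params"))
  m <- params$m_snps
  p <- params$p_causal
  if (params$effect_scale == "per_allele") {
    if (!inherits(weights, "impact_weights"))
      stop("per_allele effects require impact weights", call. = FALSE)
    stopifnot(length(weights$sigma1) == m)
    v1 <- params$h1_sq / (p * sum(weights$sigma1^2))
    v2 <- params$h2_sq / (p * sum(weights$sigma2^2))
  } else {
    v1 <- params$h1_sq / (p * m)
    v2 <- params$h2_sq / (p * m)
  }
  cv <- params$rho_ge * sqrt(v1 * v2)
  draws <- with_seed(seed, {
    mask <- runif(m) < p
    u1 <- rnorm(m)
    u2 <- rnorm(m)
    list(mask = mask, u1 = u1, u2 = u2)
  })
  # Cholesky of the 2x2 slab covariance; guard the h^2 = 0 edge.
  b1 <- sqrt(v1) * draws$u1
  b2 <- if (v1 > 0)
    (cv / sqrt(v1)) * draws$u1 + sqrt(max(v2 - cv^2 / v1, 0)) * draws$u2
  else sqrt(v2) * draws$u2
  b1[!draws$mask] <- 0
  b2[!draws$mask] <- 0
  structure(list(beta1 = b1, beta2 = b2, causal_mask = draws$mask,
                 scale = params$effect_scale),
            class = "effect_sizes")
}

# shared validation for the realized-correlation pair
check_effect_pairs <- function(effects) {
  nz <- effects$causal_mask & (effects$beta1 != 0 | effects$beta2 != 0)
  if (sum(nz) < 2L)
    stop("realized correlation undefined: fewer than 2 SNPs with nonzero ",
         "effects", call. = FALSE)
  invisible(nz)
}

#' Realized genetic-impact correlation
#'
#' The sample correlation of the allele-variance-weighted effects
#' `Cor(sigma1 * beta1, sigma2 * beta2)` over all SNPs — the realized
#' impact-scale genetic correlation of a drawn architecture.
#'
#' @param effects An `effect_sizes` object from [draw_effects()].
#' @param weights An [impact_weights()] object.
#' @return Scalar correlation.
#' @export
realized_impact_correlation <- function(effects, weights) {
  stopifnot(inherits(effects, "effect_sizes"),
            inherits(weights, "impact_weights"))
  check_effect_pairs(effects)
  cor(weights$sigma1 * effects$beta1, weights$sigma2 * effects$beta2)
}

#' Realized genetic-effect correlation
#'
#' The sample correlation of the per-allele effects: raw `beta` when the
#' architecture was drawn on the per-allele scale, `beta / sigma` when it
#' was drawn on the standardized scale.
#'
#' @inheritParams realized_impact_correlation
#' @return Scalar correlation.
#' @export
realized_effect_correlation <- function(effects, weights) {
  stopifnot(inherits(effects, "effect_sizes"),
            inherits(weights, "impact_weights"))
  check_effect_pairs(effects)
  if (effects$scale == "per_allele")
    cor(effects$beta1, effects$beta2)
  else
    cor(effects$beta1 / weights$sigma1, effects$beta2 / weights$sigma2)
}

#' Export per-SNP effect-size truth as TSV
#'
#' Columns: snp_id, beta1, beta2, causal, sigma1, sigma2.
#'
#' @param effects An `effect_sizes` object.
#' @param weights An [impact_weights()] object.
#' @param snp_ids SNP identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, weights, snp_ids, path) {
  out <- data.frame(snp_id = snp_ids,
                    beta1 = effects$beta1, beta2 = effects$beta2,
                    causal = effects$causal_mask,
                    sigma1 = weights$sigma1, sigma2 = weights$sigma2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Variance-normalize genotypes
#'
#' Column i is transformed as `(dosage - 2 f_i) / sqrt(2 f_i (1 - f_i))`
#' using the dataset's sample frequencies, so each column has mean ~0 and
#' variance ~1 under Hardy-Weinberg.
#'
#' @param data A [genotype_dataset()] with no monomorphic SNPs.
#' @return A numeric matrix of standardized dosages.
#' @export
normalize_genotypes <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  f <- data$freqs
  if (any(f <= 0 | f >= 1))
    stop("monomorphic SNP: cannot normalize a zero-variance column",
         call. = FALSE)
  X <- scale(data$dosages, center = 2 * f, scale = sqrt(2 * f * (1 - f)))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

#' Simulate additive phenotypes
#'
#' The genetic value is `g = X gamma` on the standardized-genotype scale,
#' where `gamma = beta` for standardized-scale effects and
#' `gamma = sigma * beta` for per-allele effects (whose slab calibration
#' already targets `Var(g) = h^2` in expectation). The trait is
#' `Y = g + eps` with `eps ~ N(0, 1 - h_sq)`, so `E[Var(Y)] = 1`.
#'
#' @param data A [genotype_dataset()] or an already-standardized dosage
#'   matrix. Passing the dataset avoids materializing the standardized
#'   matrix (the genetic value is accumulated from raw dosages).
#' @param beta Effect vector for this population, on the scale declared by
#'   `effect_scale`.
#' @param h_sq Heritability in `[0, 1]` used for the residual variance.
#' @param effect_scale `"standardized"` or `"per_allele"`.
#' @param sigma Per-SNP allelic impacts; required for per-allele effects.
#' @param seed Integer seed (residual draw).
#' @return A `phenotype_set` with fields `values`, `genetic_values`,
#'   `h_sq_used`.
#' @export
simulate_phenotypes <- function(data, beta, h_sq,
                                effect_scale = c("standardized",
                                                 "per_allele"),
                                sigma = NULL, seed = NULL) {
  effect_scale <- match.arg(effect_scale)
  if (h_sq < 0 || h_sq > 1)
    stop("h_sq must lie in [0, 1]", call. = FALSE)
  gamma <- if (effect_scale == "per_allele") {
    if (is.null(sigma))
      stop("per_allele effects require sigma", call. = FALSE)
    sigma * beta
  } else beta
  if (inherits(data, "genotype_dataset")) {
    f <- data$freqs
    if (any(f <= 0 | f >= 1))
      stop("monomorphic SNP in genotype data", call. = FALSE)
    s <- sqrt(2 * f * (1 - f))
    w <- gamma / s
    g <- as.vector(data$dosages %*% w) - sum(2 * f * w)
  } else {
    g <- as.vector(data %*% gamma)
  }
  n <- length(g)
  eps <- if (h_sq >= 1) numeric(n) else
    with_seed(seed, rnorm(n, 0, sqrt(1 - h_sq)))
  structure(list(values = g + eps, genetic_values = g, h_sq_used = h_sq),
            class = "phenotype_set")
}
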