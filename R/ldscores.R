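# Reference-panel LD scores: windowed within-population scores with
# small-sample bias correction, and cross-population scores in
# genetic-impact and genetic-effect modes.

# Standardize panel columns (sd with denominator L-1). Monomorphic columns
# are zeroed with a warning: their correlations are defined as 0 since the
# SNP should have been filtered upstream.
standardize_panel <- function(panel) {
  X <- scale(panel$dosages)
  mono <- !is.finite(colSums(X))
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) in reference panel; their LD ",
            "correlations are set to 0", call. = FALSE)
    X[, mono] <- 0
  }
  X
}

# lag-correlation matrix: r[i, d+1] = cor(x_i, x_{i+d}), d = 0..W
panel_lag_cor <- function(X, W) {
  L <- nrow(X)
  C <- cpp_lag_crossprod(X, X, as.integer(W)) / (L - 1)
  # a monomorphic (zeroed) column makes its own d = 0 entry 0, keep as is
  C
}

# bias-corrected squared correlation, E[g(r_hat^2)] ~ r^2 for a panel of
# size L (the uncorrected estimate is inflated by (1 - r^2)/(L - 2))
corrected_r2 <- function(r2, L) r2 - (1 - r2) / (L - 2)

#' Windowed LD correlations around one SNP
#'
#' Pearson correlations of standardized dosage columns between SNP `i` and
#' every SNP within `W` indices, the windowed approximation to row i of
#' the full LD matrix.
#'
#' @param panel A reference [genotype_dataset()] with at least 3
#'   individuals.
#' @param i SNP index.
#' @param W Window half-width in SNP-index units.
#' @return Named numeric vector of correlations `r(i, j)` for
#'   `j in [i - W, i + W]` (clipped at the boundaries); `r(i, i) = 1`.
#' @export
ld_correlation_window <- function(panel, i, W) {
  stopifnot(inherits(panel, "genotype_dataset"))
  L <- nrow(panel$dosages)
  if (L < 3L) stop("panel must have at least 3 individuals", call. = FALSE)
  m <- ncol(panel$dosages)
  stopifnot(i >= 1L, i <= m)
  js <- max(1L, i - W):min(m, i + W)
  X <- standardize_panel(subset_snps(panel, js))
  xi <- X[, which(js == i)]
  r <- as.vector(crossprod(xi, X)) / (L - 1)
  if (panel$freqs[i] > 0 && panel$freqs[i] < 1) r[js == i] <- 1
  names(r) <- panel$snp_ids[js]
  r
}

#' Within-population LD scores
#'
#' For each SNP, the windowed sum of bias-corrected squared LD
#' correlations, `ell_i = sum_j r2(i,j) - (1 - r2(i,j))/(L - 2)`, over
#' `j in [i - W, i + W]`, including the self term (which contributes
#' exactly 1).
#'
#' @param panel A reference [genotype_dataset()], `L >= 3` individuals.
#' @param W Window half-width in SNP-index units.
#' @return Numeric vector of per-SNP scores.
#' @export
within_scores <- function(panel, W = 100) {
  stopifnot(inherits(panel, "genotype_dataset"))
  L <- nrow(panel$dosages)
  if (L <= 2L) stop("panel size must exceed 2", call. = FALSE)
  X <- standardize_panel(panel)
  C <- panel_lag_cor(X, min(W, ncol(X) - 1L))
  within_scores_from_lags(C, L)
}

within_scores_from_lags <- function(C, L) {
  m <- nrow(C)
  W <- ncol(C) - 1L
  ell <- rep(1, m)  # self term
  for (d in seq_len(W)) {
    if (d >= m) break
    g <- corrected_r2(C[seq_len(m - d), d + 1L]^2, L)
    ell[seq_len(m - d)] <- ell[seq_len(m - d)] + g
    ell[(d + 1L):m] <- ell[(d + 1L):m] + g
  }
  ell
}

cross_scores_from_lags <- function(C1, C2, L1, L2, weight = NULL) {
  m <- nrow(C1)
  W <- ncol(C1) - 1L
  # self term: r1(i,i) * r2(i,i) (0 if monomorphic in a panel)
  ellx <- C1[, 1L] * C2[, 1L]
  if (is.null(weight)) weight <- rep(1, m)
  ellx <- ellx * weight
  for (d in seq_len(W)) {
    if (d >= m) break
    lo <- seq_len(m - d)
    hi <- (d + 1L):m
    u <- C1[lo, d + 1L] * C2[lo, d + 1L]
    # contribution to i from neighbor j = i + d carries j's weight, and
    # vice versa
    ellx[lo] <- ellx[lo] + u * weight[hi]
    ellx[hi] <- ellx[hi] + u * weight[lo]
  }
  ellx
}

#' Cross-population LD scores
#'
#' For each SNP, the windowed sum of products of the two populations'
#' LD correlations. In `impact` mode
#' `ellx_i = sum_j r1(i,j) r2(i,j)`; in `effect` mode each term is
#' additionally weighted by `sigma1_j sigma2_j / (c1 c2)`, where `sigma`
#' are allelic impacts from the panel allele frequencies and
#' `c_k = sqrt(mean(sigma_k^2))` over the analysis SNP set. Cross products
#' from independent panels are unbiased, so no small-sample correction is
#' applied.
#'
#' @param panel1,panel2 Reference [genotype_dataset()]s sharing SNP set and
#'   order.
#' @param mode `"impact"` or `"effect"`.
#' @param W Window half-width in SNP-index units.
#' @return Numeric vector of per-SNP cross scores.
#' @export
cross_scores <- function(panel1, panel2, mode = c("impact", "effect"),
                         W = 100) {
  mode <- match.arg(mode)
  sc <- ld_scores(panel1, panel2, window = W)
  if (mode == "impact") sc$ellx_impact else sc$ellx_effect
}

#' Compute the full LD-score table for a population pair
#'
#' Runs the windowed within-population scores for both panels and the
#' cross-population scores in both modes, returning them in one aligned
#' table.
#'
#' @param panel1,panel2 Reference [genotype_dataset()]s sharing SNP set and
#'   order.
#' @param window Window half-width in SNP-index units. The default 100
#'   captures essentially all LD mass of the geometric-decay simulator at
#'   `ld_rho <= 0.95`.
#' @return An `ld_scores` data frame with columns `snp`, `af1`, `af2`,
#'   `ell1`, `ell2`, `ellx_impact`, `ellx_effect` and attributes `window`,
#'   `L1`, `L2`.
#' @export
ld_scores <- function(panel1, panel2, window = 100) {
  stopifnot(inherits(panel1, "genotype_dataset"),
            inherits(panel2, "genotype_dataset"))
  if (!identical(panel1$snp_ids, panel2$snp_ids))
    stop("panels must share the same SNP set and order", call. = FALSE)
  L1 <- nrow(panel1$dosages)
  L2 <- nrow(panel2$dosages)
  if (L1 <= 2L || L2 <= 2L)
    stop("panel size must exceed 2", call. = FALSE)
  m <- ncol(panel1$dosages)
  W <- as.integer(min(window, m - 1L))
  X1 <- standardize_panel(panel1)
  C1 <- panel_lag_cor(X1, W)
  rm(X1)
  X2 <- standardize_panel(panel2)
  C2 <- panel_lag_cor(X2, W)
  rm(X2)
  f1 <- panel1$freqs
  f2 <- panel2$freqs
  s1 <- sqrt(2 * pmin(pmax(f1, 0), 1) * (1 - pmin(pmax(f1, 0), 1)))
  s2 <- sqrt(2 * pmin(pmax(f2, 0), 1) * (1 - pmin(pmax(f2, 0), 1)))
  wgt <- (s1 * s2) / (sqrt(mean(s1^2)) * sqrt(mean(s2^2)))
  out <- data.frame(snp = panel1$snp_ids, af1 = f1, af2 = f2,
                    ell1 = within_scores_from_lags(C1, L1),
                    ell2 = within_scores_from_lags(C2, L2),
                    ellx_impact = cross_scores_from_lags(C1, C2, L1, L2),
                    ellx_effect = cross_scores_from_lags(C1, C2, L1, L2,
                                                         weight = wgt),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "window") <- W
  attr(out, "L1") <- L1
  attr(out, "L2") <- L2
  class(out) <- c("ld_scores", "data.frame")
  out
}

scores_cols <- c("SNP", "af1", "af2", "ell1", "ell2", "ellx_impact",
                 "ellx_effect")

#' Write / read an LD-score table
#'
#' Tab-separated text with header
#' `SNP af1 af2 ell1 ell2 ellx_impact ellx_effect`, rows in ascending SNP
#' index order; numeric fields round-trip to 6 significant digits.
#'
#' @param scores An `ld_scores` data frame from [ld_scores()].
#' @param path File path.
#' @return `write_scores()` returns `path` invisibly; `read_scores()`
#'   returns an `ld_scores` data frame.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "data.frame"))
  out <- data.frame(SNP = scores$snp,
                    af1 = signif(scores$af1, 6), af2 = signif(scores$af2, 6),
                    ell1 = signif(scores$ell1, 6),
                    ell2 = signif(scores$ell2, 6),
                    ellx_impact = signif(scores$ellx_impact, 6),
                    ellx_effect = signif(scores$ellx_effect, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (!identical(header, scores_cols))
    stop("LD-score file header mismatch: expected `",
         paste(scores_cols, collapse = " "), "`", call. = FALSE)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  out <- data.frame(snp = tab$SNP, af1 = tab$af1, af2 = tab$af2,
                    ell1 = tab$ell1, ell2 = tab$ell2,
                    ellx_impact = tab$ellx_impact,
                    ellx_effect = tab$ellx_effect,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ld_scores", "data.frame")
  out
}
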