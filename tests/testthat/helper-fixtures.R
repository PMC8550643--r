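# Shared fixtures: all built in code at test time.

tiny_panel <- function(n = 200, m = 60, ld_rho = 0.8, fst = 0.055,
                       seed = 1, label = "T", keep_haplotypes = FALSE,
                       freq_range = c(0.05, 0.95)) {
  anc <- ancestral_frequencies(m, range = freq_range, seed = seed)
  pm <- population_model(label, fst, ld_rho)
  f <- draw_population_frequencies(anc, pm, seed + 1)
  simulate_genotypes(f, pm, n, seed + 2, keep_haplotypes = keep_haplotypes)
}

# genotype_dataset with prescribed per-SNP allele counts (for exact MAF
# fixtures): column j carries `alleles[j]` copies of the coded allele
# among 2n chromosomes.
counts_dataset <- function(alleles, n = 500, population = "fix") {
  m <- length(alleles)
  stopifnot(all(alleles <= 2 * n))
  D <- matrix(0, n, m)
  for (j in seq_len(m)) {
    k2 <- alleles[j] %/% 2
    if (k2 > 0) D[seq_len(k2), j] <- 2
    if (alleles[j] %% 2 == 1) D[k2 + 1, j] <- 1
  }
  genotype_dataset(D, population = population)
}

# Z statistics drawn from the estimator's own generative model (no LD):
# z_k ~ BVN(0, [[v1, c],[c, v2]]) with v = 1 + N h ell / M.
synth_z_pair <- function(m, n1, n2, h1, h2, rho, ell1 = rep(1, m),
                         ell2 = rep(1, m), ellx = rep(1, m), seed = 1) {
  set.seed(seed)
  v1 <- 1 + n1 * h1 * ell1 / m
  v2 <- 1 + n2 * h2 * ell2 / m
  cv <- sqrt(n1 * n2 * h1 * h2) * rho * ellx / m
  u1 <- rnorm(m)
  u2 <- rnorm(m)
  z1 <- sqrt(v1) * u1
  z2 <- (cv / sqrt(v1)) * u1 + sqrt(pmax(v2 - cv^2 / v1, 1e-12)) * u2
  snp <- sprintf("s%d", seq_len(m))
  mk <- function(z, n) {
    out <- data.frame(snp = snp, a1 = "A", a2 = "G", af = 0.5, n = n,
                      beta = z / sqrt(n), se = 1 / sqrt(n), z = z,
                      stringsAsFactors = FALSE)
    class(out) <- c("sumstats", "data.frame")
    out
  }
  sc <- data.frame(snp = snp, af1 = 0.5, af2 = 0.5, ell1 = ell1,
                   ell2 = ell2, ellx_impact = ellx, ellx_effect = ellx,
                   stringsAsFactors = FALSE)
  class(sc) <- c("ld_scores", "data.frame")
  list(stats1 = mk(z1, n1), stats2 = mk(z2, n2), scores = sc)
}

# Independent weighted bivariate-normal log-likelihood used as the grid
# oracle; written from the model definition, not from the package's
# objective code.
oracle_rho_loglik <- function(rho, z1, z2, n1, n2, h1, h2, ell1, ell2,
                              ellx, m, w) {
  v1 <- 1 + n1 * h1 * ell1 / m
  v2 <- 1 + n2 * h2 * ell2 / m
  cv <- rho * sqrt(n1 * n2 * h1 * h2) * ellx / m
  det <- v1 * v2 - cv^2
  if (any(det <= 0)) return(-Inf)
  ll <- -log(2 * pi) - 0.5 * log(det) -
    0.5 * (v2 * z1^2 - 2 * cv * z1 * z2 + v1 * z2^2) / det
  sum(w * ll)
}

oracle_h_loglik <- function(h2, z, n, ell, m, w) {
  v <- 1 + n * h2 * ell / m
  sum(w * dnorm(z, 0, sqrt(v), log = TRUE))
}
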