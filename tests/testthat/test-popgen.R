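test_that("Balding-Nichols drift reproduces the Beta moments", {
  anc <- ancestral_frequencies(10000, freqs = rep(0.3, 10000))
  pm <- population_model("P", fst = 0.15, ld_rho = 0)
  f <- draw_population_frequencies(anc, pm, seed = 11)
  expect_equal(mean(f), 0.3, tolerance = 0.01 / 0.3)
  expect_lt(abs(var(f) - 0.15 * 0.3 * 0.7), 0.2 * 0.15 * 0.3 * 0.7)
  # zero-drift limit: distribution collapses on the ancestral frequency
  anc5 <- ancestral_frequencies(2000, freqs = rep(0.5, 2000))
  pm0 <- population_model("P0", fst = 1e-4, ld_rho = 0)
  f0 <- draw_population_frequencies(anc5, pm0, seed = 12)
  expect_equal(mean(f0), 0.5, tolerance = 0.002)
  expect_lt(sd(f0), 0.01)
  # determinism and input validation
  expect_identical(f, draw_population_frequencies(anc, pm, seed = 11))
  bad <- anc
  bad$freqs[5] <- NaN
  expect_error(draw_population_frequencies(bad, pm, 1), "finite")
})

test_that("latent AR(1) haplotypes match the orthant-probability oracle", {
  m <- 30
  pm <- population_model("L", fst = 0.05, ld_rho = 0.9)
  d <- simulate_genotypes(rep(0.5, m), pm, 2500, seed = 3,
                          keep_haplotypes = TRUE)
  H <- d$haplotypes
  # oracle: binary correlation of two standard normals thresholded at
  # t = qnorm(f), latent correlation rho^lag, via numerical integration
  oracle_r <- function(rho, f = 0.5) {
    t <- qnorm(f)
    p11 <- integrate(function(z)
      dnorm(z) * pnorm((t - rho * z) / sqrt(1 - rho^2)),
      -Inf, t, rel.tol = 1e-10)$value
    (p11 - f^2) / (f * (1 - f))
  }
  obs <- vapply(1:5, function(lag) {
    mean(vapply(seq_len(m - lag), function(j)
      cor(H[, j], H[, j + lag]), 0))
  }, 0)
  exp_r <- vapply(1:5, function(lag) oracle_r(0.9^lag), 0)
  expect_true(all(abs(obs - exp_r) < 0.05))
  expect_gt(obs[1], 0.5)
  expect_lt(obs[1], 0.95)
  expect_true(all(diff(obs) < 0))
})

test_that("no-LD limit gives uncorrelated adjacent SNPs", {
  pm <- population_model("I", fst = 0.05, ld_rho = 0)
  d <- simulate_genotypes(runif(1000, 0.2, 0.8), pm, 300, seed = 5)
  r_adj <- vapply(seq_len(999), function(j)
    cor(d$dosages[, j], d$dosages[, j + 1]), 0)
  expect_lt(abs(mean(r_adj)), 0.05)
})

test_that("simulated allele frequencies converge on their targets", {
  target <- runif(300, 0.1, 0.9)
  pm <- population_model("F", fst = 0.05, ld_rho = 0.8)
  d <- simulate_genotypes(target, pm, 5000, seed = 7)
  dev <- abs(d$freqs - target)
  expect_lt(mean(dev), 0.005)                    # binomial SE ~ 0.005
  expect_lte(unname(quantile(dev, 0.99)), 0.02)
  expect_lt(max(dev), 0.03)
  expect_equal(d$freqs, colMeans(d$dosages) / 2)
  expect_error(simulate_genotypes(c(0.5, 1), pm, 10, 1), "inside")
})

test_that("haplotypic r2 is non-increasing in SNP lag", {
  d <- tiny_panel(n = 1500, m = 40, ld_rho = 0.85, seed = 31,
                  keep_haplotypes = TRUE)
  H <- d$haplotypes
  r2 <- vapply(1:10, function(lag)
    mean(vapply(seq_len(40 - lag), function(j)
      cor(H[, j], H[, j + lag])^2, 0)), 0)
  # allow small Monte-Carlo wiggle on the tail of the decay
  expect_true(all(diff(r2) < 0.01))
  expect_gt(r2[1], r2[10])
})

test_that("admixture degenerates correctly at the boundaries", {
  src_a <- tiny_panel(n = 400, m = 40, seed = 41, label = "A",
                      keep_haplotypes = TRUE)
  src_b <- tiny_panel(n = 400, m = 40, seed = 51, label = "B",
                      keep_haplotypes = TRUE)
  # admix_prop = 1: marginally indistinguishable from source a
  adm <- simulate_admixed(src_a, src_b, admix_prop = 1, block_len = 5,
                          n_individuals = 400, seed = 61)
  expect_lt(max(abs(adm$freqs - src_a$freqs)), 0.08)
  # block_len >= M with deterministic sources: single-ancestry haplotypes
  ha <- genotype_dataset(matrix(2, 50, 20),
                         haplotypes = matrix(1L, 100, 20))
  hb <- genotype_dataset(matrix(0, 50, 20),
                         haplotypes = matrix(0L, 100, 20))
  adm2 <- simulate_admixed(ha, hb, admix_prop = 0.5, block_len = 20,
                           n_individuals = 200, seed = 62,
                           keep_haplotypes = TRUE)
  expect_true(all(adm2$haplotypes %in% c(0L, 1L)))
  expect_true(all(apply(adm2$haplotypes, 1, function(h)
    all(h == h[1]))))
  expect_error(simulate_admixed(src_a, tiny_panel(m = 39, seed = 9,
                                                  keep_haplotypes = TRUE),
                                0.5, 5, 10, 1),
               "share")
})

test_that("admixture creates long-range LD absent from the sources", {
  m <- 40
  set.seed(71)
  # sources with a large frequency difference at every SNP
  from_haps <- function(p) {
    H <- matrix(rbinom(1600 * m, 1L, p), 1600, m)
    odd <- seq(1L, 1600L, by = 2L)
    genotype_dataset(H[odd, ] + H[odd + 1L, ], haplotypes = H)
  }
  ha <- from_haps(0.85)
  hb <- from_haps(0.15)
  adm <- simulate_admixed(ha, hb, admix_prop = 0.5, block_len = 2,
                          n_individuals = 800, seed = 72)
  far <- function(d, i, j) cor(d[, i], d[, j])^2
  pairs <- cbind(1:10, 21:30)  # 10 block lengths apart
  r2_adm <- mean(apply(pairs, 1, function(p)
    far(adm$dosages, p[1], p[2])))
  r2_a <- mean(apply(pairs, 1, function(p) far(ha$dosages, p[1], p[2])))
  r2_b <- mean(apply(pairs, 1, function(p) far(hb$dosages, p[1], p[2])))
  expect_gt(r2_adm, r2_a)
  expect_gt(r2_adm, r2_b)
})

test_that("MAF filtering keeps exactly the SNPs at or above f0", {
  d <- counts_dataset(c(4, 50, 300, 996), n = 500)  # freqs .004/.05/.3/.996
  kept <- filter_maf(d, 0.01)
  expect_identical(kept$snp_ids, d$snp_ids[2:3])
  expect_identical(filter_maf(d, 0)$snp_ids, d$snp_ids)
  expect_error(filter_maf(d, 0.45), "removed all")
})

test_that("relatedness filter removes duplicates and spares the unrelated", {
  d <- tiny_panel(n = 60, m = 5000, ld_rho = 0, seed = 81)
  # unrelated individuals: null kinship SD ~ 1/(2 sqrt(M)) << 0.05
  expect_identical(dim(filter_related(d, 0.05)), dim(d))
  expect_identical(dim(filter_related(d, 0.5)), dim(d))
  dup <- genotype_dataset(rbind(d$dosages, d$dosages[1, ]),
                          d$snp_ids, d$population)
  filt <- filter_related(dup, 0.05)
  expect_identical(nrow(filt$dosages), 60L)
  # the later copy is the one removed
  expect_identical(filt$dosages, d$dosages)
})

test_that("SNP intersection keeps shared polymorphic SNPs in order", {
  a <- counts_dataset(c(100, 200, 300), n = 400)
  a$snp_ids <- c("a", "b", "c")
  b <- counts_dataset(c(150, 250, 350), n = 400)
  b$snp_ids <- c("b", "c", "d")
  out <- intersect_snps(a, b)
  expect_identical(out$pop1$snp_ids, c("b", "c"))
  expect_identical(out$pop2$snp_ids, c("b", "c"))
  idab <- intersect_snps(a, a)
  expect_identical(idab$pop1$snp_ids, a$snp_ids)
  # monomorphic in one population drops from both
  b2 <- b
  b2$freqs[1] <- 0
  expect_identical(intersect_snps(a, b2)$pop1$snp_ids, "c")
  c0 <- counts_dataset(c(10, 20), n = 400)
  c0$snp_ids <- c("x", "y")
  expect_error(intersect_snps(a, c0), "shared")
})

test_that("MAF filtering commutes with the SNP intersection", {
  a <- tiny_panel(n = 300, m = 80, seed = 91, freq_range = c(0.02, 0.98))
  b <- tiny_panel(n = 300, m = 80, seed = 101, freq_range = c(0.02, 0.98))
  f0 <- 0.05
  path1 <- intersect_snps(filter_maf(a, f0), filter_maf(b, f0))
  both <- intersect_snps(a, b)
  keep <- pmin(both$pop1$freqs, 1 - both$pop1$freqs) >= f0 &
    pmin(both$pop2$freqs, 1 - both$pop2$freqs) >= f0
  expect_identical(path1$pop1$snp_ids, both$pop1$snp_ids[keep])
  expect_identical(path1$pop2$snp_ids, both$pop2$snp_ids[keep])
})

test_that("reference-panel sampling is a seeded uniform subsample", {
  d <- tiny_panel(n = 100, m = 30, seed = 111)
  p1 <- sample_reference_panel(d, 40, seed = 5)
  p2 <- sample_reference_panel(d, 40, seed = 5)
  expect_identical(p1$dosages, p2$dosages)
  full <- sample_reference_panel(d, 100, seed = 6)
  expect_identical(dim(full$dosages), dim(d$dosages))
  expect_equal(sort(rowSums(full$dosages)), sort(rowSums(d$dosages)))
  expect_error(sample_reference_panel(d, 101, 1), "exceeds")
  expect_error(sample_reference_panel(d, 2, 1), "exceed")
})

test_that("genotype text and VCF exports round-trip", {
  d <- tiny_panel(n = 40, m = 12, seed = 121)
  tmp <- tempfile(fileext = ".txt")
  write_genotypes(d, tmp)
  back <- read_genotypes(tmp, population = d$population)
  expect_equal(unname(back$dosages), unname(d$dosages))
  expect_identical(back$snp_ids, d$snp_ids)
  vcf_path <- tempfile(fileext = ".vcf")
  write_vcf(d, vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos_back <- t(matrix(c("0/0" = 0, "0/1" = 1, "1/1" = 2)[gt],
                       nrow(gt), ncol(gt)))
  expect_equal(unname(dos_back), unname(d$dosages))
})
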