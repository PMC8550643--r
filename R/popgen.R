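# Population genotype simulation: ancestral frequencies, Balding-Nichols
# drift, latent-AR(1) haplotypes with distance-decaying LD, two-way
# admixture, QC filters, and reference-panel subsampling.

#' Ancestral allele frequencies
#'
#' Container for the shared ancestral allele-frequency spectrum from which
#' diverged populations are drifted. By default frequencies are drawn
#' uniformly on `range`, a flat spectrum that keeps all SNPs comfortably
#' polymorphic after drift.
#'
#' @param m Number of SNPs.
#' @param range Length-2 numeric, support of the uniform frequency draw;
#'   must lie strictly inside (0, 1).
#' @param freqs Optional explicit frequency vector (overrides the draw).
#' @param seed Integer seed for the draw.
#' @return An object of class `ancestral_freqs` with fields `freqs` and
#'   0-based `positions`.
#' @export
ancestral_frequencies <- function(m, range = c(0.05, 0.95), freqs = NULL,
                                  seed = NULL) {
  if (is.null(freqs)) {
    stopifnot(length(range) == 2L, range[1] > 0, range[2] < 1,
              range[1] < range[2])
    freqs <- with_seed(seed, runif(m, range[1], range[2]))
  }
  if (any(!is.finite(freqs)))
    stop("ancestral frequencies must be finite", call. = FALSE)
  if (any(freqs <= 0 | freqs >= 1))
    stop("ancestral frequencies must lie strictly inside (0, 1)",
         call. = FALSE)
  structure(list(freqs = as.numeric(freqs),
                 positions = seq_along(freqs) - 1L),
            class = "ancestral_freqs")
}

#' Population divergence / LD model
#'
#' @param label Population name.
#' @param fst Drift parameter in (0, 1): the Balding-Nichols F separating
#'   this population from the shared ancestor.
#' @param ld_rho Latent AR(1) autocorrelation in `[0, 1)` between adjacent
#'   SNPs; haplotypic LD decays geometrically with index distance.
#' @return A `population_model` object.
#' @export
population_model <- function(label, fst, ld_rho) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(fst) || fst <= 0 || fst >= 1)
    stop("fst must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1)
    stop("ld_rho must lie in [0, 1)", call. = FALSE)
  structure(list(label = label, fst = fst, ld_rho = ld_rho),
            class = "population_model")
}

#' Built-in population presets
#'
#' Drift and LD presets for three continental-style populations. The
#' per-population `fst` is the drift from the shared ancestor, so a pair's
#' divergence is roughly the sum of its two values: EUR-EAS ~ 0.11,
#' EUR-YRI ~ 0.15, EAS-YRI ~ 0.17. `ld_rho` orders LD extent the way the
#' continental panels do (African-like LD is shortest-range). The exact
#' values are tunable configuration, not empirical claims.
#'
#' @return Named list of [population_model()] objects (`eur`, `eas`, `yri`).
#' @export
population_presets <- function() {
  list(eur = population_model("EUR", fst = 0.055, ld_rho = 0.90),
       eas = population_model("EAS", fst = 0.055, ld_rho = 0.90),
       yri = population_model("YRI", fst = 0.095, ld_rho = 0.80))
}

#' Genotype dataset
#'
#' Individuals-by-SNPs dosage container. Per-SNP sample allele frequencies
#' are (re)computed from the dosage matrix so the frequency invariant holds
#' by construction.
#'
#' @param dosages Numeric matrix, n x M, entries in \{0, 1, 2\}.
#' @param snp_ids Character vector of stable SNP identifiers.
#' @param population Population label.
#' @param haplotypes Optional 2n x M 0/1 integer matrix of the underlying
#'   haplotypes (rows 2i-1, 2i belong to individual i); required as source
#'   material by [simulate_admixed()].
#' @return A `genotype_dataset` object with fields `dosages`, `freqs`,
#'   `snp_ids`, `population` and optionally `haplotypes`.
#' @export
genotype_dataset <- function(dosages, snp_ids = NULL, population = "pop",
                             haplotypes = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(snp_ids)) snp_ids <- sprintf("s%d", seq_len(ncol(dosages)))
  stopifnot(length(snp_ids) == ncol(dosages))
  if (!is.null(haplotypes))
    stopifnot(nrow(haplotypes) == 2L * nrow(dosages),
              ncol(haplotypes) == ncol(dosages))
  structure(list(dosages = dosages,
                 freqs = colMeans(dosages) / 2,
                 snp_ids = as.character(snp_ids),
                 population = population,
                 haplotypes = haplotypes),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %s: %d individuals x %d SNPs%s\n",
              x$population, nrow(x$dosages), ncol(x$dosages),
              if (is.null(x$haplotypes)) "" else " (+haplotypes)"))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

# Row/column subsetting that keeps freqs and haplotypes consistent.
subset_individuals <- function(data, idx) {
  hap <- data$haplotypes
  if (!is.null(hap)) {
    hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    hap <- hap[hrows, , drop = FALSE]
  }
  genotype_dataset(data$dosages[idx, , drop = FALSE], data$snp_ids,
                   data$population, hap)
}

subset_snps <- function(data, idx) {
  hap <- data$haplotypes
  if (!is.null(hap)) hap <- hap[, idx, drop = FALSE]
  genotype_dataset(data$dosages[, idx, drop = FALSE], data$snp_ids[idx],
                   data$population, hap)
}

#' Drift population allele frequencies from an ancestral spectrum
#'
#' Each population frequency is drawn from the Balding-Nichols distribution
#' `Beta(f(1-F)/F, (1-f)(1-F)/F)` around ancestral frequency `f` with
#' `F = fst`, then clipped to `[0.001, 0.999]` to avoid degenerate
#' thresholds downstream.
#'
#' @param ancestral An [ancestral_frequencies()] object.
#' @param model A [population_model()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Numeric vector of population-specific frequencies.
#' @export
draw_population_frequencies <- function(ancestral, model, seed = NULL) {
  stopifnot(inherits(ancestral, "ancestral_freqs"),
            inherits(model, "population_model"))
  f <- ancestral$freqs
  if (any(!is.finite(f)))
    stop("non-finite ancestral frequency", call. = FALSE)
  fst <- model$fst
  shape1 <- f * (1 - fst) / fst
  shape2 <- (1 - f) * (1 - fst) / fst
  out <- with_seed(seed, rbeta(length(f), shape1, shape2))
  pmin(pmax(out, 0.001), 0.999)
}

#' Simulate genotypes with distance-decaying LD
#'
#' Haplotypes are generated from a stationary latent Gaussian AR(1) process
#' with autocorrelation `ld_rho` across adjacent SNP indices, thresholded
#' per SNP at the normal quantile matching its target frequency; a
#' genotype is the sum of two independent haplotypes. Adjacent-SNP
#' haplotypic correlation therefore decays geometrically with index
#' distance.
#'
#' @param pop_freqs Per-SNP target allele frequencies, strictly in (0, 1).
#' @param model A [population_model()] supplying `ld_rho` and the label.
#' @param n_individuals Number of individuals (>= 1).
#' @param seed Integer seed.
#' @param snp_ids Optional SNP identifiers.
#' @param keep_haplotypes Keep the 0/1 haplotype matrix (needed as source
#'   material for [simulate_admixed()]); doubles memory, default off.
#' @return A [genotype_dataset()].
#' @export
simulate_genotypes <- function(pop_freqs, model, n_individuals, seed = NULL,
                               snp_ids = NULL, keep_haplotypes = FALSE) {
  stopifnot(inherits(model, "population_model"), n_individuals >= 1)
  if (any(!is.finite(pop_freqs) | pop_freqs <= 0 | pop_freqs >= 1))
    stop("frequencies must lie strictly inside (0, 1)", call. = FALSE)
  res <- cpp_sim_dosages(qnorm(pop_freqs), model$ld_rho,
                         as.integer(n_individuals), pcg_seed(seed),
                         keep_haplotypes)
  genotype_dataset(res$dosages, snp_ids, model$label, res$haplotypes)
}

#' Two-way admixture specification
#'
#' @param source_a,source_b [population_model()]s for the two ancestries.
#' @param prop Genome-wide expected proportion of `source_a` ancestry.
#' @param block_len Ancestry-block length in SNPs.
#' @param concentration Beta concentration of the individual-level ancestry
#'   propensity (mean `prop`); smaller values give more between-individual
#'   ancestry variance and hence stronger long-range admixture LD. The
#'   default 6 gives an ancestry SD of ~0.15 at prop 0.8, in line with
#'   two-way admixed human cohorts.
#' @param n_source Individuals to simulate per source haplotype pool when
#'   the harness builds an admixed cohort.
#' @param label Population label of the admixed cohort.
#' @return An `admixed_spec` object.
#' @export
admixed_spec <- function(source_a = population_presets()$yri,
                         source_b = population_presets()$eur,
                         prop = 0.8, block_len = 50, concentration = 6,
                         n_source = 2000, label = "ADM") {
  stopifnot(inherits(source_a, "population_model"),
            inherits(source_b, "population_model"),
            prop > 0, prop <= 1, block_len >= 1, concentration > 0)
  structure(list(source_a = source_a, source_b = source_b, prop = prop,
                 block_len = as.integer(block_len),
                 concentration = concentration,
                 n_source = as.integer(n_source), label = label),
            class = "admixed_spec")
}

#' Simulate an admixed population from two source haplotype pools
#'
#' Each admixed haplotype is a mosaic of contiguous blocks of `block_len`
#' SNPs. An individual first receives an ancestry propensity
#' `pi ~ Beta(mean = admix_prop, concentration)` shared by both haplotypes;
#' each block's ancestry is then Bernoulli(`pi`) and the block is copied
#' from a uniformly chosen haplotype of that source pool. Between-individual
#' variation in `pi` is what creates long-range (cross-block) LD between
#' SNPs whose frequencies differ between the sources, as in real admixed
#' cohorts; with `concentration = Inf` blocks become independent and the
#' long-range LD vanishes.
#'
#' @param panel_a,panel_b Source [genotype_dataset()]s carrying haplotypes
#'   (see `keep_haplotypes` in [simulate_genotypes()]); must share SNP ids.
#' @param admix_prop Expected proportion of `panel_a` ancestry, in (0, 1];
#'   `1` degenerates to resampling `panel_a`.
#' @param block_len Ancestry-block length in SNPs (>= 1).
#' @param n_individuals Number of admixed individuals.
#' @param seed Integer seed.
#' @param concentration Beta concentration of the ancestry propensity.
#' @param label Population label.
#' @param keep_haplotypes Keep the admixed haplotype matrix.
#' @return A [genotype_dataset()].
#' @export
simulate_admixed <- function(panel_a, panel_b, admix_prop, block_len,
                             n_individuals, seed = NULL, concentration = 6,
                             label = "ADM", keep_haplotypes = FALSE) {
  stopifnot(inherits(panel_a, "genotype_dataset"),
            inherits(panel_b, "genotype_dataset"),
            admix_prop > 0, admix_prop <= 1, block_len >= 1,
            n_individuals >= 1)
  if (!identical(panel_a$snp_ids, panel_b$snp_ids))
    stop("source panels must share the same SNP set", call. = FALSE)
  if (is.null(panel_a$haplotypes) || is.null(panel_b$haplotypes))
    stop("source panels must carry haplotypes (keep_haplotypes = TRUE)",
         call. = FALSE)
  m <- ncol(panel_a$dosages)
  n <- as.integer(n_individuals)
  hap_a <- panel_a$haplotypes
  hap_b <- panel_b$haplotypes
  blocks <- split(seq_len(m), ceiling(seq_len(m) / block_len))
  H <- with_seed(seed, {
    pi_ind <- if (admix_prop >= 1) rep(1, n) else
      rbeta(n, admix_prop * concentration, (1 - admix_prop) * concentration)
    pi_hap <- rep(pi_ind, each = 2L)
    H <- matrix(0L, 2L * n, m)
    for (cols in blocks) {
      anc <- rbinom(2L * n, 1L, pi_hap) == 1L
      rows_a <- sample.int(nrow(hap_a), 2L * n, replace = TRUE)
      rows_b <- sample.int(nrow(hap_b), 2L * n, replace = TRUE)
      if (any(anc))
        H[anc, cols] <- hap_a[rows_a[anc], cols, drop = FALSE]
      if (any(!anc))
        H[!anc, cols] <- hap_b[rows_b[!anc], cols, drop = FALSE]
      H
    }
    H
  })
  odd <- seq(1L, 2L * n, by = 2L)
  dos <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  genotype_dataset(dos, panel_a$snp_ids, label,
                   if (keep_haplotypes) H else NULL)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains exactly the SNPs with `min(f, 1 - f) >= f0`.
#'
#' @param data A [genotype_dataset()].
#' @param f0 Minimum minor allele frequency, `0 <= f0 < 0.5`.
#' @return The filtered [genotype_dataset()].
#' @export
filter_maf <- function(data, f0) {
  stopifnot(inherits(data, "genotype_dataset"), f0 >= 0, f0 < 0.5)
  keep <- pmin(data$freqs, 1 - data$freqs) >= f0
  if (!any(keep))
    stop("minor allele frequency filter removed all SNPs (threshold too ",
         "aggressive)", call. = FALSE)
  subset_snps(data, which(keep))
}

#' Filter related individuals
#'
#' Kinship between two individuals is estimated as half the correlation of
#' their standardized genotype vectors (0.5 for duplicates). Pairs
#' exceeding `r0` are resolved greedily and deterministically: scanning
#' pairs in order, the higher-index member is removed unless one of the
#' pair is already gone.
#'
#' @param data A [genotype_dataset()] with at least 2 SNPs.
#' @param r0 Maximum pairwise kinship, `0 < r0 <= 0.5`.
#' @return The filtered [genotype_dataset()].
#' @export
filter_related <- function(data, r0) {
  stopifnot(inherits(data, "genotype_dataset"), r0 > 0, r0 <= 0.5,
            ncol(data$dosages) >= 2L)
  n <- nrow(data$dosages)
  if (n < 2L) return(data)
  poly <- data$freqs > 0 & data$freqs < 1
  X <- scale(data$dosages[, poly, drop = FALSE])
  kin <- 0.5 * stats::cor(t(X))
  bad <- which(upper.tri(kin) & kin > r0, arr.ind = TRUE)
  if (nrow(bad) == 0L) return(data)
  bad <- bad[order(bad[, 1L], bad[, 2L]), , drop = FALSE]
  removed <- logical(n)
  for (k in seq_len(nrow(bad))) {
    i <- bad[k, 1L]; j <- bad[k, 2L]
    if (!removed[i] && !removed[j]) removed[max(i, j)] <- TRUE
  }
  subset_individuals(data, which(!removed))
}

#' Restrict two datasets to their shared polymorphic SNPs
#'
#' Both outputs are restricted, in the order of `pop1`, to SNP identifiers
#' present and polymorphic (sample frequency strictly inside (0, 1)) in
#' both inputs.
#'
#' @param pop1,pop2 [genotype_dataset()]s.
#' @return A list with elements `pop1` and `pop2`.
#' @export
intersect_snps <- function(pop1, pop2) {
  stopifnot(inherits(pop1, "genotype_dataset"),
            inherits(pop2, "genotype_dataset"))
  poly1 <- pop1$snp_ids[pop1$freqs > 0 & pop1$freqs < 1]
  poly2 <- pop2$snp_ids[pop2$freqs > 0 & pop2$freqs < 1]
  common <- poly1[poly1 %in% poly2]
  if (length(common) == 0L)
    stop("no shared polymorphic SNPs between the two datasets",
         call. = FALSE)
  list(pop1 = subset_snps(pop1, match(common, pop1$snp_ids)),
       pop2 = subset_snps(pop2, match(common, pop2$snp_ids)))
}

#' Sample an external reference panel
#'
#' Uniform without-replacement subsample of `L` individuals, standing in
#' for an external LD reference when individual-level GWAS data are not
#' available.
#'
#' @param data A [genotype_dataset()].
#' @param L Panel size, `2 < L <= n`.
#' @param seed Integer seed.
#' @return A [genotype_dataset()] of `L` individuals.
#' @export
sample_reference_panel <- function(data, L, seed = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  n <- nrow(data$dosages)
  if (L <= 2L)
    stop("panel size L must exceed 2 (LD correlations undefined)",
         call. = FALSE)
  if (L > n)
    stop("panel size L exceeds the number of individuals", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, L))
  subset_individuals(data, idx)
}
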