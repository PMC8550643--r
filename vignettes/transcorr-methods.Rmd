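---
title: "Estimating trans-ancestral genetic correlation from summary statistics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating trans-ancestral genetic correlation from summary statistics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A complex trait measured in two ancestrally diverged populations has, per
SNP, two effect sizes. The *genetic correlation* between the populations —
the correlation of those per-SNP effects — measures how transferable a
genetic architecture is from one population to the other. When only GWAS
summary statistics (per-SNP marginal effect, SE, allele frequency, sample
size) are available, the correlation and the per-population SNP
heritabilities can still be estimated by modelling the joint distribution
of Z statistics, with linkage disequilibrium (LD) supplied by external
reference panels. `transcorr` implements that estimator together with a
fully synthetic simulation pipeline and an evaluation harness that
measures when the estimates are *accurate* (|bias| < 0.05) and *stable*
(SE < 0.1) — jointly, an "ideal estimate".

Two correlation conventions are supported throughout. The **genetic-effect
correlation** is the correlation of per-allele effect sizes. The
**genetic-impact correlation** is the correlation of allele-variance
normalized effects, i.e. of `sigma * beta` with
`sigma = sqrt(2 f (1 - f))`. They coincide when allele frequencies agree
between populations and increasingly diverge as frequencies drift apart.

## Generative model

**Effect sizes.** Per SNP i, the pair `(beta_1i, beta_2i)` follows a
bivariate spike-and-slab: with probability `p` it is bivariate normal with
per-population variances `h_k^2 / (p M)` and correlation `rho_ge`;
otherwise both effects are exactly zero. The `1/p` factor preserves the
expected total genetic variance under the spike; at the default `p = 0.99`
it changes the slab variance by only 1%, but exactness costs nothing. In
`per_allele` mode the slab variance is instead
`h_k^2 / (p * sum(sigma_k^2))`, so realized heritability still targets
`h_k^2` despite the frequency-dependent allelic impact (the expectation of
`2f(1-f)` is not 1). The two modes exist because the field's phenotype
equation applies effects to *normalized* genotypes while the impact
correlation treats them as *per-allele*; `effect_scale` makes the chosen
convention explicit, and the default (`standardized`) makes the expected
genetic variance exactly `h^2` by construction.

**Phenotypes.** `Y = X gamma + eps` with `X` variance-normalized
genotypes, `gamma` the standardized-scale effects and
`eps ~ N(0, 1 - h^2)`, so `E[Var(Y)] = 1` for every heritability. The
realized impact correlation of a draw, `Cor(sigma_1 beta_1,
sigma_2 beta_2)`, is recorded next to the target `rho_ge` in every
evaluation report.

**Genotypes.** Real chromosomes are replaced by a two-layer synthetic
model that reproduces the two features the estimator actually consumes:
allele-frequency divergence between populations, and LD that decays with
distance.

* *Divergence*: ancestral frequencies are uniform on (0.05, 0.95); each
  population drifts them through a Balding–Nichols draw
  `Beta(f(1-F)/F, (1-f)(1-F)/F)` with `F` the per-population `fst`
  (clipped to [0.001, 0.999] to avoid degenerate thresholds). The presets
  (`fst` 0.055/0.055/0.095 for EUR/EAS/YRI-like populations) give pairwise
  divergences of roughly 0.11–0.19, ordering the pairs the way the
  continental panels order; the exact values are configuration, not
  claims.
* *LD*: each haplotype is a stationary latent Gaussian AR(1) across SNP
  index (autocorrelation `ld_rho`, presets 0.9 for EUR/EAS-like and 0.8
  for the shorter-LD YRI-like populations), thresholded at `qnorm(f_j)`;
  a genotype is the sum of two independent haplotypes. Haplotypic
  correlation then decays geometrically with index distance, which is the
  property the windowed LD scores rely on. There is no physical map:
  "distance" is SNP-index difference.

**Admixture.** An admixed cohort is a mosaic of `block_len`-SNP ancestry
blocks copied from two source haplotype pools. Each individual first
draws an ancestry propensity `pi ~ Beta(mean = prop, concentration)`
shared by both haplotypes; block ancestries are then Bernoulli(`pi`).
The between-individual variance of `pi` is what creates *long-range*
admixture LD between SNPs whose frequencies differ between sources — with
block ancestries drawn independently at a fixed `prop`, cross-block
covariance would be exactly zero and the hallmark failure mode of
homogeneous-panel estimators would not exist in the simulation. The
default concentration 6 gives an ancestry SD of about 0.15 at
`prop = 0.8`, in line with two-way admixed human cohorts.

**QC and panels.** Cohorts are filtered at minor allele frequency
`f0 = 0.01` and restricted to SNPs polymorphic in both populations. A
kinship filter (`filter_related`, half-correlation of standardized
genotype vectors, greedy higher-index removal above `r0 = 0.05`) is part
of the QC API; the scenario pipeline simulates unrelated individuals by
construction and therefore skips it. Reference panels of `L = 500`
individuals per population are drawn as independent samples of the same
population model — the "external panel" of a GWAS is precisely a sample
of individuals outside the study cohort.

## The estimator

GWAS summary statistics come from per-SNP marginal regression on
variance-normalized dosages, so `beta_hat` is on the standardized scale
and under an (approximately) infinitesimal architecture

```
Var(z_ki)       = 1 + N_k h_k^2 ell_k,i / M,
Cov(z_1i, z_2i) = sqrt(N1 N2) rho sqrt(h1^2 h2^2) ell_x,i / M,
```

where `ell_k,i` is SNP i's LD score in population k and `ell_x,i` the
cross-population score. Scores are computed from the reference panels in
a window of `W = 100` SNP indices (geometric LD decay makes the beyond-
window mass negligible for `ld_rho <= 0.95`):

* within scores sum bias-corrected squared correlations
  `r^2 - (1 - r^2)/(L - 2)`, including the self term (1); the correction
  removes the `~2W/(L-2)` inflation a finite panel would otherwise add;
* cross scores sum products `r_1(i,j) r_2(i,j)` (impact mode), optionally
  weighted by `sigma_1j sigma_2j / (c_1 c_2)` with
  `c_k = sqrt(mean(sigma_k^2))` (effect mode). Products of correlations
  from independent panels are already unbiased, so no correction is
  applied there. The effect-mode normalization is derived from the
  per-allele covariance algebra and validated by parameter recovery; the
  window and correction conventions are internal decisions, justified by
  the recovery and calibration tests rather than by any published
  formula.

Fitting is a **two-stage approximate weighted likelihood** on the per-SNP
statistics, treated as independent across SNPs: first each heritability
maximizes the normal likelihood of `z_k` over `h_k^2` in [0, 1], then the
correlation maximizes the bivariate-normal likelihood over `rho` in
[-1, 1] with the heritabilities held fixed. Per-SNP weights
`1/max(ell, 1)` down-weight signal that LD double-counts; the weight
choice is ours and is validated by recovery and jackknife calibration.
The 1-D searches are Brent's method at tolerance 1e-6 with both interval
endpoints checked explicitly, so boundary maxima (null heritability, a
correlation pinned at ±1) are returned exactly; a dense-grid oracle test
holds the optimizer to 0.002. A proposal making any per-SNP covariance
non-positive-definite is rejected inside the search, and a zero
first-stage heritability short-circuits `rho` to 0 with a degeneracy
flag (the correlation is undefined there). Standard errors come from a
delete-one-block jackknife over `b = 20` contiguous SNP blocks —
contiguity respects local LD; `M` stays at the full analysis count
throughout.

## Evaluation harness

A `scenario` bundles population models, cohort sizes, SNP count, panel
size, architecture, QC and estimator configuration; replicate `r` derives
all of its seeds deterministically from `(base_seed, r)`, so every run is
bitwise reproducible and no operation touches the global RNG state. The
default scenario — the package's standard study conditions — is
N1 = N2 = 10,000, M = 8,000 SNPs, L = 500, h1² = h2² = rho = 0.5,
p = 0.99, 30 replicates. These sizes were chosen so that a full recovery
experiment runs in minutes on one core while the information content
(`N h^2 ell / M` per SNP) stays comparable to chromosome-scale studies;
the absolute sample-size/SNP-count thresholds of such studies do not
transfer to this scale and are not claimed.

`sweep_scenario` walks L, N or M over an ascending grid and reports, per
parameter, the smallest value that is ideal *with all larger tested
values also ideal* — a guard against Monte-Carlo flickers (the choice of
rule is ours). SNP-count sweeps change the simulated M directly rather
than thinning a fixed set.

`mismatch_experiment` reruns identical replicates (same seeds, same
summary statistics) scoring population 2 either with its own panel or
with a panel from a drift/LD-discordant population. With a shorter-LD
panel standing in for a longer-LD population, the cross scores shrink
faster than the inflated second-stage heritability compensates, so the
correlation shifts upward and `h2²` inflates — the direction the
evaluation asserts. Population 1 keeps its panel, so its heritability is
bitwise identical between arms.

`admixture_experiment` compares scoring an admixed cohort with a panel of
admixed individuals against a homogeneous source-population panel. By
default the source arm uses the longer-LD (minority, European-like)
source: its windowed scores overstate the admixed cohort's local LD —
ancestry switching truncates LD at block boundaries — and the cohort's
heritability is pulled downward, the documented hazard of standing a
continental panel in for an admixed GWAS. The majority-ancestry
(African-like) panel is also available (`panel_source = "a"`); in this
synthetic model its within-window LD deficit and the admixed cohort's
boundary-truncated LD nearly cancel, so it probes a much weaker version
of the same failure mode.

## Numerical choices and edge cases

* Genotype simulation and the LD lag products are compiled (Rcpp); the
  latent normals come from a PCG32 + ziggurat stream seeded from R's RNG,
  so results are deterministic across platforms given the seed.
* Z statistics are capped at `±sqrt(n-2)` (with a warning) so degenerate
  perfectly-correlated columns report a finite statistic.
* Monomorphic SNPs in a reference panel have their correlations defined
  as 0 with a warning — they should have been filtered, but a panel
  subsample can lose a rare allele that the cohort retains.
* Frequencies are clipped to [0.001, 0.999] after drift; `optimize`'s
  interior search is supplemented by explicit endpoint evaluation.
* Sub-seeds for pipeline stages are derived by a fixed affine map on the
  replicate seed; all of them stay below 2^31.

## What passing tests do and do not show

The simulator reproduces frequency divergence, geometric LD decay,
admixture LD and the spike-and-slab architecture, and the test suite
shows the estimator is unbiased and stable *under that model*. Real
genomes have recombination-map structure, MAF-dependent architectures,
population stratification within cohorts, sample overlap and
genomic-control corrections, none of which are modelled; conclusions
about absolute sample-size or SNP-count requirements on real data do not
follow from these tests. Binary traits, covariates, physical-distance
windows and PCA-adjusted LD scores for admixed panels are out of scope.
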