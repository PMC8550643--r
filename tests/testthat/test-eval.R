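fake_fit <- function(h1, h2, rho, se = 0.02) {
  structure(list(h1_sq_hat = h1, h2_sq_hat = h2, rho_hat = rho,
                 se_h1 = se, se_h2 = se, se_rho = se, mode = "impact",
                 loglik = 0, converged = TRUE, degenerate = FALSE,
                 n_snps_used = 100L),
            class = "fit_result")
}

test_that("bias, SE and the ideal classification follow their definitions", {
  truth <- list(h1_sq = 0.5, h2_sq = 0.5, rho_ge = 0.5)
  fits <- lapply(c(0.52, 0.48, 0.50, 0.50), function(r)
    fake_fit(0.5, 0.5, r))
  rep1 <- summarize_replicates(fits, truth = truth)
  expect_equal(unname(rep1$bias["rho"]), 0)
  expect_equal(unname(rep1$empirical_se["rho"]),
               sd(c(0.52, 0.48, 0.50, 0.50)), tolerance = 1e-12)
  expect_equal(unname(rep1$empirical_se["rho"]), 0.01633, tolerance = 1e-3)
  expect_true(rep1$ideal[["rho"]])
  # constant bias of 0.10: accuracy fails
  rep2 <- summarize_replicates(lapply(1:4, function(i)
    fake_fit(0.5, 0.5, 0.60)), truth = truth)
  expect_equal(unname(rep2$bias["rho"]), 0.10)
  expect_false(rep2$ideal[["rho"]])
  # small bias but unstable: stability fails
  set.seed(1)
  wobble <- 0.52 + c(-1.2, -0.4, 0.4, 1.2) * 0.12
  rep3 <- summarize_replicates(lapply(wobble, function(r)
    fake_fit(0.5, 0.5, r)), truth = truth)
  expect_lt(abs(rep3$bias[["rho"]]), 0.05)
  expect_gt(rep3$empirical_se[["rho"]], 0.1)
  expect_false(rep3$ideal[["rho"]])
  # single replicate: empirical SE and ideal flag undefined
  rep4 <- summarize_replicates(list(fake_fit(0.5, 0.5, 0.5)),
                               truth = truth)
  expect_true(is.na(rep4$empirical_se[["rho"]]))
  expect_true(is.na(rep4$ideal[["rho"]]))
  expect_error(summarize_replicates(list(), truth = truth), "successful")
})

tiny_scenario <- function(base_seed = 5, ...) {
  pp <- population_presets()
  default_scenario(base_seed = base_seed, n1 = 600, n2 = 600,
                   m_snps = 300, panel_size = 80, n_replicates = 2,
                   window = 40, ...)
}

test_that("scenario runs are bitwise reproducible from the base seed", {
  s <- tiny_scenario()
  r1 <- run_scenario(s)
  r2 <- run_scenario(s)
  expect_identical(r1$fits, r2$fits)
  expect_identical(r1$truths, r2$truths)
  expect_length(r1$failures, 0)
})

test_that("scenario runs leave the global RNG untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(run_scenario(tiny_scenario(base_seed = 6,
                                       n_replicates = 1)))
  expect_identical(.Random.seed, before)
})

test_that("a single-value sweep reduces to run + summarize", {
  s <- tiny_scenario(base_seed = 7)
  sw <- sweep_scenario("L", 80, s)
  direct <- summarize_replicates(run_scenario(s))
  expect_equal(sw$reports[["80"]]$per_replicate, direct$per_replicate)
  expect_error(sweep_scenario("L", numeric(0), s), "empty")
  expect_error(sweep_scenario("L", c(100, 50), s), "ascending")
})

test_that("larger cohorts stabilize the correlation estimate", {
  s <- tiny_scenario(base_seed = 21, m_snps = 500, panel_size = 150,
                     n_replicates = 6)
  sw <- sweep_scenario("N", c(2000, 10000), s)
  expect_lt(sw$reports[["10000"]]$empirical_se[["rho"]],
            sw$reports[["2000"]]$empirical_se[["rho"]])
})

test_that("the recovery grid tracks the varied parameter", {
  s <- tiny_scenario(base_seed = 23, n1 = 2000, n2 = 2000, m_snps = 400,
                     panel_size = 150, n_replicates = 3)
  gr <- recovery_grid(s, "rho", values = c(0.2, 0.8))
  expect_equal(gr[["0.2"]]$truth$rho_ge, 0.2)
  expect_equal(gr[["0.8"]]$truth$rho_ge, 0.8)
  expect_lt(mean(gr[["0.2"]]$per_replicate$rho),
            mean(gr[["0.8"]]$per_replicate$rho))
  gh <- recovery_grid(s, "h2", values = c(0.1, 0.9))
  expect_lt(mean(gh[["0.1"]]$per_replicate$h2),
            mean(gh[["0.9"]]$per_replicate$h2))
})

test_that("negative genetic correlations are recovered end to end", {
  s <- tiny_scenario(base_seed = 27, n1 = 3000, n2 = 3000, m_snps = 1000,
                     panel_size = 300, n_replicates = 3, rho_ge = -0.6)
  rep <- summarize_replicates(run_scenario(s))
  expect_lt(abs(mean(rep$per_replicate$rho) + 0.6), 0.15)
})

test_that("inadequate axis values yield no ideal minimum", {
  s <- tiny_scenario(base_seed = 8, n_replicates = 3)
  sw <- sweep_scenario("N", c(200, 300), s)
  expect_true(all(is.na(sw$minima)))
})

test_that("the mismatch control arm is the plain scenario run", {
  s <- tiny_scenario(base_seed = 9, n_replicates = 3, panel_size = 100)
  wrong <- population_presets()$yri
  mx <- mismatch_experiment(s, wrong)
  direct <- summarize_replicates(run_scenario(s))
  expect_equal(mx$correct$per_replicate$rho, direct$per_replicate$rho)
  expect_equal(mx$correct$per_replicate$h1, direct$per_replicate$h1)
  # population 1 is scored identically in both arms
  expect_equal(mx$pairs$h1_matched, mx$pairs$h1_mismatched)
  expect_error(mismatch_experiment(s, s$pop2), "differ")
})

test_that("admixed cohorts run end to end and a source panel biases h2 down", {
  pp <- population_presets()
  adm <- admixed_spec(source_a = pp$yri, source_b = pp$eur, prop = 0.8,
                      block_len = 50, n_source = 800)
  s <- scenario(pop1 = pp$eur, pop2 = adm, n1 = 3000, n2 = 3000,
                m_snps = 1200, panel_size = 350, n_replicates = 6,
                base_seed = 11)
  ax <- admixture_experiment(s, panel_source = "b")
  expect_length(ax$failures, 0)
  # arm A (own panel) completes and keeps population 1 accurate
  expect_lt(abs(ax$own_panel$bias[["h1"]]), 0.1)
  expect_lt(abs(ax$source_panel$bias[["h1"]]), 0.1)
  # scoring the admixed cohort with the long-LD source panel drags its
  # heritability down
  expect_lt(ax$source_panel$bias[["h2"]], 0)
  expect_lt(ax$source_panel$bias[["h2"]], ax$own_panel$bias[["h2"]])
})

test_that("scenario YAML configuration round-trips", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c(
    "pop1: {label: EUR, fst: 0.055, ld_rho: 0.9}",
    "pop2: {label: EAS, fst: 0.055, ld_rho: 0.9}",
    "n1: 500", "n2: 400", "m_snps: 200", "panel_size: 60",
    "arch: {h1_sq: 0.4, h2_sq: 0.6, rho_ge: 0.2, p_causal: 0.95}",
    "qc: {f0: 0.02}", "n_replicates: 2", "base_seed: 17"), tmp)
  s <- read_scenario_yaml(tmp)
  expect_identical(s$n1, 500L)
  expect_identical(s$pop2$label, "EAS")
  expect_equal(s$h2_sq, 0.6)
  expect_equal(s$f0, 0.02)
  expect_identical(s$base_seed, 17L)
  # admixed form
  tmp2 <- tempfile(fileext = ".yaml")
  writeLines(c(
    "pop1: {label: EUR, fst: 0.055, ld_rho: 0.9}",
    "admixed:",
    "  source_a: {label: YRI, fst: 0.095, ld_rho: 0.8}",
    "  source_b: {label: EUR, fst: 0.055, ld_rho: 0.9}",
    "  prop: 0.8",
    "n1: 500", "n2: 400", "m_snps: 200", "panel_size: 60"), tmp2)
  s2 <- read_scenario_yaml(tmp2)
  expect_s3_class(s2$pop2, "admixed_spec")
  expect_equal(s2$pop2$prop, 0.8)
})
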