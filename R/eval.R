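# Evaluation harness: scenario definitions, the simulate -> QC -> panel ->
# sumstats -> scores -> fit pipeline per replicate, bias/stability
# summaries with the ideal-estimate classification, axis sweeps, and the
# panel-misspecification and admixture experiments.

#' Define an evaluation scenario
#'
#' A scenario fixes everything one replicate of the pipeline needs: the
#' two population models (population 2 may be a two-way [admixed_spec()]),
#' cohort sizes, SNP count, reference-panel size, architecture parameters,
#' QC threshold and estimator configuration. Replicate r of a run uses
#' seeds derived deterministically from `(base_seed, r)`.
#'
#' @param pop1 A [population_model()].
#' @param pop2 A [population_model()] or an [admixed_spec()].
#' @param n1,n2 GWAS cohort sizes.
#' @param m_snps Analysis SNP count M (post-QC target).
#' @param panel_size External reference-panel size L per population.
#' @param h1_sq,h2_sq,rho_ge,p_causal,effect_scale Architecture parameters
#'   (see [arch_params()]).
#' @param f0 Minor-allele-frequency QC threshold.
#' @param window LD-score window half-width in SNP indices.
#' @param n_replicates Number of replicates.
#' @param base_seed Integer base seed; a run is bitwise reproducible from
#'   `(scenario, base_seed)`.
#' @param config A [likelihood_config()]; defaults to impact mode for
#'   standardized-scale architectures and effect mode for per-allele ones.
#' @param m_buffer Oversimulation factor for SNPs so the post-QC
#'   intersection still reaches `m_snps`.
#' @return A `scenario` object.
#' @export
scenario <- function(pop1, pop2, n1, n2, m_snps, panel_size,
                     h1_sq = 0.5, h2_sq = 0.5, rho_ge = 0.5,
                     p_causal = 0.99,
                     effect_scale = c("standardized", "per_allele"),
                     f0 = 0.01, window = 100, n_replicates = 30,
                     base_seed = 1, config = NULL, m_buffer = 1.08) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(inherits(pop1, "population_model"),
            inherits(pop2, "population_model") ||
              inherits(pop2, "admixed_spec"),
            n1 >= 1, n2 >= 1, m_snps >= 50, panel_size > 2,
            n_replicates >= 1, m_buffer >= 1)
  if (is.null(config))
    config <- likelihood_config(
      mode = if (effect_scale == "per_allele") "effect" else "impact")
  structure(list(pop1 = pop1, pop2 = pop2,
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 m_snps = as.integer(m_snps),
                 panel_size = as.integer(panel_size),
                 h1_sq = h1_sq, h2_sq = h2_sq, rho_ge = rho_ge,
                 p_causal = p_causal, effect_scale = effect_scale,
                 f0 = f0, window = window,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed), config = config,
                 m_buffer = m_buffer),
            class = "scenario")
}

#' The desk-scale default scenario
#'
#' Two EUR/EAS-like populations, N1 = N2 = 10,000, M = 8,000 SNPs,
#' L = 500 reference individuals, h1^2 = h2^2 = rho_ge = 0.5, p = 0.99,
#' 30 replicates: the package's standard conditions for parameter-recovery
#' experiments, sized so a full run takes minutes on one core.
#'
#' @param base_seed Integer base seed.
#' @param ... Overrides passed on to [scenario()].
#' @return A `scenario` object.
#' @export
default_scenario <- function(base_seed = 1, ...) {
  pp <- population_presets()
  args <- list(pop1 = pp$eur, pop2 = pp$eas, n1 = 10000, n2 = 10000,
               m_snps = 8000, panel_size = 500, h1_sq = 0.5, h2_sq = 0.5,
               rho_ge = 0.5, p_causal = 0.99, n_replicates = 30,
               base_seed = base_seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario, args)
}

# panel/cohort split of one simulated super-sample
split_panel <- function(data, L, seed) {
  n <- nrow(data$dosages)
  idx <- sort(with_seed(seed, sample.int(n, L)))
  list(panel = subset_individuals(data, idx),
       cohort = subset_individuals(data, setdiff(seq_len(n), idx)))
}

# QC in one pass: MAF filter in each cohort, shared-polymorphic
# intersection, then uniform trim to the target M (same rules as
# filter_maf + intersect_snps, applied as a single subset so desk-scale
# cohorts are copied once).
qc_snp_index <- function(cohort1, cohort2, f0, m_target) {
  maf1 <- pmin(cohort1$freqs, 1 - cohort1$freqs)
  maf2 <- pmin(cohort2$freqs, 1 - cohort2$freqs)
  keep <- which(maf1 >= f0 & maf2 >= f0 &
                  cohort1$freqs > 0 & cohort1$freqs < 1 &
                  cohort2$freqs > 0 & cohort2$freqs < 1)
  if (length(keep) == 0L)
    stop("QC removed all SNPs", call. = FALSE)
  if (length(keep) > m_target) keep <- keep[seq_len(m_target)]
  keep
}

# One replicate of the full pipeline. Optionally also fits a mismatched
# arm (population 2 scored with a panel from `mismatch_model`) and, for an
# admixed population 2, a source-panel arm.
sim_replicate <- function(s, seed, mismatch_model = NULL,
                          admix_source_arm = FALSE,
                          admix_source = c("b", "a")) {
  admix_source <- match.arg(admix_source)
  ds <- function(k) derive_seed(seed, k)
  L <- s$panel_size
  m_total <- ceiling(s$m_snps * s$m_buffer)
  anc <- ancestral_frequencies(m_total, seed = ds(1))
  admixed <- inherits(s$pop2, "admixed_spec")

  # The cohort and its external reference panel are independent draws of
  # unrelated individuals from the same population model (the panel stands
  # in for L individuals outside the GWAS).
  f1p <- draw_population_frequencies(anc, s$pop1, ds(2))
  sp1 <- list(cohort = simulate_genotypes(f1p, s$pop1, s$n1, ds(3)),
              panel = simulate_genotypes(f1p, s$pop1, L, ds(4)))

  src_panel <- NULL
  if (admixed) {
    sp2_spec <- s$pop2
    fa <- draw_population_frequencies(anc, sp2_spec$source_a, ds(5))
    fb <- draw_population_frequencies(anc, sp2_spec$source_b, ds(6))
    src_a <- simulate_genotypes(fa, sp2_spec$source_a, sp2_spec$n_source,
                                ds(7), keep_haplotypes = TRUE)
    src_b <- simulate_genotypes(fb, sp2_spec$source_b, sp2_spec$n_source,
                                ds(8), keep_haplotypes = TRUE)
    d2 <- simulate_admixed(src_a, src_b, sp2_spec$prop, sp2_spec$block_len,
                           s$n2 + L, ds(9), sp2_spec$concentration,
                           sp2_spec$label)
    if (admix_source_arm) {
      src <- if (admix_source == "a") src_a else src_b
      src$haplotypes <- NULL
      src_panel <- sample_reference_panel(src, L, ds(11))
    }
    rm(src_a, src_b)
    sp2 <- split_panel(d2, L, ds(10))
    rm(d2)
  } else {
    f2p <- draw_population_frequencies(anc, s$pop2, ds(5))
    sp2 <- list(cohort = simulate_genotypes(f2p, s$pop2, s$n2, ds(7)),
                panel = simulate_genotypes(f2p, s$pop2, L, ds(10)))
  }

  keep <- qc_snp_index(sp1$cohort, sp2$cohort, s$f0, s$m_snps)
  cohort1 <- subset_snps(sp1$cohort, keep)
  panel1 <- subset_snps(sp1$panel, keep)
  rm(sp1)
  cohort2 <- subset_snps(sp2$cohort, keep)
  panel2 <- subset_snps(sp2$panel, keep)
  rm(sp2)
  if (!is.null(src_panel)) src_panel <- subset_snps(src_panel, keep)
  m_used <- length(keep)

  arch <- arch_params(s$h1_sq, s$h2_sq, s$rho_ge, s$p_causal, m_used,
                      s$effect_scale)
  wts <- impact_weights(cohort1$freqs, cohort2$freqs)
  eff <- draw_effects(arch, wts, ds(12))
  phen1 <- simulate_phenotypes(cohort1, eff$beta1, s$h1_sq, s$effect_scale,
                               wts$sigma1, ds(13))
  phen2 <- simulate_phenotypes(cohort2, eff$beta2, s$h2_sq, s$effect_scale,
                               wts$sigma2, ds(14))
  ss1 <- run_gwas(cohort1, phen1)
  rm(cohort1)
  ss2 <- run_gwas(cohort2, phen2)
  rm(cohort2)

  scores <- ld_scores(panel1, panel2, window = s$window)
  fit <- full_fit(ss1, ss2, scores, M = m_used, config = s$config)

  truth <- list(h1_sq = s$h1_sq, h2_sq = s$h2_sq, rho_ge = s$rho_ge,
                rho_gi = realized_impact_correlation(eff, wts),
                rho_effect = realized_effect_correlation(eff, wts))
  diag <- list(mean_z2_1 = mean(ss1$z^2), mean_z2_2 = mean(ss2$z^2),
               mean_ell1 = mean(scores$ell1), mean_ell2 = mean(scores$ell2))

  out <- list(fit = fit, truth = truth, diagnostics = diag, m_used = m_used)

  if (!is.null(mismatch_model)) {
    f3p <- draw_population_frequencies(anc, mismatch_model, ds(20))
    panel_mis <- simulate_genotypes(f3p, mismatch_model, L, ds(21))
    panel_mis <- subset_snps(panel_mis, keep)
    scores_mis <- ld_scores(panel1, panel_mis, window = s$window)
    out$fit_mismatch <- full_fit(ss1, ss2, scores_mis, M = m_used,
                                 config = s$config)
  }
  if (!is.null(src_panel)) {
    scores_src <- ld_scores(panel1, src_panel, window = s$window)
    out$fit_source_panel <- full_fit(ss1, ss2, scores_src, M = m_used,
                                     config = s$config)
  }
  out
}

replicate_seed <- function(base_seed, r) derive_seed(base_seed, 1000 + r)

#' Run an evaluation scenario
#'
#' Executes the full pipeline (simulate genotypes, QC, reference-panel
#' split, spike-and-slab effects, phenotypes, GWAS, LD scores, likelihood
#' fit) for each replicate, with per-replicate seeds derived
#' deterministically from the scenario's base seed. A stage failure is
#' recorded for its replicate and the run continues.
#'
#' @param s A [scenario()].
#' @return An `eval_run`: list with `fits` (per-replicate `fit_result`s),
#'   `truths`, `diagnostics`, `failures`, and the scenario.
#' @export
run_scenario <- function(s) {
  stopifnot(inherits(s, "scenario"))
  fits <- vector("list", s$n_replicates)
  truths <- vector("list", s$n_replicates)
  diags <- vector("list", s$n_replicates)
  failures <- character(0)
  for (r in seq_len(s$n_replicates)) {
    res <- tryCatch(sim_replicate(s, replicate_seed(s$base_seed, r)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("replicate %d: %s", r, conditionMessage(res)))
    } else {
      fits[[r]] <- res$fit
      truths[[r]] <- res$truth
      diags[[r]] <- res$diagnostics
    }
  }
  structure(list(fits = fits, truths = truths, diagnostics = diags,
                 failures = failures, scenario = s),
            class = "eval_run")
}

run_estimates <- function(fits) {
  ok <- !vapply(fits, is.null, logical(1))
  do.call(rbind, lapply(which(ok), function(r) {
    f <- fits[[r]]
    data.frame(replicate = r, h1 = f$h1_sq_hat, h2 = f$h2_sq_hat,
               rho = f$rho_hat, se_h1 = f$se_h1, se_h2 = f$se_h2,
               se_rho = f$se_rho)
  }))
}

#' Summarize replicate estimates into a bias/stability report
#'
#' For each parameter (rho, h1^2, h2^2): bias = mean estimate - truth,
#' empirical SE = sample SD across replicates, mean reported (jackknife)
#' SE, and the ideal-estimate classification
#' `ideal = |bias| < 0.05 & empirical SE < 0.1` — an estimate is "ideal"
#' when it is both accurate and stable. With a single successful
#' replicate the empirical SE is undefined (NA) and `ideal` is flagged NA.
#'
#' @param run An `eval_run` from [run_scenario()], or a list of
#'   `fit_result`s together with `truth`.
#' @param truth Optional named list (`h1_sq`, `h2_sq`, `rho_ge`) overriding
#'   the truth stored in the run.
#' @return An `eval_report` with fields `per_replicate`, `truth`, `bias`,
#'   `empirical_se`, `mean_reported_se`, `ideal`, `n_failures`.
#' @export
summarize_replicates <- function(run, truth = NULL) {
  if (inherits(run, "eval_run")) {
    fits <- run$fits
    if (is.null(truth)) {
      s <- run$scenario
      tr <- run$truths[!vapply(run$truths, is.null, logical(1))]
      truth <- list(h1_sq = s$h1_sq, h2_sq = s$h2_sq, rho_ge = s$rho_ge,
                    mean_rho_gi = mean(vapply(tr, `[[`, 0, "rho_gi")))
    }
    n_failures <- length(run$failures)
  } else {
    fits <- run
    n_failures <- 0L
    if (is.null(truth)) stop("truth required", call. = FALSE)
  }
  est <- run_estimates(fits)
  if (is.null(est) || nrow(est) == 0L)
    stop("no successful replicates to summarize", call. = FALSE)
  tvec <- c(rho = truth$rho_ge, h1 = truth$h1_sq, h2 = truth$h2_sq)
  bias <- c(rho = mean(est$rho), h1 = mean(est$h1), h2 = mean(est$h2)) -
    tvec
  if (nrow(est) >= 2L) {
    emp <- c(rho = sd(est$rho), h1 = sd(est$h1), h2 = sd(est$h2))
  } else {
    emp <- c(rho = NA_real_, h1 = NA_real_, h2 = NA_real_)
  }
  rep_se <- c(rho = mean(est$se_rho), h1 = mean(est$se_h1),
              h2 = mean(est$se_h2))
  ideal <- abs(bias) < 0.05 & emp < 0.1
  structure(list(per_replicate = est, truth = truth, bias = bias,
                 empirical_se = emp, mean_reported_se = rep_se,
                 ideal = ideal, n_failures = n_failures),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d replicates (%d failed)\n",
              nrow(x$per_replicate), x$n_failures))
  tab <- data.frame(bias = x$bias, empirical_se = x$empirical_se,
                    mean_jackknife_se = x$mean_reported_se,
                    ideal = x$ideal)
  print(round(tab[, 1:3], 4))
  cat("ideal:", paste(names(x$ideal), x$ideal, sep = "=",
                      collapse = "  "), "\n")
  invisible(x)
}

#' Sweep one scenario axis
#'
#' Runs the scenario template across an ascending grid of one axis —
#' reference-panel size `L`, cohort size `N` (sets N1 = N2), or SNP count
#' `M` — and reports, per parameter, the smallest axis value whose report
#' is ideal with all larger tested values also ideal (guarding against
#' Monte-Carlo flickers).
#'
#' @param axis `"L"`, `"N"` or `"M"`.
#' @param values Ascending numeric grid.
#' @param template A [scenario()].
#' @return List with `reports` (one `eval_report` per value, named) and
#'   `minima` (named vector: smallest adequate value per parameter, NA if
#'   none).
#' @export
sweep_scenario <- function(axis = c("L", "N", "M"), values, template) {
  axis <- match.arg(axis)
  stopifnot(inherits(template, "scenario"))
  if (length(values) == 0L) stop("empty sweep grid", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE))
    stop("sweep values must be sorted ascending", call. = FALSE)
  reports <- lapply(values, function(v) {
    s <- template
    if (axis == "L") s$panel_size <- as.integer(v)
    if (axis == "N") s$n1 <- s$n2 <- as.integer(v)
    if (axis == "M") s$m_snps <- as.integer(v)
    summarize_replicates(run_scenario(s))
  })
  names(reports) <- as.character(values)
  ideal_mat <- t(vapply(reports, function(r) r$ideal, logical(3)))
  minima <- apply(ideal_mat, 2L, function(ok) {
    ok[is.na(ok)] <- FALSE
    adequate <- rev(cumprod(rev(ok))) == 1  # ideal here and at all larger
    if (any(adequate)) values[which(adequate)[1L]] else NA_real_
  })
  list(reports = reports, minima = minima)
}

#' Recovery grid over true parameter values
#'
#' Runs the scenario template across a grid of one architecture parameter
#' — the genetic correlation or one heritability over, by default, 0 to 1
#' in increments of 0.1 — with the other parameters left at the
#' template's values (0.5 in the default scenario). The classic
#' parameter-recovery design for checking that mean estimates track the
#' truth across the whole range.
#'
#' @param template A [scenario()].
#' @param param `"rho"`, `"h1"` or `"h2"`.
#' @param values Grid of true values (`rho` may extend over `[-1, 1]`).
#' @return Named list of `eval_report`s, one per grid value.
#' @export
recovery_grid <- function(template, param = c("rho", "h1", "h2"),
                          values = seq(0, 1, by = 0.1)) {
  param <- match.arg(param)
  stopifnot(inherits(template, "scenario"))
  reports <- lapply(values, function(v) {
    s <- template
    if (param == "rho") s$rho_ge <- v
    if (param == "h1") s$h1_sq <- v
    if (param == "h2") s$h2_sq <- v
    summarize_replicates(run_scenario(s))
  })
  names(reports) <- as.character(values)
  reports
}

#' Reference-panel misspecification experiment
#'
#' Runs identical replicates (same seeds, same cohorts and summary
#' statistics) under two score sets: population 2 scored with its own
#' matched panel versus with a panel simulated from `wrong_panel_source`
#' (a population with different drift and/or LD decay). Reports both arms
#' and the per-parameter bias shift (mismatched minus matched).
#'
#' @param template A [scenario()] with a non-admixed population 2.
#' @param wrong_panel_source A [population_model()] differing from
#'   `template$pop2`.
#' @return List with `correct`, `mismatched` (both `eval_report`s),
#'   `shift` (named vector), and `pairs` (per-replicate estimates of both
#'   arms).
#' @export
mismatch_experiment <- function(template, wrong_panel_source) {
  stopifnot(inherits(template, "scenario"),
            inherits(wrong_panel_source, "population_model"))
  if (inherits(template$pop2, "admixed_spec"))
    stop("use admixture_experiment() for an admixed population 2",
         call. = FALSE)
  if (isTRUE(all.equal(wrong_panel_source[c("fst", "ld_rho")],
                       template$pop2[c("fst", "ld_rho")])))
    stop("wrong_panel_source must differ from the population-2 model",
         call. = FALSE)
  fits_ok <- vector("list", template$n_replicates)
  fits_mis <- vector("list", template$n_replicates)
  truths <- vector("list", template$n_replicates)
  failures <- character(0)
  for (r in seq_len(template$n_replicates)) {
    res <- tryCatch(
      sim_replicate(template, replicate_seed(template$base_seed, r),
                    mismatch_model = wrong_panel_source),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("replicate %d: %s", r, conditionMessage(res)))
    } else {
      fits_ok[[r]] <- res$fit
      fits_mis[[r]] <- res$fit_mismatch
      truths[[r]] <- res$truth
    }
  }
  truth <- list(h1_sq = template$h1_sq, h2_sq = template$h2_sq,
                rho_ge = template$rho_ge)
  rep_ok <- summarize_replicates(fits_ok, truth = truth)
  rep_mis <- summarize_replicates(fits_mis, truth = truth)
  est_ok <- rep_ok$per_replicate
  est_mis <- rep_mis$per_replicate
  pairs <- merge(est_ok, est_mis, by = "replicate",
                 suffixes = c("_matched", "_mismatched"))
  list(correct = rep_ok, mismatched = rep_mis,
       shift = rep_mis$bias - rep_ok$bias, pairs = pairs,
       failures = failures)
}

#' Admixed-population panel experiment
#'
#' Population 2 is a two-way admixed cohort. Arm A scores it with a
#' reference panel drawn from the admixed population itself; arm B scores
#' it with a panel from one of its source populations — the classic
#' situation of standing in a homogeneous continental panel for an
#' admixed GWAS cohort. By default arm B uses the source with the
#' longer-range LD profile, the configuration in which the windowed panel
#' scores overstate the admixed cohort's local LD and heritability is
#' pulled downward.
#'
#' @param template A [scenario()] whose `pop2` is an [admixed_spec()].
#' @param panel_source `"b"` or `"a"`: which source population supplies
#'   the arm-B panel.
#' @return List with `own_panel`, `source_panel` (both `eval_report`s),
#'   `shift`, `pairs`, `failures`.
#' @export
admixture_experiment <- function(template, panel_source = c("b", "a")) {
  panel_source <- match.arg(panel_source)
  stopifnot(inherits(template, "scenario"))
  if (!inherits(template$pop2, "admixed_spec"))
    stop("template$pop2 must be an admixed_spec", call. = FALSE)
  fits_own <- vector("list", template$n_replicates)
  fits_src <- vector("list", template$n_replicates)
  failures <- character(0)
  for (r in seq_len(template$n_replicates)) {
    res <- tryCatch(
      sim_replicate(template, replicate_seed(template$base_seed, r),
                    admix_source_arm = TRUE, admix_source = panel_source),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("replicate %d: %s", r, conditionMessage(res)))
    } else {
      fits_own[[r]] <- res$fit
      fits_src[[r]] <- res$fit_source_panel
    }
  }
  truth <- list(h1_sq = template$h1_sq, h2_sq = template$h2_sq,
                rho_ge = template$rho_ge)
  rep_own <- summarize_replicates(fits_own, truth = truth)
  rep_src <- summarize_replicates(fits_src, truth = truth)
  pairs <- merge(rep_own$per_replicate, rep_src$per_replicate,
                 by = "replicate", suffixes = c("_own", "_source"))
  list(own_panel = rep_own, source_panel = rep_src,
       shift = rep_src$bias - rep_own$bias, pairs = pairs,
       failures = failures)
}

#' Read a scenario from a YAML configuration file
#'
#' Expected keys: `pop1`/`pop2` (each `label`, `fst`, `ld_rho`), or
#' `admixed` (with `source_a`, `source_b`, `prop`, `block_len`) in place
#' of `pop2`; `n1`, `n2`, `m_snps`, `panel_size`; optional `arch`
#' (`h1_sq`, `h2_sq`, `rho_ge`, `p_causal`, `effect_scale`), `qc` (`f0`),
#' `window`, `n_replicates`, `base_seed`.
#'
#' @param path YAML file path.
#' @return A `scenario` object.
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_model <- function(x) population_model(x$label %||% "pop",
                                           fst = x$fst, ld_rho = x$ld_rho)
  pop1 <- as_model(cfg$pop1)
  pop2 <- if (!is.null(cfg$admixed)) {
    a <- cfg$admixed
    admixed_spec(source_a = as_model(a$source_a),
                 source_b = as_model(a$source_b),
                 prop = a$prop %||% 0.8,
                 block_len = a$block_len %||% 50,
                 concentration = a$concentration %||% 6,
                 n_source = a$n_source %||% 2000,
                 label = a$label %||% "ADM")
  } else as_model(cfg$pop2)
  arch <- cfg$arch %||% list()
  scenario(pop1 = pop1, pop2 = pop2, n1 = cfg$n1, n2 = cfg$n2,
           m_snps = cfg$m_snps, panel_size = cfg$panel_size,
           h1_sq = arch$h1_sq %||% 0.5, h2_sq = arch$h2_sq %||% 0.5,
           rho_ge = arch$rho_ge %||% 0.5,
           p_causal = arch$p_causal %||% 0.99,
           effect_scale = arch$effect_scale %||% "standardized",
           f0 = (cfg$qc %||% list())$f0 %||% 0.01,
           window = cfg$window %||% 100,
           n_replicates = cfg$n_replicates %||% 30,
           base_seed = cfg$base_seed %||% 1)
}
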