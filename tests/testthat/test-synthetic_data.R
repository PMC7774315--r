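scenario_two_samples <- function(seed = 1, cv = 0, supp = c(1, 1),
                                 ion = c(1, 1), n_replicates = 1L) {
  simulation_config(
    seed = seed,
    samples = data.frame(sample_id = c("a", "b"),
                         digestion_suppression = supp,
                         ionization_factor = ion,
                         stringsAsFactors = FALSE),
    true_abundance = cbind(ELAAVPSR = c(6e4, 3e4), TYMVR = c(4e4, 1e4)),
    proteins = c(A = "ELAAVPSR", B = "TYMVR"),
    replicate_cv = cv, n_replicates = n_replicates)
}

test_that("noise-free, distortion-free simulation reproduces the truth exactly", {
  tab <- simulate_measurements(scenario_two_samples())
  get <- function(s, a) tab$peak_area[tab$sample_id == s & tab$analyte_id == a]
  expect_equal(get("a", "ELAAVPSR"), 6e4)
  expect_equal(get("b", "TYMVR"), 1e4)
  expect_equal(get("a", "IS"), 1e5)
  expect_equal(get("a", "bLG"), 5e5)
})

test_that("digestion suppression spares the internal standard", {
  cfg <- scenario_two_samples(supp = c(0.09, 0.63))
  tab <- simulate_measurements(cfg)
  get <- function(s, a) tab$peak_area[tab$sample_id == s & tab$analyte_id == a]
  # bLG loses 91% in the strongly suppressed sample, IS loses nothing
  expect_equal(matrix_recovery(get("a", "bLG"), 5e5)$loss_pct, 91)
  expect_equal(matrix_recovery(get("a", "IS"), 1e5)$loss_pct, 0)
  expect_equal(matrix_recovery(get("b", "bLG"), 5e5)$loss_pct, 37)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- default_scenario(seed = 42)
  t1 <- simulate_measurements(cfg)
  t2 <- simulate_measurements(cfg)
  expect_identical(t1, t2)
  c1 <- simulate_calibration(cfg)
  expect_identical(c1, simulate_calibration(cfg))
  # a different seed perturbs the noise
  t3 <- simulate_measurements(default_scenario(seed = 43))
  expect_false(identical(t1$peak_area, t3$peak_area))
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_measurements(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("config validation rejects out-of-range factors", {
  expect_error(scenario_two_samples(supp = c(1.2, 1)), "\\[0, 1\\]")
  expect_error(scenario_two_samples(ion = c(0, 1)), "positive")
  expect_error(scenario_two_samples(cv = -0.1), ">= 0")
})

test_that("noiseless calibration simulation recovers the configured line", {
  cfg <- scenario_two_samples()
  cfg$calibration$noise_sd <- 0
  cal <- simulate_calibration(cfg)
  f <- fit_linearity(cal)
  expect_equal(f$a, cfg$calibration$intercept, tolerance = 1e-8)
  expect_equal(f$b, cfg$calibration$slope, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_identical(attr(cal, "n_floored"), 0L)
})

test_that("simulated calibrations stay in the reported linearity regime", {
  # additive noise at the default level keeps R^2 at the published order
  r2 <- vapply(1:25, function(k) {
    cfg <- default_scenario(seed = 100 + k)
    fit_linearity(simulate_calibration(cfg))$r_squared
  }, numeric(1))
  expect_gte(min(r2), 0.9892)
})

test_that("negative simulated areas are floored and flagged", {
  cfg <- scenario_two_samples()
  cfg$calibration <- list(amounts = c(1, 2, 3), slope = 0.1, intercept = 0,
                          noise_sd = 50, replicates = 5L, unit = "pg")
  cal <- simulate_calibration(cfg)
  expect_true(all(cal$peak_area >= 0))
  expect_gt(attr(cal, "n_floored"), 0L)
})

test_that("normalisation exactly undoes pure ionization-stage suppression", {
  cfg <- scenario_two_samples(ion = c(0.7, 1.3))
  tab <- simulate_measurements(cfg)
  norm <- is_normalize(tab, is_reference_area = cfg$is_true_area)
  get <- function(s, a) norm$peak_area[norm$sample_id == s &
                                         norm$analyte_id == a]
  expect_equal(get("a", "ELAAVPSR"), 6e4, tolerance = 1e-12)
  expect_equal(get("b", "TYMVR"), 1e4, tolerance = 1e-12)
})

test_that("recovery experiment reports zero error in the noise-free case", {
  cfg <- scenario_two_samples(ion = c(0.96, 1.04))
  rep <- recovery_experiment(cfg, n_runs = 3)
  expect_equal(rep$median_abs_rel_error, 0, tolerance = 1e-12)
  expect_equal(unique(rep$kendall_tau), 1)
})

test_that("digestion-stage suppression leaves the documented bias", {
  cfg <- scenario_two_samples(supp = c(0.09, 1))
  rep <- recovery_experiment(cfg, n_runs = 2)
  # IS normalisation cannot correct digestion losses: bias = suppression - 1
  expect_equal(unique(round(rep$rel_error[, "a"], 10)), 0.09 - 1)
  expect_equal(unique(round(rep$rel_error[, "b"], 10)), 0)
})

test_that("IS recovery from simulated ionization drift stays in the accepted band", {
  # +/-4% ionization effects with 2% replicate CV: recovery within
  # 92.2-107.6% in at least 95% of runs
  n_runs <- 200
  inside <- logical(n_runs)
  for (k in seq_len(n_runs)) {
    set.seed(5000 + k)
    cfg <- simulation_config(
      seed = 5000 + k,
      samples = data.frame(sample_id = "s",
                           digestion_suppression = 1,
                           ionization_factor = runif(1, 0.96, 1.04)),
      true_abundance = cbind(ELAAVPSR = 1e4),
      proteins = c(A = "ELAAVPSR"),
      replicate_cv = 0.02, n_replicates = 3L)
    tab <- simulate_measurements(cfg)
    samples <- data.frame(sample_id = "s", day = 1,
                          peak_area = tab$peak_area[tab$analyte_id == "IS"])
    set.seed(9000 + k)
    sigma <- sqrt(log(1 + 0.02^2))
    water_ref <- cfg$is_true_area * rlnorm(3, -sigma^2 / 2, sigma)
    rec <- is_recovery(samples, reference = water_ref)
    inside[k] <- rec$range[["min"]] >= 92.2 && rec$range[["max"]] <= 107.6
  }
  expect_gte(mean(inside), 0.95)
})

test_that("scenario files round-trip through YAML", {
  cfg <- default_scenario(seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(cfg, path)
  back <- read_scenario(path)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$samples, cfg$samples)
  expect_equal(back$true_abundance, cfg$true_abundance,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$proteins, cfg$proteins)
  expect_identical(simulate_measurements(back), simulate_measurements(cfg))
  expect_error(read_scenario(withr::local_tempfile(fileext = ".yaml",
                                                   lines = "seed: 1")),
               "samples")
})
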