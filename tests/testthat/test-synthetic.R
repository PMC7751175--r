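test_that("default isoform profiles encode the category orderings", {
  p <- make_isoform_profiles()
  expect_equal(nrow(p), 14)
  checks <- check_profile_orderings(p)
  expect_true(all(checks))
  expect_false(attr(checks, "degenerate"))
  # determinism and seeded jitter reproducibility
  expect_identical(make_isoform_profiles(seed = 3),
                   make_isoform_profiles(seed = 3))
  j1 <- make_isoform_profiles(seed = 3, jitter_cv = 0.05)
  j2 <- make_isoform_profiles(seed = 3, jitter_cv = 0.05)
  expect_identical(j1, j2)
  expect_false(identical(j1$kcat, make_isoform_profiles()$kcat))
})

test_that("profile overrides are applied and validated", {
  o <- make_isoform_profiles(overrides = data.frame(isoform_id = 2,
                                                    kcat = 99))
  expect_equal(o$kcat[o$isoform_id == 2], 99)
  expect_error(make_isoform_profiles(
    overrides = data.frame(isoform_id = 2, kcat = -1)), "positive")
  expect_error(make_isoform_profiles(
    overrides = data.frame(isoform_id = 77, kcat = 1)), "unknown")
  # all categories identical -> orderings flagged degenerate
  same <- make_isoform_profiles(overrides = data.frame(
    isoform_id = 1:14, kcat = 10, km_pep = 100, km_hco3 = 50,
    ki_malate = 5, ki_aspartate = 5))
  expect_true(attr(check_profile_orderings(same), "degenerate"))
})

test_that("zero-noise simulation reproduces the rate law exactly", {
  prof <- make_isoform_profiles()[1, ]
  des <- assay_design(n_runs = 1, n_technical_reps = 1,
                      residual_hco3_true = 0, run_scale_factors = 1,
                      noise_cv = 0, noise_sd = 0,
                      include_zero_hco3 = FALSE, include_blanks = FALSE,
                      inhibitor_levels = list())
  pts <- simulate_rates(des, prof, seed = 1)
  truth <- kinetic_params(prof$kcat * des$enzyme_conc / 1000,
                          prof$km_pep, prof$km_hco3)
  expect_equal(pts$rate_uM_per_s,
               eval_rate(truth, pts$pep_uM, pts$hco3_uM),
               tolerance = 1e-12)
})

test_that("simulation is byte-identical for a fixed seed", {
  prof <- make_isoform_profiles()[4, ]
  des <- assay_design(n_runs = 2, n_technical_reps = 2)
  a <- simulate_rates(des, prof, seed = 123)
  b <- simulate_rates(des, prof, seed = 123)
  expect_identical(a, b)
  c <- simulate_rates(des, prof, seed = 124)
  expect_false(identical(a$rate_uM_per_s, c$rate_uM_per_s))
})

test_that("technical replicate means converge to the noiseless rate", {
  prof <- make_isoform_profiles()[1, ]
  des <- assay_design(pep_levels = 200, hco3_levels = 1000,
                      inhibitor_levels = list(), n_runs = 1,
                      n_technical_reps = 10000, residual_hco3_true = 0,
                      run_scale_factors = 1, noise_cv = 0.05,
                      noise_sd = 5e-4, include_zero_hco3 = FALSE,
                      include_blanks = FALSE)
  pts <- simulate_rates(des, prof, seed = 2024)
  truth <- eval_rate(kinetic_params(prof$kcat * 4 / 1000, prof$km_pep,
                                    prof$km_hco3), 200, 1000)
  se <- sqrt((truth * 0.05)^2 + (5e-4)^2) / sqrt(nrow(pts))
  expect_lt(abs(mean(pts$rate_uM_per_s) - truth), 4 * se)
})

test_that("absorbance traces follow Beer-Lambert", {
  # 1 uM NADH consumed over the trace at eps = 6220 /M/cm, l = 1 cm
  tr <- simulate_trace(rate = 1 / 900, duration = 900, nadh0 = 200)
  expect_equal(tr$a340[1] - tr$a340[nrow(tr)], 6.22e-3, tolerance = 1e-9)
  flat <- simulate_trace(rate = 0, blank_rate = 0, noise_sd = 0)
  expect_equal(length(unique(flat$a340)), 1L)
  n1 <- simulate_trace(rate = 0.01, noise_sd = 1e-4, seed = 5)
  n2 <- simulate_trace(rate = 0.01, noise_sd = 1e-4, seed = 5)
  expect_identical(n1, n2)
  expect_warning(simulate_trace(rate = 1, duration = 900, nadh0 = 100),
                 "exhausted")
})

test_that("initial rates are extracted, blank-corrected and calibrated", {
  r <- 0.02
  tr <- simulate_trace(rate = r, duration = 600)
  expect_equal(extract_initial_rate(tr), r, tolerance = 1e-6)

  # paired blank removes the background oxidation rate
  b <- 0.004
  tr2 <- simulate_trace(rate = r, blank_rate = b, duration = 600)
  blank <- simulate_trace(rate = 0, blank_rate = b, duration = 600)
  expect_equal(extract_initial_rate(tr2, blank_trace = blank), r,
               tolerance = 1e-6)

  # slope of -0.009 A/min at eps*l = 6.22e-3 A/uM -> 0.02412 uM/s
  slope_per_s <- -0.009 / 60
  tt <- 0:120
  synth <- data.frame(time = tt, a340 = 1 + slope_per_s * tt)
  cal <- calibrate_nadh(c(0, 50, 100, 200), 6.22e-3 * c(0, 50, 100, 200))
  expect_equal(extract_initial_rate(synth, window = 120,
                                    calibration = cal),
               0.0241158, tolerance = 1e-4)

  short <- data.frame(time = 0:3, a340 = rep(1, 4))
  expect_error(extract_initial_rate(short, window = 3,
                                    calibration = cal), "window too short")
  # strong curvature triggers a nonlinearity warning
  curved <- data.frame(time = tt, a340 = 1 - 1e-4 * tt^2)
  attr(curved, "epsilon") <- 6220; attr(curved, "path_length") <- 1
  expect_warning(extract_initial_rate(curved, window = 120), "nonlinear")
})

test_that("NADH standard curves recover slope and planted intercept", {
  conc <- c(10, 50, 100, 150, 200)
  cal <- calibrate_nadh(conc, 6.22e-3 * conc)
  expect_equal(cal$slope, 6.22e-3, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  cal2 <- calibrate_nadh(conc, 0.05 + 6.22e-3 * conc)
  expect_equal(cal2$intercept, 0.05, tolerance = 1e-9)
  expect_error(calibrate_nadh(rep(100, 4), 1:4), ">= 3 distinct")
})

test_that("trace simulation round-trips through fitting", {
  prof <- make_isoform_profiles()[1, ]
  des <- noiseless_design()
  pts <- simulate_rates(des, prof, seed = 3)
  # re-measure every well through a simulated trace and refit
  pts$rate_uM_per_s <- vapply(pts$rate_uM_per_s, function(r) {
    extract_initial_rate(simulate_trace(rate = r, duration = 300))
  }, numeric(1))
  fit <- fit_bisubstrate(pts)
  expect_lt(rel_err(fit$params$kcat, prof$kcat), 1e-3)
  expect_lt(rel_err(fit$params$km_pep, prof$km_pep), 1e-3)
  expect_lt(rel_err(fit$params$km_hco3, prof$km_hco3), 1e-3)
})
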