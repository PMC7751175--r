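test_that("noiseless grid data are recovered exactly", {
  prof <- make_isoform_profiles()[2, ]
  pts <- simulate_rates(noiseless_design(), prof, seed = 1)
  fit <- fit_bisubstrate(pts)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$params$kcat, prof$kcat), 1e-4)
  expect_lt(rel_err(fit$params$km_pep, prof$km_pep), 1e-4)
  expect_lt(rel_err(fit$params$km_hco3, prof$km_hco3), 1e-4)
  expect_equal(unname(fit$run_factors), 1)
})

test_that("a planted per-run activity factor is recovered", {
  prof <- make_isoform_profiles()[1, ]
  pts <- simulate_rates(noiseless_design(), prof, seed = 1)
  pts2 <- pts
  pts2$run_id <- "run02"
  pts2$rate_uM_per_s <- pts2$rate_uM_per_s * 1.2
  fit <- fit_bisubstrate(rbind(pts, pts2))
  expect_equal(fit$run_factors[["run01"]], 1)
  expect_lt(abs(fit$run_factors[["run02"]] - 1.2), 1e-3)
  expect_lt(rel_err(fit$params$kcat, prof$kcat), 1e-4)
})

test_that("residual bicarbonate is estimated jointly and standalone", {
  prof <- make_isoform_profiles()[1, ]
  des <- assay_design(inhibitor_levels = list(), n_runs = 1,
                      n_technical_reps = 1, residual_hco3_true = 30,
                      run_scale_factors = 1, noise_cv = 0, noise_sd = 0,
                      include_blanks = FALSE)
  pts <- simulate_rates(des, prof, seed = 1)
  fit <- fit_bisubstrate(pts)
  expect_lt(abs(fit$residual_hco3 - 30), 0.1)
  expect_lt(rel_err(fit$params$km_hco3, prof$km_hco3), 1e-3)

  # standalone 1-D estimation given the true parameters
  et_uM <- des$enzyme_conc / 1000
  truth <- kinetic_params(prof$kcat * et_uM, prof$km_pep, prof$km_hco3)
  zb <- pts[pts$hco3_uM == 0, ]
  expect_lt(abs(estimate_residual_bicarbonate(zb, truth) - 30), 0.1)

  # zero observed rates -> zero background
  zb0 <- zb
  zb0$rate_uM_per_s <- 0
  expect_equal(estimate_residual_bicarbonate(zb0, truth), 0)

  # two-stage option agrees with the joint estimate on clean data
  fit2 <- fit_bisubstrate(pts, two_stage = TRUE)
  expect_lt(abs(fit2$residual_hco3 - 30), 0.5)

  expect_warning(
    b <- estimate_residual_bicarbonate(pts[pts$hco3_uM > 0, ][1:3, ], truth),
    "no wells")
  expect_equal(b, 0)
})

test_that("residual bicarbonate survives 2 percent noise", {
  prof <- make_isoform_profiles()[1, ]
  et_uM <- 4 / 1000
  truth <- kinetic_params(prof$kcat * et_uM, prof$km_pep, prof$km_hco3)
  errs <- vapply(1:20, function(s) {
    des <- assay_design(inhibitor_levels = list(), n_runs = 1,
                        n_technical_reps = 3, residual_hco3_true = 30,
                        run_scale_factors = 1, noise_cv = 0.02,
                        noise_sd = 0, include_blanks = FALSE)
    pts <- simulate_rates(des, prof, seed = 100 + s)
    b0 <- estimate_residual_bicarbonate(pts[pts$hco3_uM == 0, ], truth)
    abs(b0 - 30) / 30
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("estimates are equivariant to rescaling all rates", {
  prof <- make_isoform_profiles()[3, ]
  pts <- simulate_rates(noiseless_design(), prof, seed = 5)
  f1 <- fit_bisubstrate(pts)
  pts2 <- pts
  pts2$rate_uM_per_s <- pts2$rate_uM_per_s * 37.5
  f2 <- fit_bisubstrate(pts2)
  expect_lt(rel_err(f2$params$km_pep, f1$params$km_pep), 1e-6)
  expect_lt(rel_err(f2$params$km_hco3, f1$params$km_hco3), 1e-6)
  expect_lt(rel_err(f2$params$vmax, 37.5 * f1$params$vmax), 1e-6)
})

test_that("standard errors shrink as replication grows", {
  prof <- make_isoform_profiles()[1, ]
  mean_se <- function(n_reps) {
    ses <- vapply(1:3, function(s) {
      des <- assay_design(inhibitor_levels = list(), n_runs = 1,
                          n_technical_reps = n_reps,
                          residual_hco3_true = 0, run_scale_factors = 1,
                          noise_cv = 0.05, noise_sd = 5e-4,
                          include_zero_hco3 = FALSE,
                          include_blanks = FALSE)
      pts <- simulate_rates(des, prof, seed = 300 + s)
      f <- fit_bisubstrate(pts)
      c(f$params$se_km_pep, f$params$se_km_hco3)
    }, numeric(2))
    rowMeans(ses)
  }
  lo <- mean_se(2)
  hi <- mean_se(10)
  expect_true(all(hi < lo))
})

test_that("degenerate designs and inhibited data are rejected", {
  prof <- make_isoform_profiles()[1, ]
  pts <- simulate_rates(noiseless_design(), prof, seed = 1)
  one_b <- pts[pts$hco3_uM == 10000, ]
  expect_error(fit_bisubstrate(one_b), "non-identifiable")
  one_a <- pts[pts$pep_uM == 5000, ]
  expect_error(fit_bisubstrate(one_a), "non-identifiable")
  inh <- pts
  inh$inhibitor <- "malate"
  inh$inhibitor_mM <- 5
  expect_error(fit_bisubstrate(inh), "inhibitor-free")
  expect_error(fit_bisubstrate(pts, reference_run = "nope"),
               "reference run")
})

test_that("negative blank-corrected rates are retained, not clipped", {
  prof <- make_isoform_profiles()[1, ]
  pts <- simulate_rates(noiseless_design(), prof, seed = 1)
  pts$rate_uM_per_s[1] <- -1e-4  # low-signal well below the blank
  fit <- fit_bisubstrate(pts)
  expect_equal(fit$n_points, nrow(pts))
  expect_true(fit$converged)
})

test_that("assay tables round-trip through delimited text", {
  prof <- make_isoform_profiles()[1, ]
  des <- assay_design(n_runs = 1, n_technical_reps = 1)
  pts <- simulate_rates(des, prof, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assay_points(pts, path)
  back <- read_assay_points(path)
  expect_equal(back$rate_uM_per_s, pts$rate_uM_per_s, tolerance = 1e-12)
  expect_identical(back$run_id, pts$run_id)
  expect_identical(back$is_blank, pts$is_blank)
  expect_error(validate_assay_points(pts[, -4]), "missing columns")
})
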