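# Seeded synthetic assay data with the statistical structure the fitting
# stages assume: rates from the bi-substrate rate law with per-run activity
# scaling, residual background bicarbonate, competitive inhibition, and
# additive + proportional measurement noise; plus NADH-coupled absorbance
# traces for the initial-rate extraction stage.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs the expression and restores the caller's RNG state,
#' so seeded generators never perturb surrounding randomness.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define a synthetic assay design
#'
#' Defaults mirror a typical PEPC characterization: PEP varied from 10 uM
#' to 5 mM and added bicarbonate from 10 uM to 10 mM on log-spaced grids,
#' inhibition assayed at 10 mM fixed bicarbonate with malate and aspartate
#' between 0 and 25 mM, enzyme at 4 nM (within the 2-9 nM assay range),
#' three independent runs with three technical replicates, a residual
#' background bicarbonate of 30 uM, and 5 percent proportional noise over
#' a small additive floor.
#'
#' @param pep_levels PEP concentrations (uM).
#' @param hco3_levels Added bicarbonate concentrations (uM).
#' @param inhibitor_levels Named list of nonzero inhibitor concentrations
#'   (mM) per inhibitor.
#' @param fixed_hco3_for_inhibition Bicarbonate concentration for the
#'   inhibition series (uM).
#' @param enzyme_conc Total enzyme (nM).
#' @param n_runs Number of independent runs (enzyme preparations).
#' @param n_technical_reps Technical replicates per well.
#' @param residual_hco3_true True background bicarbonate b0 (uM).
#' @param run_scale_factors Per-run multiplicative activity factors;
#'   default cycles 1, 1.1, 0.9, 1.2, 0.85 (first run is the reference).
#' @param noise_cv Proportional noise coefficient of variation (fraction).
#' @param noise_sd Additive noise SD (uM/s).
#' @param include_zero_hco3 Include wells without added bicarbonate (used
#'   to estimate b0).
#' @param include_blanks Include no-enzyme blank wells.
#' @return A list of class \code{assay_design}.
#' @export
assay_design <- function(pep_levels = c(10, 25, 75, 200, 600, 1500, 5000),
                         hco3_levels = c(10, 30, 100, 300, 1000, 3000, 10000),
                         inhibitor_levels = list(
                           malate = c(1, 2.5, 5, 10, 25),
                           aspartate = c(1, 2.5, 5, 10, 25)),
                         fixed_hco3_for_inhibition = 10000,
                         enzyme_conc = 4,
                         n_runs = 3,
                         n_technical_reps = 3,
                         residual_hco3_true = 30,
                         run_scale_factors = NULL,
                         noise_cv = 0.05,
                         noise_sd = 5e-4,
                         include_zero_hco3 = TRUE,
                         include_blanks = TRUE) {
  stopifnot(all(pep_levels > 0), all(hco3_levels > 0),
            n_technical_reps >= 1, n_runs >= 1, enzyme_conc > 0,
            residual_hco3_true >= 0, noise_cv >= 0, noise_sd >= 0)
  if (is.null(run_scale_factors)) {
    run_scale_factors <- rep(c(1, 1.1, 0.9, 1.2, 0.85),
                             length.out = n_runs)
  }
  if (length(run_scale_factors) != n_runs || any(run_scale_factors <= 0)) {
    stop("need one positive scale factor per run")
  }
  structure(list(
    pep_levels = pep_levels, hco3_levels = hco3_levels,
    inhibitor_levels = inhibitor_levels,
    fixed_hco3_for_inhibition = fixed_hco3_for_inhibition,
    enzyme_conc = enzyme_conc, n_runs = n_runs,
    n_technical_reps = n_technical_reps,
    residual_hco3_true = residual_hco3_true,
    run_scale_factors = run_scale_factors,
    noise_cv = noise_cv, noise_sd = noise_sd,
    include_zero_hco3 = include_zero_hco3,
    include_blanks = include_blanks
  ), class = "assay_design")
}

# Default true parameters for the 14 isoforms. Magnitudes are synthetic
# placeholders chosen to encode the qualitative category-level pattern:
# co-opted native enzymes have higher kcat than their non-C4 orthologs
# (1.87x and 2.26x for the two co-opted lineages), laterally acquired
# enzymes have convergent high kcat (>= 1.5x the co-opted natives) and
# high KM(PEP) (>= 1.8x any native, >= 3.1x the replaced co-opted copies)
# and elevated KM(HCO3-), each LGT clustering with its donor; the non-C4
# ppc-1P6 enzyme is least inhibitor-sensitive (largest KI) and the non-C4
# ppc-1P3 enzymes most sensitive (smallest KI).
isoform_defaults <- function() {
  d <- data.frame(
    isoform_id = 1:14,
    accession = c("RSA5-03_P6", "TPE1-10", "P_pygmaeum", "RSA5-03_P3",
                  "MAD1-03", "A_angusta", "M_maximus", "A_cimicina",
                  "TAN4-08", "T_triandra", "AUS1-01", "S_barbata",
                  "RSA3-01", "RSA4-01"),
    lineage = c("Non-C4", "Native co-opted 1", "Non-C4", "Non-C4",
                "Native co-opted 2", "Native co-opted 2", "Donor_M",
                "LGT:M", "LGT:M", "Donor_A", "LGT:A", "Donor_C",
                "LGT:C", "LGT:C"),
    category = c("non-C4", "native co-opted", "non-C4", "non-C4",
                 "native co-opted", "native co-opted", "donor", "LGT",
                 "LGT", "donor", "LGT", "donor", "LGT", "LGT"),
    kcat = c(25, 46.75, 18, 19, 42.94, 55,
             88, 90, 86, 92, 93, 95, 96, 96),
    km_pep = c(70, 55, 45, 48, 50, 85,
               172, 180, 175, 200, 205, 240, 245, 245),
    km_hco3 = c(25, 45, 22, 24, 40, 50,
                120, 130, 115, 180, 185, 250, 255, 255),
    ki_malate = c(15, 4, 1.2, 1.3, 3.0, 5,
                  3.5, 4, 3.8, 4.5, 4.6, 5, 5.2, 5.2),
    ki_aspartate = c(20, 10, 2.0, 2.2, 4.5, 6,
                     5, 5.5, 5.2, 6, 6.2, 6.5, 6.8, 6.8),
    stringsAsFactors = FALSE
  )
  d
}

#' Generate true kinetic profiles for the 14 isoforms
#'
#' Returns one profile per isoform with its lineage, coarse category
#' (non-C4, native co-opted, donor, LGT) and true kinetic parameters
#' (kcat, KM(PEP), KM(HCO3-), KiA.KB, and KI for malate and aspartate).
#' Defaults encode the qualitative fold-change pattern across categories
#' (see \code{\link{check_profile_orderings}}); they are synthetic
#' placeholders, not measured values. An optional seeded lognormal jitter
#' perturbs the defaults reproducibly.
#'
#' @param seed Integer seed (only used when \code{jitter_cv > 0}).
#' @param overrides Optional data.frame with column \code{isoform_id} and
#'   any of \code{kcat, km_pep, km_hco3, ki_malate, ki_aspartate} to
#'   replace defaults.
#' @param jitter_cv Lognormal jitter CV (fraction), default 0
#'   (deterministic defaults).
#' @param kia_kb Fixed KiA.KB (uM^2).
#' @return data.frame of class \code{isoform_profiles}, one row per
#'   isoform.
#' @export
make_isoform_profiles <- function(seed = 1L, overrides = NULL,
                                  jitter_cv = 0, kia_kb = 50) {
  d <- isoform_defaults()
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "isoform_id" %in% names(overrides))
    for (col in intersect(names(overrides),
                          c("kcat", "km_pep", "km_hco3",
                            "ki_malate", "ki_aspartate"))) {
      idx <- match(overrides$isoform_id, d$isoform_id)
      if (anyNA(idx)) stop("unknown isoform_id in overrides")
      d[[col]][idx] <- overrides[[col]]
      if (any(d[[col]] <= 0)) stop("overridden ", col, " must be positive")
    }
  }
  if (jitter_cv > 0) {
    d <- with_seed(seed, {
      for (col in c("kcat", "km_pep", "km_hco3", "ki_malate",
                    "ki_aspartate")) {
        d[[col]] <- d[[col]] * exp(stats::rnorm(nrow(d), 0, jitter_cv))
      }
      d
    })
  }
  d$kia_kb <- kia_kb
  class(d) <- c("isoform_profiles", "data.frame")
  d
}

#' Check category-level orderings of a profile set
#'
#' Asserts the qualitative pattern the defaults encode: every co-opted
#' native kcat exceeds every non-C4 kcat; the smallest LGT kcat is at
#' least 1.5x the largest co-opted native kcat; the smallest LGT KM(PEP)
#' is at least 1.8x the largest native (non-C4 or co-opted) KM(PEP); and
#' the non-C4 ppc-1P6 isoform (isoform 1) has the largest malate and
#' aspartate KI of all isoforms.
#'
#' @param profiles Output of \code{\link{make_isoform_profiles}}.
#' @return Named logical vector of the four checks, with attribute
#'   \code{degenerate} = TRUE when all categories share identical values
#'   (orderings trivially equal).
#' @export
check_profile_orderings <- function(profiles) {
  p <- profiles
  noncop <- p$kcat[p$category == "non-C4"]
  coop <- p$category == "native co-opted"
  lgt <- p$category == "LGT"
  native <- p$category %in% c("non-C4", "native co-opted")
  res <- c(
    kcat_coopted_gt_nonC4 = min(p$kcat[coop]) > max(noncop),
    kcat_lgt_ge_1.5x_coopted = min(p$kcat[lgt]) >= 1.5 * max(p$kcat[coop]),
    km_pep_lgt_ge_1.8x_native = min(p$km_pep[lgt]) >=
      1.8 * max(p$km_pep[native]),
    ki_nonC4_P6_max = all(p$ki_malate[p$isoform_id == 1] >=
                            p$ki_malate[p$isoform_id != 1]) &&
      all(p$ki_aspartate[p$isoform_id == 1] >=
            p$ki_aspartate[p$isoform_id != 1])
  )
  degenerate <- length(unique(round(p$kcat, 12))) == 1L
  attr(res, "degenerate") <- degenerate
  res
}

# competitive inhibition wrt PEP: both KA and KiA.KB scale by (1 + I/KI),
# which makes the secondary-plot relation exact for kcat/KM(PEP)
inhibited_params <- function(profile_row, inhibitor, inhibitor_mM) {
  ki <- switch(inhibitor,
               malate = profile_row$ki_malate,
               aspartate = profile_row$ki_aspartate,
               stop("unknown inhibitor: ", inhibitor))
  fac <- 1 + inhibitor_mM / ki
  list(km_pep = profile_row$km_pep * fac,
       kia_kb = profile_row$kia_kb * fac)
}

#' Simulate a synthetic assay table for one isoform
#'
#' For each run and technical replicate, generates wells over the full
#' PEP x bicarbonate grid (inhibitor-free), optional wells without added
#' bicarbonate, the inhibition series (all PEP levels at the fixed
#' bicarbonate for every inhibitor concentration), and optional no-enzyme
#' blanks. Each observed rate is
#' \deqn{f_{run} \cdot v(A, B + b_0) (1 + \epsilon_{prop}) + \epsilon_{add}}
#' with \eqn{v} the bi-substrate rate law (competitively inhibited when an
#' inhibitor is present), \eqn{\epsilon_{prop} \sim N(0, cv^2)} and
#' \eqn{\epsilon_{add} \sim N(0, sd^2)}. Blank wells contain only additive
#' noise. Output is reproducible for a given seed.
#'
#' @param design An \code{\link{assay_design}}.
#' @param profile One row of \code{\link{make_isoform_profiles}} (or a
#'   data.frame whose first row is used).
#' @param seed Integer seed.
#' @return A validated assay-point data.frame.
#' @export
simulate_rates <- function(design, profile, seed = 1L) {
  stopifnot(inherits(design, "assay_design"))
  profile <- as.data.frame(profile)[1L, , drop = FALSE]
  et_uM <- design$enzyme_conc / 1000
  true_par <- kinetic_params(vmax = profile$kcat * et_uM,
                             km_pep = profile$km_pep,
                             km_hco3 = profile$km_hco3,
                             kia_kb = profile$kia_kb)
  b0 <- design$residual_hco3_true

  grid <- expand.grid(pep_uM = design$pep_levels,
                      hco3_uM = design$hco3_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$inhibitor <- "none"; grid$inhibitor_mM <- 0
  if (design$include_zero_hco3) {
    z <- data.frame(pep_uM = design$pep_levels, hco3_uM = 0,
                    inhibitor = "none", inhibitor_mM = 0)
    grid <- rbind(grid, z)
  }
  for (inh in names(design$inhibitor_levels)) {
    for (lev in design$inhibitor_levels[[inh]]) {
      grid <- rbind(grid, data.frame(
        pep_uM = design$pep_levels,
        hco3_uM = design$fixed_hco3_for_inhibition,
        inhibitor = inh, inhibitor_mM = lev))
    }
  }

  rows <- list()
  with_seed(seed, {
    for (r in seq_len(design$n_runs)) {
      f <- design$run_scale_factors[r]
      for (k in seq_len(design$n_technical_reps)) {
        g <- grid
        v <- numeric(nrow(g))
        plain <- g$inhibitor_mM == 0
        v[plain] <- eval_rate(true_par, g$pep_uM[plain], g$hco3_uM[plain] + b0)
        for (i in which(!plain)) {
          ip <- inhibited_params(profile, g$inhibitor[i], g$inhibitor_mM[i])
          pi <- kinetic_params(vmax = true_par$vmax, km_pep = ip$km_pep,
                               km_hco3 = true_par$km_hco3,
                               kia_kb = ip$kia_kb)
          v[i] <- eval_rate(pi, g$pep_uM[i], g$hco3_uM[i] + b0)
        }
        eps_p <- stats::rnorm(nrow(g), 0, design$noise_cv)
        eps_a <- stats::rnorm(nrow(g), 0, design$noise_sd)
        g$rate_uM_per_s <- f * v * (1 + eps_p) + eps_a
        g$run_id <- sprintf("run%02d", r)
        g$replicate_id <- sprintf("rep%d", k)
        g$enzyme_nM <- design$enzyme_conc
        g$is_blank <- FALSE
        rows[[length(rows) + 1L]] <- g
        if (design$include_blanks) {
          nb <- 3L
          rows[[length(rows) + 1L]] <- data.frame(
            pep_uM = rep(max(design$pep_levels), nb),
            hco3_uM = max(design$hco3_levels),
            inhibitor = "none", inhibitor_mM = 0,
            rate_uM_per_s = stats::rnorm(nb, 0, design$noise_sd),
            run_id = sprintf("run%02d", r),
            replicate_id = sprintf("rep%d", k),
            enzyme_nM = 0, is_blank = TRUE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  out$isoform_id <- as.character(profile$isoform_id)
  validate_assay_points(out[, assay_columns])
}

#' Simulate an NADH-coupled absorbance trace
#'
#' The carboxylation rate is monitored through oxidation of NADH at
#' 340 nm in a coupled assay: absorbance follows Beer-Lambert,
#' \eqn{A_{340}(t) = \epsilon \ell [NADH](t)} + noise, with NADH declining
#' at (rate + blank_rate) until exhaustion.
#'
#' @param rate Enzymatic NADH consumption rate (uM/s).
#' @param duration Trace length (s).
#' @param nadh0 Initial NADH (uM), default 200 (0.2 mM assay mix).
#' @param blank_rate Background NADH oxidation rate (uM/s).
#' @param noise_sd Absorbance noise SD.
#' @param epsilon Molar extinction coefficient (1/M/cm), default 6220.
#' @param path_length Optical path length (cm).
#' @param dt Sampling interval (s).
#' @param seed Seed for the absorbance noise (NULL = no seeding).
#' @return data.frame of class \code{nadh_trace} with columns \code{time}
#'   (s) and \code{a340}; attributes record the simulation constants. A
#'   warning is raised when NADH is exhausted within the trace.
#' @export
simulate_trace <- function(rate, duration = 900, nadh0 = 200,
                           blank_rate = 0, noise_sd = 0,
                           epsilon = 6220, path_length = 1, dt = 1,
                           seed = NULL) {
  stopifnot(nadh0 > 0, duration > 0, dt > 0, rate >= 0, blank_rate >= 0)
  t <- seq(0, duration, by = dt)
  nadh <- pmax(nadh0 - (rate + blank_rate) * t, 0)
  if (any(nadh == 0)) {
    warning("NADH exhausted before the end of the trace")
  }
  eps_uM <- epsilon / 1e6  # absorbance per uM per cm
  a <- eps_uM * path_length * nadh
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(t), 0, noise_sd)
             else with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
    a <- a + noise
  }
  out <- data.frame(time = t, a340 = a)
  attr(out, "epsilon") <- epsilon
  attr(out, "path_length") <- path_length
  class(out) <- c("nadh_trace", "data.frame")
  out
}

#' Fit an NADH standard curve
#'
#' Least-squares line mapping NADH concentration to absorbance, as used to
#' calibrate plate-reader measurements where the effective path length is
#' not known.
#'
#' @param conc Standard concentrations (uM), >= 3 distinct values.
#' @param absorbance Measured absorbances.
#' @return List of class \code{nadh_calibration} with \code{slope}
#'   (absorbance per uM), \code{intercept}, and the calibrated
#'   concentration \code{range}.
#' @export
calibrate_nadh <- function(conc, absorbance) {
  stopifnot(length(conc) == length(absorbance))
  if (length(unique(conc)) < 3L) {
    stop("need >= 3 distinct standard concentrations")
  }
  fit <- stats::lm(absorbance ~ conc)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 range = range(conc)),
            class = "nadh_calibration")
}

#' Extract an initial rate from an absorbance trace
#'
#' Fits a least-squares line to the early part of the trace, converts the
#' absorbance slope to a NADH consumption rate via the calibration (or the
#' trace's Beer-Lambert constants), flips the sign to a positive rate, and
#' subtracts the rate of a paired no-enzyme blank trace when given. A
#' quadratic curvature check warns when the window is visibly nonlinear
#' (early lag or substrate depletion).
#'
#' @param trace A \code{\link{simulate_trace}} output or data.frame with
#'   \code{time} and \code{a340}.
#' @param window Length of the fitting window (s); default the first 10
#'   percent of the trace or the time to 10 percent NADH depletion,
#'   whichever is shorter.
#' @param calibration Optional \code{\link{calibrate_nadh}} result; when
#'   NULL the trace's \code{epsilon} and \code{path_length} attributes are
#'   used.
#' @param blank_trace Optional paired blank trace; its rate is subtracted.
#' @return Rate in uM/s.
#' @export
extract_initial_rate <- function(trace, window = NULL, calibration = NULL,
                                 blank_trace = NULL) {
  stopifnot(all(c("time", "a340") %in% names(trace)))
  slope_per_uM <- if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "nadh_calibration"))
    calibration$slope
  } else {
    eps <- attr(trace, "epsilon"); pl <- attr(trace, "path_length")
    if (is.null(eps) || is.null(pl)) {
      stop("no calibration given and trace lacks Beer-Lambert attributes")
    }
    (eps / 1e6) * pl
  }
  duration <- max(trace$time)
  if (is.null(window)) {
    window <- 0.1 * duration
    # stop before 10% NADH depletion where that comes sooner
    a0 <- trace$a340[1L]
    depleted <- trace$time[trace$a340 <= 0.9 * a0]
    if (length(depleted)) window <- min(window, depleted[1L])
  }
  sel <- trace$time <= window
  if (sum(sel) < 5L) stop("window too short: fewer than 5 samples")
  tt <- trace$time[sel]; aa <- trace$a340[sel]
  fit <- stats::lm(aa ~ tt)
  slope <- unname(stats::coef(fit)[2L])
  # curvature check: quadratic term's contribution over the window
  qfit <- stats::lm(aa ~ tt + I(tt^2))
  q <- unname(stats::coef(qfit)[3L])
  if (is.finite(q) && abs(q) * window^2 > 0.1 * abs(slope) * window +
        .Machine$double.eps) {
    warning("trace appears nonlinear over the fitting window")
  }
  rate <- -slope / slope_per_uM
  if (!is.null(blank_trace)) {
    rate <- rate - extract_initial_rate(blank_trace, window = window,
                                        calibration = calibration)
  }
  rate
}
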