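#' Fit the constrained bi-substrate rate law to inhibitor-free assay data
#'
#' Ordinary (unweighted) nonlinear least squares on blank-corrected rates.
#' Free parameters are \eqn{V_{max}}, \eqn{K_A} = KM(PEP), \eqn{K_B} =
#' KM(HCO3-), one multiplicative activity factor per non-reference run and,
#' when wells without added bicarbonate are present, a residual-bicarbonate
#' offset \eqn{b_0} entering as effective [B] = nominal + \eqn{b_0}. The
#' denominator product \eqn{K_{iA}K_B} is held fixed (default 50 uM^2).
#'
#' The predicted rate of a well in run \eqn{r} is
#' \deqn{f_r \cdot \frac{V_{max} A (B + b_0)}
#'   {A(B+b_0) + K_A (B+b_0) + K_B A + K_{iA}K_B}}
#' with the reference run's factor fixed at 1 for identifiability.
#'
#' Optimization is Levenberg-Marquardt (\code{minpack.lm::nls.lm}) on
#' log-scale kinetic parameters and run factors (so all stay positive) and
#' a square-root scale offset (so \eqn{b_0 \ge 0}), multi-started from five
#' deterministic initial guesses derived from data quantiles; the start
#' with the lowest final residual sum of squares wins, ties broken by
#' start index. Standard errors come from the Gauss-Newton approximation
#' to the curvature at the optimum on the natural parameter scale, scaled
#' by the residual variance.
#'
#' @param points Assay-point data.frame (see
#'   \code{\link{validate_assay_points}}); must be inhibitor-free, contain
#'   at least two distinct PEP and two distinct added-bicarbonate levels,
#'   and blank wells are dropped before fitting.
#' @param kia_kb Fixed \eqn{K_{iA}K_B} (uM^2), default 50.
#' @param reference_run run_id whose activity factor is fixed at 1;
#'   default the lexicographically first run.
#' @param estimate_b0 \code{"auto"} (estimate when no-added-bicarbonate
#'   wells exist), \code{TRUE} or \code{FALSE}.
#' @param two_stage If TRUE, estimate \eqn{b_0} beforehand from the
#'   zero-bicarbonate wells with provisional parameters and hold it fixed
#'   in the main fit, instead of estimating it jointly (the default).
#' @param b0_start Starting value for the residual-bicarbonate offset (uM).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#'
#' @return An object of class \code{fit_result}: list with \code{params}
#'   (a \code{\link{kinetic_params}} with kcat, efficiencies and SEs),
#'   \code{run_factors} (named, reference exactly 1), \code{residual_hco3}
#'   (uM), \code{rss}, \code{n_points}, \code{converged}, \code{enzyme_nM}
#'   and \code{se_vmax}.
#' @export
fit_bisubstrate <- function(points, kia_kb = 50, reference_run = NULL,
                            estimate_b0 = "auto", two_stage = FALSE,
                            b0_start = 10, max_iter = 200) {
  points <- validate_assay_points(points)
  points <- points[!points$is_blank, , drop = FALSE]
  if (any(points$inhibitor_mM > 0 &
          tolower(points$inhibitor) != "none")) {
    stop("fit_bisubstrate expects inhibitor-free data")
  }
  zero_b <- points$hco3_uM == 0
  fitpts <- points
  if (length(unique(fitpts$pep_uM)) < 2L ||
      length(unique(fitpts$hco3_uM[!zero_b])) < 2L) {
    stop("non-identifiable design: need >= 2 distinct PEP and ",
         ">= 2 distinct added-bicarbonate levels")
  }

  runs <- sort(unique(fitpts$run_id))
  if (is.null(reference_run)) reference_run <- runs[1L]
  if (!reference_run %in% runs) stop("reference run not present: ",
                                     reference_run)
  free_runs <- setdiff(runs, reference_run)

  if (identical(estimate_b0, "auto")) estimate_b0 <- any(zero_b)
  if (estimate_b0 && !any(zero_b)) {
    warning("no wells without added bicarbonate; b0 fixed at 0")
    estimate_b0 <- FALSE
  }

  A <- fitpts$pep_uM
  Bn <- fitpts$hco3_uM
  obs <- fitpts$rate_uM_per_s
  run_idx <- match(fitpts$run_id, runs)
  ref_idx <- match(reference_run, runs)

  # theta layout: log Vmax, log KA, log KB, log f (free runs), sqrt(b0)
  n_free_f <- length(free_runs)
  joint_b0 <- estimate_b0 && !two_stage
  b0_fixed <- 0

  predict_nat <- function(vmax, ka, kb, fvec, b0) {
    Beff <- Bn + b0
    denom <- A * Beff + ka * Beff + kb * A + kia_kb
    fvec[run_idx] * vmax * A * Beff / denom
  }
  unpack <- function(theta) {
    vmax <- exp(theta[1L]); ka <- exp(theta[2L]); kb <- exp(theta[3L])
    fvec <- rep(1, length(runs))
    if (n_free_f)
      fvec[match(free_runs, runs)] <- exp(theta[3L + seq_len(n_free_f)])
    b0 <- if (joint_b0) theta[3L + n_free_f + 1L]^2 else b0_fixed
    list(vmax = vmax, ka = ka, kb = kb, fvec = fvec, b0 = b0)
  }
  resid_fn <- function(theta) {
    p <- unpack(theta)
    obs - predict_nat(p$vmax, p$ka, p$kb, p$fvec, p$b0)
  }

  if (two_stage && estimate_b0) {
    # alternate between fitting with b0 held fixed and re-estimating b0
    # from the zero-bicarbonate wells (coordinate descent on the same
    # objective the joint fit minimizes)
    pos <- fitpts[!zero_b, , drop = FALSE]
    b0_fixed <- 0
    for (it in 1:40) {
      pos_b <- pos
      pos_b$hco3_uM <- pos_b$hco3_uM + b0_fixed
      prov <- fit_bisubstrate(pos_b, kia_kb = kia_kb,
                              reference_run = reference_run,
                              estimate_b0 = FALSE, max_iter = max_iter)
      b0_new <- suppressWarnings(estimate_residual_bicarbonate(
        fitpts[zero_b, , drop = FALSE], prov$params))
      if (abs(b0_new - b0_fixed) < 1e-3) {
        b0_fixed <- b0_new
        break
      }
      b0_fixed <- b0_new
    }
  }

  vq <- max(obs)
  pepq <- stats::quantile(A[A > 0], c(0.1, 0.25, 0.5, 0.75, 0.9),
                          names = FALSE)
  bq <- stats::quantile(Bn[Bn > 0], c(0.1, 0.25, 0.5, 0.75, 0.9),
                        names = FALSE)
  starts <- list(
    c(1.20 * vq, pepq[3], bq[3]),
    c(1.05 * vq, pepq[2], bq[2]),
    c(2.00 * vq, pepq[4], bq[4]),
    c(1.50 * vq, pepq[1], bq[5]),
    c(3.00 * vq, pepq[5], bq[1])
  )

  best <- NULL
  for (i in seq_along(starts)) {
    s <- starts[[i]]
    theta0 <- c(log(s), rep(0, n_free_f),
                if (joint_b0) sqrt(b0_start) else NULL)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, maxfev = 5000L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss, start = i)
    }
  }
  if (is.null(best)) {
    stop("all optimization starts failed")
  }
  fit <- best$fit
  converged <- fit$info %in% 1:4
  p <- unpack(fit$par)

  # Gauss-Newton curvature on the natural scale (Vmax, KA, KB, f_r, b0)
  nat <- c(p$vmax, p$ka, p$kb,
           if (n_free_f) p$fvec[match(free_runs, runs)] else NULL,
           if (joint_b0) p$b0 else NULL)
  pred_nat_vec <- function(nat) {
    fvec <- rep(1, length(runs))
    if (n_free_f) fvec[match(free_runs, runs)] <- nat[3L + seq_len(n_free_f)]
    b0 <- if (joint_b0) nat[3L + n_free_f + 1L] else b0_fixed
    predict_nat(nat[1L], nat[2L], nat[3L], fvec, b0)
  }
  J <- numeric_jacobian(pred_nat_vec, nat)
  n <- length(obs); npar <- length(nat)
  sigma2 <- best$rss / max(n - npar, 1L)
  covm <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  ses <- if (is.null(covm)) rep(NA_real_, npar) else sqrt(pmax(diag(covm), 0))

  et_nM <- unique(fitpts$enzyme_nM[fitpts$enzyme_nM > 0])
  et_nM <- if (length(et_nM)) mean(fitpts$enzyme_nM[fitpts$enzyme_nM > 0])
           else NA_real_
  kcat <- if (is.na(et_nM)) NA_real_ else kcat_from_vmax(p$vmax, et_nM)
  se_kcat <- if (is.na(et_nM)) NA_real_ else ses[1L] / (et_nM / 1000)

  params <- kinetic_params(vmax = p$vmax, km_pep = p$ka, km_hco3 = p$kb,
                           kia_kb = kia_kb, kcat = kcat,
                           se_kcat = se_kcat, se_km_pep = ses[2L],
                           se_km_hco3 = ses[3L])
  rf <- stats::setNames(p$fvec, runs)
  rf[reference_run] <- 1
  structure(list(
    params = params,
    run_factors = rf,
    reference_run = reference_run,
    residual_hco3 = if (estimate_b0) (if (two_stage) b0_fixed else p$b0)
                    else 0,
    rss = best$rss,
    n_points = n,
    converged = converged,
    start_index = best$start,
    enzyme_nM = et_nM,
    se_vmax = ses[1L]
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Bi-substrate fit:", x$n_points, "points, RSS =",
      format(x$rss, digits = 4),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(x$params)
  if (length(x$run_factors) > 1L) {
    cat("  Run factors (reference", x$reference_run, "= 1):\n")
    for (r in names(x$run_factors)) {
      cat(sprintf("    %s: %.4g\n", r, x$run_factors[[r]]))
    }
  }
  cat(sprintf("  Residual bicarbonate b0: %.4g uM\n", x$residual_hco3))
  invisible(x)
}

#' Estimate residual background bicarbonate from no-added-bicarbonate wells
#'
#' Bicarbonate is removed from assay buffers by sparging, but a residual
#' background remains; it is determined from wells assayed without added
#' bicarbonate. Given provisional kinetic parameters, finds the offset
#' \eqn{b_0 \ge 0} minimizing the squared deviation between the observed
#' rates and the rate law evaluated at effective [B] = \eqn{b_0}.
#'
#' @param points Assay points with \code{hco3_uM == 0} (others are
#'   dropped with a warning).
#' @param params Provisional \code{\link{kinetic_params}}.
#' @param upper Upper bound of the search interval (uM), default 10000.
#' @return Estimated \eqn{b_0} in uM (0 when no qualifying wells, with a
#'   warning).
#' @export
estimate_residual_bicarbonate <- function(points, params, upper = 1e4) {
  points <- validate_assay_points(points)
  points <- points[!points$is_blank & points$hco3_uM == 0, , drop = FALSE]
  if (nrow(points) == 0L) {
    warning("no wells without added bicarbonate; returning b0 = 0")
    return(0)
  }
  obj <- function(b0) {
    sum((points$rate_uM_per_s - eval_rate(params, points$pep_uM, b0))^2)
  }
  if (obj(0) <= .Machine$double.eps) return(0)
  opt <- stats::optimize(obj, interval = c(0, upper), tol = 1e-6)
  # optimize() never returns the boundary; accept 0 when it is at least as good
  if (obj(0) <= opt$objective) 0 else opt$minimum
}

# central-difference Jacobian of a vector-valued function
#' @keywords internal
numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1e-8)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
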