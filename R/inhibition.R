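#' Fit a single-substrate Michaelis-Menten hyperbola
#'
#' Least-squares fit of \eqn{v = V^{app} A / (K^{app} + A)} to rate-vs-PEP
#' data at one fixed bicarbonate and inhibitor condition. Used as the
#' primary fit behind each point of an inhibition secondary plot.
#'
#' @param pep PEP concentrations (uM).
#' @param rate Observed rates (uM/s).
#' @return List with \code{vmax_app}, \code{km_app}, their SEs (from the
#'   Gauss-Newton curvature), the parameter covariance matrix \code{cov},
#'   \code{rss} and \code{converged}.
#' @export
fit_michaelis <- function(pep, rate) {
  stopifnot(length(pep) == length(rate), all(pep >= 0))
  if (length(unique(pep)) < 2L) stop("need >= 2 distinct PEP levels")
  if (all(rate <= 0)) {
    return(list(vmax_app = 0, km_app = NA_real_, se_vmax_app = NA_real_,
                se_km_app = NA_real_, cov = NULL, rss = sum(rate^2),
                converged = FALSE, degenerate = TRUE))
  }
  resid_fn <- function(theta) {
    v <- exp(theta[1L]); k <- exp(theta[2L])
    rate - v * pep / (k + pep)
  }
  starts <- list(c(1.2 * max(rate), stats::median(pep)),
                 c(1.05 * max(rate), stats::quantile(pep, 0.25, names = FALSE)),
                 c(2 * max(rate), stats::quantile(pep, 0.75, names = FALSE)))
  best <- NULL
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(starts[[i]]), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit,
                                                              rss = rss)
  }
  if (is.null(best)) stop("hyperbola fit failed")
  v <- exp(best$fit$par[1L]); k <- exp(best$fit$par[2L])
  J <- numeric_jacobian(function(p) p[1L] * pep / (p[2L] + pep), c(v, k))
  sigma2 <- best$rss / max(length(rate) - 2L, 1L)
  covm <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  ses <- if (is.null(covm)) c(NA_real_, NA_real_) else sqrt(pmax(diag(covm), 0))
  list(vmax_app = v, km_app = k, se_vmax_app = ses[1L], se_km_app = ses[2L],
       cov = covm, rss = best$rss, converged = best$fit$info %in% 1:4,
       degenerate = FALSE)
}

#' Apparent catalytic efficiency at one inhibitor concentration
#'
#' Fits a Michaelis-Menten hyperbola in PEP to the wells sharing one
#' inhibitor concentration and one fixed bicarbonate concentration, then
#' returns the apparent catalytic efficiency
#' \eqn{(k_{cat}/K_m)^{app} = (V^{app}/[E]_T)/K^{app}} with a standard
#' error propagated (first order) from the hyperbola fit's covariance.
#'
#' @param points Assay points all sharing one \code{inhibitor_mM} and one
#'   \code{hco3_uM}; at least 4 distinct PEP levels.
#' @return List with \code{inhibitor}, \code{inhibitor_mM},
#'   \code{efficiency} (1/s/uM), \code{se}, \code{kcat_app},
#'   \code{km_app}, \code{n_points} and \code{degenerate}.
#' @export
apparent_efficiency_at_inhibitor <- function(points) {
  points <- validate_assay_points(points)
  points <- points[!points$is_blank, , drop = FALSE]
  if (length(unique(points$inhibitor_mM)) != 1L ||
      length(unique(points$hco3_uM)) != 1L) {
    stop("points must share a single inhibitor concentration and a single ",
         "fixed bicarbonate concentration")
  }
  if (length(unique(points$pep_uM)) < 4L) {
    stop("design error: need >= 4 distinct PEP levels")
  }
  et_uM <- mean(points$enzyme_nM) / 1000
  if (et_uM <= 0) stop("enzyme concentration must be positive")
  mm <- fit_michaelis(points$pep_uM, points$rate_uM_per_s)
  if (isTRUE(mm$degenerate)) {
    return(list(inhibitor = points$inhibitor[1L],
                inhibitor_mM = points$inhibitor_mM[1L],
                efficiency = 0, se = NA_real_, kcat_app = 0,
                km_app = NA_real_, n_points = nrow(points),
                degenerate = TRUE))
  }
  kcat_app <- mm$vmax_app / et_uM
  eff <- kcat_app / mm$km_app
  se <- NA_real_
  if (!is.null(mm$cov)) {
    # eff = (V/ET)/K; gradient wrt (V, K)
    g <- c(1 / (et_uM * mm$km_app), -mm$vmax_app / (et_uM * mm$km_app^2))
    se <- sqrt(max(drop(t(g) %*% mm$cov %*% g), 0))
  }
  list(inhibitor = points$inhibitor[1L],
       inhibitor_mM = points$inhibitor_mM[1L],
       efficiency = eff, se = se, kcat_app = kcat_app, km_app = mm$km_app,
       n_points = nrow(points), degenerate = FALSE)
}

#' Fit an inhibition constant from a secondary plot
#'
#' Least-squares fit of the competitive-inhibition secondary-plot model
#' \deqn{(k_{cat}/K_m)^{app} = \frac{k_{cat}/K_m}{1 + [I]/K_I}}
#' to a series of apparent efficiencies measured at increasing inhibitor
#' concentrations. The series must include \eqn{[I] = 0}. An optional
#' inverse-variance weighting uses the per-point SEs.
#'
#' When the series shows no decline (the unconstrained \eqn{K_I} estimate
#' diverges), the fit is flagged \code{unbounded} and \code{ki} is
#' \code{Inf}, with \code{ki_lower} giving a rough lower bound: the
#' smallest \eqn{K_I} whose best-fitting curve stays within 5 percent of
#' every observed efficiency.
#'
#' @param series data.frame with columns \code{inhibitor_mM} and
#'   \code{efficiency}, optionally \code{se}; >= 3 levels including 0.
#' @param weighted If TRUE and SEs are available, weight residuals by
#'   1/SE.
#' @param inhibitor Label stored on the result.
#' @return Object of class \code{inhibition_fit}: list with \code{ki}
#'   (mM), \code{se_ki}, \code{uninhibited_efficiency}, \code{se_eff0},
#'   \code{series}, \code{rss}, \code{unbounded}, \code{ki_lower}.
#' @export
fit_ki <- function(series, weighted = FALSE, inhibitor = NA_character_) {
  stopifnot(is.data.frame(series),
            all(c("inhibitor_mM", "efficiency") %in% names(series)))
  if (nrow(series) < 3L) stop("need >= 3 inhibitor levels")
  if (!any(series$inhibitor_mM == 0)) {
    stop("series must include an uninhibited ([I] = 0) point")
  }
  I <- series$inhibitor_mM
  y <- series$efficiency
  w <- rep(1, length(y))
  if (weighted && !is.null(series$se) && all(is.finite(series$se)) &&
      all(series$se > 0)) {
    w <- 1 / series$se
  }
  model <- function(e0, ki) e0 / (1 + I / ki)
  resid_fn <- function(theta) {
    w * (y - model(exp(theta[1L]), exp(theta[2L])))
  }
  e00 <- max(mean(y[I == 0]), .Machine$double.eps)
  # KI starts bracket the assayed range
  ki_starts <- c(stats::median(I[I > 0]), max(I), max(min(I[I > 0]), 0.1))
  best <- NULL
  for (k0 in ki_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(c(e00, k0)), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit,
                                                              rss = rss)
  }
  if (is.null(best)) stop("secondary-plot fit failed")
  e0 <- exp(best$fit$par[1L]); ki <- exp(best$fit$par[2L])

  unbounded <- FALSE; ki_lower <- NA_real_
  rss_flat <- sum((w * (y - stats::weighted.mean(y, w^2)))^2)
  if (ki > 100 * max(I) && best$rss > 0.95 * rss_flat) {
    # no resolvable decline over the assayed range
    unbounded <- TRUE
    # lower confidence bound: smallest KI whose best-fitting curve stays
    # within 5 percent of every observed efficiency
    max_dev <- function(k) {
      e_hat <- sum(w^2 * y / (1 + I / k)) / sum(w^2 / (1 + I / k)^2)
      max(abs(y - e_hat / (1 + I / k)) /
            pmax(abs(y), .Machine$double.eps))
    }
    grid <- exp(seq(log(max(min(I[I > 0]) / 10, 1e-3)),
                    log(1000 * max(I)), length.out = 400L))
    ok <- vapply(grid, max_dev, numeric(1)) <= 0.05
    if (any(ok)) ki_lower <- min(grid[ok])
    ki <- Inf
  }

  se <- c(NA_real_, NA_real_)
  if (!unbounded) {
    J <- numeric_jacobian(function(p) w * p[1L] / (1 + I / p[2L]), c(e0, ki))
    sigma2 <- best$rss / max(length(y) - 2L, 1L)
    covm <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  }
  structure(list(
    inhibitor = inhibitor,
    ki = ki, se_ki = se[2L],
    uninhibited_efficiency = e0, se_eff0 = se[1L],
    series = series, rss = best$rss,
    unbounded = unbounded, ki_lower = ki_lower,
    converged = best$fit$info %in% 1:4
  ), class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("Secondary-plot inhibition fit",
      if (!is.na(x$inhibitor)) paste0("(", x$inhibitor, ")"), "\n")
  if (x$unbounded) {
    cat("  KI unbounded (no decline over assayed range); lower bound ~",
        format(x$ki_lower, digits = 3), "mM\n")
  } else {
    cat(sprintf("  KI = %.4g +/- %.3g mM\n", x$ki, x$se_ki))
  }
  cat(sprintf("  kcat/Km at [I]=0: %.4g 1/s/uM\n", x$uninhibited_efficiency))
  invisible(x)
}

#' Inhibition analysis of an assay table
#'
#' Runs \code{\link{apparent_efficiency_at_inhibitor}} for every inhibitor
#' concentration of each inhibitor present, then fits
#' \code{\link{fit_ki}} to each secondary plot. Uninhibited
#' (\code{inhibitor == "none"} or \code{inhibitor_mM == 0}) wells at the
#' same fixed bicarbonate are shared as the [I] = 0 point of every series.
#'
#' @param points Assay-point data.frame measured at one fixed bicarbonate
#'   concentration with varying PEP and inhibitor levels.
#' @param weighted Passed to \code{\link{fit_ki}}.
#' @return Named list of \code{inhibition_fit} objects, one per inhibitor.
#' @export
inhibition_analysis <- function(points, weighted = FALSE) {
  points <- validate_assay_points(points)
  points <- points[!points$is_blank, , drop = FALSE]
  uninhib <- points[points$inhibitor_mM == 0 |
                      tolower(points$inhibitor) == "none", , drop = FALSE]
  inhibitors <- setdiff(unique(points$inhibitor[points$inhibitor_mM > 0]),
                        "none")
  if (!length(inhibitors)) stop("no inhibited wells present")
  out <- list()
  for (inh in inhibitors) {
    sub <- points[points$inhibitor == inh & points$inhibitor_mM > 0, ,
                  drop = FALSE]
    fixed_b <- unique(sub$hco3_uM)
    if (length(fixed_b) != 1L) {
      stop("inhibited wells for ", inh,
           " span several bicarbonate concentrations")
    }
    levels <- sort(unique(sub$inhibitor_mM))
    rows <- lapply(levels, function(l) {
      ae <- apparent_efficiency_at_inhibitor(
        sub[sub$inhibitor_mM == l, , drop = FALSE])
      data.frame(inhibitor_mM = l, efficiency = ae$efficiency, se = ae$se)
    })
    u <- uninhib[uninhib$hco3_uM == fixed_b, , drop = FALSE]
    if (nrow(u) == 0L) {
      stop("no uninhibited wells at the fixed bicarbonate concentration")
    }
    u$inhibitor_mM <- 0
    ae0 <- apparent_efficiency_at_inhibitor(u)
    series <- rbind(data.frame(inhibitor_mM = 0, efficiency = ae0$efficiency,
                               se = ae0$se),
                    do.call(rbind, rows))
    out[[inh]] <- fit_ki(series, weighted = weighted, inhibitor = inh)
  }
  out
}
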