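#' Construct a set of bi-substrate kinetic parameters
#'
#' Container for the steady-state parameters of a sequential two-substrate
#' PEPC rate law
#' \deqn{v_0 = \frac{V_{max}[A][B]}{[A][B] + K_A [B] + K_B [A] + K_{iA}K_B}}
#' where \eqn{[A]} is phosphoenolpyruvate (PEP) and \eqn{[B]} is bicarbonate.
#' The product \eqn{K_{iA} K_B} is a single fixed constant (default
#' 50 uM^2), not a free parameter.
#'
#' Concentrations are in micromolar throughout, rates in uM/s, so
#' \code{vmax} is uM/s, \code{km_pep} and \code{km_hco3} are uM,
#' \code{kia_kb} is uM^2 and \code{kcat} is 1/s.
#'
#' @param vmax Maximal rate (uM/s). Must be > 0.
#' @param km_pep Michaelis constant for PEP, \eqn{K_A} (uM). Must be > 0.
#' @param km_hco3 Michaelis constant for bicarbonate, \eqn{K_B} (uM).
#'   Must be > 0.
#' @param kia_kb Fixed denominator constant \eqn{K_{iA}K_B} (uM^2),
#'   default 50.
#' @param kcat Turnover number (1/s), i.e. \code{vmax} divided by total
#'   enzyme concentration in uM. Optional; supply when \eqn{[E]_T} is known.
#' @param se_kcat,se_km_pep,se_km_hco3 Standard errors (same units as the
#'   parameter); \code{NA} when not estimated.
#'
#' @return An object of class \code{kinetic_params}: a list with the fields
#'   above plus derived catalytic efficiencies \code{efficiency_pep} and
#'   \code{efficiency_hco3} (kcat/KM, 1/s/uM; \code{NA} if kcat unknown).
#' @export
#' @examples
#' kp <- kinetic_params(vmax = 10, km_pep = 100, km_hco3 = 20)
#' eval_rate(kp, pep = 100, hco3 = 20)
kinetic_params <- function(vmax, km_pep, km_hco3, kia_kb = 50,
                           kcat = NA_real_,
                           se_kcat = NA_real_, se_km_pep = NA_real_,
                           se_km_hco3 = NA_real_) {
  stopifnot(is.numeric(vmax), length(vmax) == 1L,
            is.numeric(km_pep), length(km_pep) == 1L,
            is.numeric(km_hco3), length(km_hco3) == 1L)
  if (!is.finite(vmax) || vmax <= 0) stop("vmax must be a positive number")
  if (!is.finite(km_pep) || km_pep <= 0) stop("km_pep must be positive")
  if (!is.finite(km_hco3) || km_hco3 <= 0) stop("km_hco3 must be positive")
  if (!is.finite(kia_kb) || kia_kb < 0) stop("kia_kb must be >= 0")
  for (se in list(se_kcat, se_km_pep, se_km_hco3)) {
    if (!is.na(se) && se < 0) stop("standard errors must be >= 0")
  }
  structure(list(
    vmax = vmax, kcat = kcat,
    km_pep = km_pep, km_hco3 = km_hco3, kia_kb = kia_kb,
    se_kcat = se_kcat, se_km_pep = se_km_pep, se_km_hco3 = se_km_hco3,
    efficiency_pep = if (is.na(kcat)) NA_real_ else kcat / km_pep,
    efficiency_hco3 = if (is.na(kcat)) NA_real_ else kcat / km_hco3
  ), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Bi-substrate kinetic parameters\n")
  fmt <- function(v, se, unit) {
    if (is.na(v)) return(sprintf("   (not set) %s\n", unit))
    if (is.na(se)) sprintf("%10.4g %s\n", v, unit)
    else sprintf("%10.4g +/- %.3g %s\n", v, se, unit)
  }
  cat("  Vmax:      ", sprintf("%10.4g uM/s\n", x$vmax))
  cat("  kcat:      ", fmt(x$kcat, x$se_kcat, "1/s"))
  cat("  KM(PEP):   ", fmt(x$km_pep, x$se_km_pep, "uM"))
  cat("  KM(HCO3-): ", fmt(x$km_hco3, x$se_km_hco3, "uM"))
  cat("  KiA.KB:    ", sprintf("%10.4g uM^2 (fixed)\n", x$kia_kb))
  if (!is.na(x$efficiency_pep))
    cat("  kcat/KM(PEP):  ", sprintf("%.4g 1/s/uM\n", x$efficiency_pep))
  if (!is.na(x$efficiency_hco3))
    cat("  kcat/KM(HCO3-):", sprintf("%.4g 1/s/uM\n", x$efficiency_hco3))
  invisible(x)
}

#' Evaluate the bi-substrate steady-state rate law
#'
#' Computes \eqn{v_0 = V_{max} A B / (A B + K_A B + K_B A + K_{iA}K_B)}
#' for PEP concentration \code{pep} and effective bicarbonate
#' concentration \code{hco3} (nominal added bicarbonate plus any residual
#' background). Vectorized over \code{pep} and \code{hco3}.
#'
#' @param params A \code{\link{kinetic_params}} object.
#' @param pep PEP concentration(s), uM. Must be >= 0.
#' @param hco3 Effective bicarbonate concentration(s), uM. Must be >= 0.
#' @return Initial rate(s) in uM/s; always in [0, Vmax) for finite inputs.
#' @export
eval_rate <- function(params, pep, hco3) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(pep < 0) || any(hco3 < 0)) {
    stop("substrate concentrations must be non-negative")
  }
  denom <- pep * hco3 + params$km_pep * hco3 + params$km_hco3 * pep +
    params$kia_kb
  if (any(denom == 0)) {
    stop("rate undefined: denominator is zero (A = B = 0 with KiA.KB = 0)")
  }
  params$vmax * pep * hco3 / denom
}

#' Apparent Michaelis-Menten parameters at fixed bicarbonate
#'
#' At a fixed bicarbonate concentration \eqn{B} the two-substrate rate law
#' reduces to a single-substrate hyperbola in PEP with
#' \deqn{V_{max}^{app} = \frac{V_{max} B}{B + K_B}, \qquad
#'       K_M^{app} = \frac{K_A B + K_{iA}K_B}{B + K_B}.}
#' This is the reduction used for inhibition assays run at a high fixed
#' bicarbonate concentration.
#'
#' @param params A \code{\link{kinetic_params}} object.
#' @param hco3 Fixed effective bicarbonate concentration (uM), > 0.
#' @return A list with \code{vmax_app} (uM/s) and \code{km_app} (uM).
#' @export
apparent_mm_at_fixed_b <- function(params, hco3) {
  stopifnot(inherits(params, "kinetic_params"), length(hco3) == 1L)
  if (!is.finite(hco3) || hco3 <= 0) {
    stop("degenerate design: fixed bicarbonate concentration must be > 0")
  }
  list(
    vmax_app = params$vmax * hco3 / (hco3 + params$km_hco3),
    km_app = (params$km_pep * hco3 + params$kia_kb) / (hco3 + params$km_hco3)
  )
}

#' Turnover number from maximal rate and enzyme concentration
#'
#' \eqn{k_{cat} = V_{max} / [E]_T}, with the enzyme concentration supplied
#' in nM (as assay tables record it) and converted internally to uM.
#'
#' @param vmax Maximal rate (uM/s), >= 0.
#' @param enzyme_conc Total enzyme concentration \eqn{[E]_T} (nM), > 0.
#' @return kcat in 1/s.
#' @export
#' @examples
#' kcat_from_vmax(0.02, 4)  # 5 /s
kcat_from_vmax <- function(vmax, enzyme_conc) {
  if (any(!is.finite(enzyme_conc)) || any(enzyme_conc <= 0)) {
    stop("enzyme concentration must be positive")
  }
  if (any(vmax < 0)) stop("vmax must be >= 0")
  vmax / (enzyme_conc / 1000)
}
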