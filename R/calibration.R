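#' Forward-scatter size calibration curve
#'
#' A power law `ESD = a * FSC^b` linking the dimensionless forward-scatter
#' area (FSC) of a flow-cytometry event to equivalent spherical diameter
#' (ESD, um). The default coefficients are the instrument calibration
#' obtained from size-fractionation of natural samples through
#' polycarbonate filters of increasing pore size.
#'
#' @param a coefficient (um per unit `FSC^b`); must be positive.
#' @param b exponent, dimensionless; must lie in (0, 1).
#' @return An object of class `"calibration_curve"`: a list with elements
#'   `a` and `b`, optionally carrying `r_squared` and the FSC range of the
#'   data it was fitted on (used to flag extrapolated conversions).
#' @seealso [fit_calibration()], [esd_from_fsc()], [fsc_from_esd()]
#' @export
#' @examples
#' calibration_curve()
#' esd_from_fsc(1e4, calibration_curve())
calibration_curve <- function(a = 0.0064, b = 0.5262) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0 || b >= 1)
    stop("'b' must be a single number in (0, 1)", call. = FALSE)
  structure(list(a = a, b = b, r_squared = NA_real_,
                 fsc_range = c(NA_real_, NA_real_)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("FSC -> ESD calibration: ESD[um] = %.4g * FSC^%.4g\n", x$a, x$b))
  if (is.finite(x$r_squared))
    cat(sprintf("  fitted on %d size fractions, R^2 = %.4f\n",
                attr(x, "n_points") %||% NA_integer_, x$r_squared))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert forward scatter to equivalent spherical diameter
#'
#' Applies the power-law calibration `ESD = a * FSC^b`.
#'
#' @param fsc numeric vector of forward-scatter area values; all must be
#'   positive.
#' @param calib a [calibration_curve()].
#' @return ESD in micrometres, same length as `fsc`.
#' @export
esd_from_fsc <- function(fsc, calib = calibration_curve()) {
  stopifnot(inherits(calib, "calibration_curve"))
  if (length(fsc) && (!is.numeric(fsc) || any(!is.finite(fsc) | fsc <= 0)))
    stop("all FSC values must be positive and finite", call. = FALSE)
  calib$a * fsc^calib$b
}

#' Invert the size calibration: forward scatter from ESD
#'
#' Computes the FSC value that the calibration maps to a given ESD,
#' `FSC = (ESD / a)^(1/b)`, optionally degraded by multiplicative lognormal
#' measurement noise. Used by the community simulator to emit realistic
#' flow-cytometry event tables; with `noise_cv = 0` it is the exact inverse
#' of [esd_from_fsc()].
#'
#' @param esd numeric vector of ESD in micrometres; all positive.
#' @param calib a [calibration_curve()].
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise factor applied to FSC (0 = noise-free). The factor has mean 1.
#' @return dimensionless FSC values, same length as `esd`.
#' @export
fsc_from_esd <- function(esd, calib = calibration_curve(), noise_cv = 0) {
  stopifnot(inherits(calib, "calibration_curve"))
  if (length(esd) && (!is.numeric(esd) || any(!is.finite(esd) | esd <= 0)))
    stop("all ESD values must be positive and finite", call. = FALSE)
  stopifnot(is.numeric(noise_cv), length(noise_cv) == 1L, noise_cv >= 0)
  fsc <- (esd / calib$a)^(1 / calib$b)
  if (noise_cv > 0 && length(fsc)) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fsc <- fsc * rlnorm(length(fsc), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  fsc
}

#' Fit the FSC-to-ESD power law from size-fractionation data
#'
#' Size fractionation passes a natural sample through filters of known,
#' increasing pore size; each increment admits a new particle class with
#' higher forward scatter, whose representative FSC (here: a median or other
#' user-chosen summary) is paired with the pore diameter. The calibration is
#' an ordinary least-squares fit of `log10(ESD) = log10(a) + b * log10(FSC)`.
#'
#' @param pore_um filter pore sizes in micrometres, strictly increasing,
#'   at least three values.
#' @param fsc representative FSC of the particle class newly appearing at
#'   each pore size; strictly increasing, same length as `pore_um`.
#' @return A [calibration_curve()] carrying the fitted `a`, `b`, the fit
#'   `r_squared` and the FSC range of the calibration data.
#' @export
#' @examples
#' pores <- c(0.2, 0.8, 2, 3, 5, 8)
#' fscs <- (pores / 0.0064)^(1 / 0.5262)
#' fit_calibration(pores, fscs)
fit_calibration <- function(pore_um, fsc) {
  if (length(pore_um) != length(fsc))
    stop("'pore_um' and 'fsc' must have the same length", call. = FALSE)
  if (length(pore_um) < 3L)
    stop("at least 3 (pore size, FSC) pairs are required", call. = FALSE)
  if (any(!is.finite(pore_um) | pore_um <= 0) || any(!is.finite(fsc) | fsc <= 0))
    stop("pore sizes and FSC values must be positive and finite", call. = FALSE)
  if (any(diff(pore_um) <= 0))
    stop("pore sizes must be strictly increasing (duplicated or unordered ",
         "fractions cannot anchor the size axis)", call. = FALSE)
  if (any(diff(fsc) <= 0))
    stop("FSC values must increase strictly with pore size; non-monotone ",
         "fractionation data indicate mis-assigned particle classes",
         call. = FALSE)
  fit <- lm(log10(pore_um) ~ log10(fsc))
  b <- unname(coef(fit)[2L])
  a <- 10^unname(coef(fit)[1L])
  if (b <= 0 || b >= 1)
    stop(sprintf("fitted exponent %.3f outside (0, 1); calibration data are ",
                 b), "not consistent with a scatter-size power law",
         call. = FALSE)
  out <- calibration_curve(a = a, b = b)
  out$r_squared <- suppressWarnings(summary(fit)$r.squared)
  out$fsc_range <- range(fsc)
  attr(out, "n_points") <- length(fsc)
  out
}
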