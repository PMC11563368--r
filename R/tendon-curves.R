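# Tendon constitutive curves: stress-strain boundary laws and normalised
# force-strain curves of the two Hill-type tendon families, plus
# linearisation of the high-strain region.

#' Stress of the energy-storage boundary tendon
#'
#' Analytic constitutive law for a compliant, energy-storage tendon
#' (human Achilles): \eqn{\sigma(\varepsilon) = C \varepsilon
#' e^{D\varepsilon + F\varepsilon^2}} with the strain \eqn{\varepsilon} in
#' percent. The default constants are the tensile-test fit for donors aged
#' 36-50 (C in MPa; D per percent strain; F per squared percent strain).
#'
#' @param strain_pct tendon strain in percent, non-negative (vectorised).
#' @param C,D,F material constants.
#' @return stress in MPa; 0 at zero strain.
#' @examples
#' energy_storage_stress(14.5)  # ~51.6 MPa
#' @export
energy_storage_stress <- function(strain_pct, C = 1.386, D = 0.123, F = -0.004) {
  if (!is.numeric(strain_pct) || anyNA(strain_pct)) {
    stop("`strain_pct` must be numeric and non-missing", call. = FALSE)
  }
  if (any(strain_pct < 0)) {
    stop("`strain_pct` must be non-negative (strain in percent)", call. = FALSE)
  }
  C * strain_pct * exp(D * strain_pct + F * strain_pct^2)
}

#' Convert tendon stress to force
#'
#' Multiplies stress by the tendon cross-sectional area. MPa times mm^2
#' gives N, so the units are consistent by construction.
#'
#' @param stress_mpa stress in MPa (vectorised).
#' @param csa_mm2 tendon cross-sectional area in mm^2, positive scalar.
#' @return force in N.
#' @export
stress_to_force <- function(stress_mpa, csa_mm2) {
  if (!is.numeric(csa_mm2) || length(csa_mm2) != 1L || is.na(csa_mm2) || csa_mm2 <= 0) {
    stop("`csa_mm2` must be a positive scalar", call. = FALSE)
  }
  stress_mpa * csa_mm2
}

#' Normalise a tendon force by the maximum isometric force
#'
#' @param force_n force in N (vectorised).
#' @param f_max_n maximum isometric force acting on the tendon, in N.
#' @return dimensionless F/Fmax.
#' @export
normalise_force <- function(force_n, f_max_n) {
  if (!is.numeric(f_max_n) || length(f_max_n) != 1L || is.na(f_max_n) || f_max_n <= 0) {
    stop("`f_max_n` must be a positive scalar", call. = FALSE)
  }
  force_n / f_max_n
}

#' Maximum isometric force from physiological cross-sectional area
#'
#' \eqn{F_{max} = PCSA \cdot \sigma_{max}}. The default maximum isometric
#' stress of 23 N/cm^2 is the commonly used mammalian value.
#'
#' @param pcsa_cm2 physiological cross-sectional area in cm^2, positive.
#' @param sigma_max_n_per_cm2 maximum isometric stress in N/cm^2.
#' @return maximum isometric force in N.
#' @export
fmax_from_pcsa <- function(pcsa_cm2, sigma_max_n_per_cm2 = 23) {
  if (!is.numeric(pcsa_cm2) || any(is.na(pcsa_cm2)) || any(pcsa_cm2 <= 0)) {
    stop("`pcsa_cm2` must be positive", call. = FALSE)
  }
  if (!is.numeric(sigma_max_n_per_cm2) || any(sigma_max_n_per_cm2 <= 0)) {
    stop("`sigma_max_n_per_cm2` must be positive", call. = FALSE)
  }
  pcsa_cm2 * sigma_max_n_per_cm2
}

#' Stress-strain curves for boundary tendons
#'
#' Container for a tendon stress-strain relation, either the analytic
#' energy-storage law of [energy_storage_stress()] or tabulated
#' experimental points interpolated piecewise-linearly (no smoothing).
#'
#' @param C,D,F constants of the analytic law.
#' @param strain_pct,stress_mpa ordered tabulated points (strain strictly
#'   increasing, stress non-negative).
#' @return an object of class `stress_strain_curve`; evaluate it with
#'   [eval_stress()].
#' @export
energy_storage_curve <- function(C = 1.386, D = 0.123, F = -0.004) {
  structure(
    list(kind = "analytic_energy_storage", C = C, D = D, F = F),
    class = "stress_strain_curve"
  )
}

#' @rdname energy_storage_curve
#' @export
tabulated_curve <- function(strain_pct, stress_mpa) {
  if (length(strain_pct) != length(stress_mpa) || length(strain_pct) < 2L) {
    stop("need >= 2 (strain, stress) points of equal length", call. = FALSE)
  }
  if (any(diff(strain_pct) <= 0)) {
    stop("tabulated strains must be strictly increasing", call. = FALSE)
  }
  if (any(stress_mpa < 0)) {
    stop("tabulated stresses must be non-negative", call. = FALSE)
  }
  structure(
    list(kind = "tabulated", strain_pct = as.numeric(strain_pct),
         stress_mpa = as.numeric(stress_mpa)),
    class = "stress_strain_curve"
  )
}

#' Evaluate a stress-strain curve
#'
#' @param curve a [energy_storage_curve()] or [tabulated_curve()].
#' @param strain_pct strain in percent.
#' @return stress in MPa.
#' @export
eval_stress <- function(curve, strain_pct) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (curve$kind == "analytic_energy_storage") {
    energy_storage_stress(strain_pct, curve$C, curve$D, curve$F)
  } else {
    stats::approx(curve$strain_pct, curve$stress_mpa, xout = strain_pct,
                  rule = 1)$y
  }
}

#' Normalised tendon force-strain curves of the Hill-type families
#'
#' Both assessed tendon families consist of a nonlinear toe region followed
#' by an infinitely continued linear elastic region of the normalised force
#' \eqn{F/F_{max}} over tendon strain (in percent).
#'
#' `tmm_tendon()` is the Thelen-type series-elastic element: an exponential
#' toe up to a toe strain of \eqn{0.609\,\varepsilon_0} and a linear region
#' of stiffness \eqn{1.712/\varepsilon_0} (per unit strain), where
#' \eqn{\varepsilon_0} (`eps0`, dimensionless) is the tendon strain at one
#' maximum isometric force. The default `eps0` is calibrated so the fitted
#' linear region has slope 0.52 per percent strain.
#'
#' `ehtm_tendon()` is the extended-Hill-type series-elastic element: a
#' power-law toe \eqn{f_0 (u/u_{nll})^{\nu}} with \eqn{\nu = u_{nll}/
#' \Delta U_l} (which makes the junction C1-continuous) up to the
#' nonlinear-linear transition strain `u_nll` (dimensionless), then a linear
#' region of normalised stiffness \eqn{f_0/\Delta U_l}. Defaults are
#' calibrated so the fitted linear region has slope 0.24 per percent strain
#' and extrapolated intercept -0.60.
#'
#' `custom_tendon()` wraps an arbitrary normalised force function of strain
#' in percent.
#'
#' @param eps0 TMM tendon strain (dimensionless) at maximum isometric force.
#' @param f_toe,k_toe TMM toe-region shape constants.
#' @param u_nll EHTM nonlinear-linear transition strain (dimensionless).
#' @param du_l EHTM linear-region strain scale (dimensionless).
#' @param f_0 EHTM normalised force at the transition.
#' @param fun function of strain in percent returning normalised force.
#' @param toe_strain_pct end of the toe region in percent strain.
#' @param domain valid strain range in percent, `c(lo, hi)`.
#' @param label curve label.
#' @return an object of class `tendon_curve`.
#' @examples
#' tendon_force(tmm_tendon(), 4.77)  # ~1.77 F/Fmax
#' @export
tmm_tendon <- function(eps0 = 1.712 / 52, f_toe = 0.33, k_toe = 3,
                       domain = c(0, 20), label = "TMM") {
  stopifnot(eps0 > 0, f_toe > 0, k_toe > 0)
  structure(
    list(family = "TMM", eps0 = eps0, f_toe = f_toe, k_toe = k_toe,
         toe_strain_pct = 100 * 0.609 * eps0, domain = domain, label = label),
    class = "tendon_curve"
  )
}

#' @rdname tmm_tendon
#' @export
ehtm_tendon <- function(u_nll = 0.0425, du_l = 0.0175, f_0 = 0.42,
                        domain = c(0, 20), label = "EHTM") {
  stopifnot(u_nll > 0, du_l > 0, f_0 > 0)
  structure(
    list(family = "EHTM", u_nll = u_nll, du_l = du_l, f_0 = f_0,
         toe_strain_pct = 100 * u_nll, domain = domain, label = label),
    class = "tendon_curve"
  )
}

#' @rdname tmm_tendon
#' @export
custom_tendon <- function(fun, toe_strain_pct, domain = c(0, 20),
                          label = "custom") {
  stopifnot(is.function(fun), toe_strain_pct >= 0)
  structure(
    list(family = "custom", fun = fun, toe_strain_pct = toe_strain_pct,
         domain = domain, label = label),
    class = "tendon_curve"
  )
}

#' @export
print.tendon_curve <- function(x, ...) {
  cat(sprintf("<tendon_curve> family %s (%s), toe region ends at %.3f%% strain, domain [%g, %g]%%\n",
              x$family, x$label, x$toe_strain_pct, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Evaluate a normalised tendon force-strain curve
#'
#' @param curve a [tendon_curve][tmm_tendon].
#' @param strain_pct tendon strain in percent (vectorised); must lie within
#'   the curve's domain.
#' @return normalised force F/Fmax; continuous, non-decreasing, 0 at zero
#'   strain.
#' @export
tendon_force <- function(curve, strain_pct) {
  stopifnot(inherits(curve, "tendon_curve"))
  if (any(strain_pct < curve$domain[1] - 1e-12) ||
      any(strain_pct > curve$domain[2] + 1e-12)) {
    stop(sprintf("strain outside curve domain [%g, %g]%%",
                 curve$domain[1], curve$domain[2]), call. = FALSE)
  }
  u <- strain_pct / 100  # dimensionless strain
  switch(curve$family,
    TMM = {
      eps_toe <- 0.609 * curve$eps0
      k_lin <- 1.712 / curve$eps0
      toe <- curve$f_toe * (exp(curve$k_toe * u / eps_toe) - 1) /
        (exp(curve$k_toe) - 1)
      lin <- k_lin * (u - eps_toe) + curve$f_toe
      ifelse(u <= eps_toe, toe, lin)
    },
    EHTM = {
      nu <- curve$u_nll / curve$du_l
      toe <- curve$f_0 * (u / curve$u_nll)^nu
      lin <- curve$f_0 * (1 + (u - curve$u_nll) / curve$du_l)
      ifelse(u <= curve$u_nll, toe, lin)
    },
    custom = curve$fun(strain_pct)
  )
}

#' Linear segment of a tendon force-strain curve
#'
#' The linearised high-strain region of a normalised tendon curve: slope in
#' 1/% strain and the extrapolated F/Fmax intercept at zero strain.
#'
#' @param slope slope in 1/% strain, positive.
#' @param intercept extrapolated normalised force at 0% strain.
#' @return object of class `linear_segment`.
#' @export
linear_segment <- function(slope, intercept) {
  if (!is.numeric(slope) || length(slope) != 1L || is.na(slope) || slope <= 0) {
    stop("`slope` must be a positive scalar (1/% strain)", call. = FALSE)
  }
  if (!is.numeric(intercept) || length(intercept) != 1L || is.na(intercept)) {
    stop("`intercept` must be a numeric scalar", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept),
            class = "linear_segment")
}

#' @export
print.linear_segment <- function(x, ...) {
  cat(sprintf("<linear_segment> F/Fmax = %.4f/%% * strain %+.4f\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Fit the linear region of a tendon curve
#'
#' Ordinary least squares over the linear elastic region. For a
#' `tendon_curve` the fit interval is `[toe + margin, toe + margin + width]`
#' percent strain (exact on the analytic linear branch). For raw points
#' (2-column matrix or data frame of strain percent and normalised force)
#' all supplied points are used unless `interval` restricts them; supply
#' only points above the toe region.
#'
#' @param x a `tendon_curve`, or a matrix/data.frame whose first two columns
#'   are strain (percent) and normalised force.
#' @param margin strain margin above the toe region, in percent.
#' @param width width of the fit interval, in percent strain.
#' @param n number of sample points for curve input.
#' @param interval optional `c(lo, hi)` strain restriction for point input.
#' @param ... passed to methods.
#' @return a [linear_segment()].
#' @examples
#' fit_linear_region(tmm_tendon())   # slope 0.52, intercept -0.71
#' @export
fit_linear_region <- function(x, ...) UseMethod("fit_linear_region")

#' @rdname fit_linear_region
#' @export
fit_linear_region.tendon_curve <- function(x, margin = 0.5, width = 5,
                                           n = 200, ...) {
  lo <- x$toe_strain_pct + margin
  hi <- lo + width
  if (hi > x$domain[2]) {
    stop("fit interval exceeds curve domain; no identifiable linear region",
         call. = FALSE)
  }
  eps <- seq(lo, hi, length.out = n)
  fit_points(eps, tendon_force(x, eps))
}

#' @rdname fit_linear_region
#' @export
fit_linear_region.default <- function(x, interval = NULL, ...) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("point input needs two columns", call. = FALSE)
  eps <- as.numeric(x[[1L]])
  f <- as.numeric(x[[2L]])
  if (!is.null(interval)) {
    keep <- eps >= interval[1] & eps <= interval[2]
    eps <- eps[keep]
    f <- f[keep]
  }
  if (length(eps) < 2L) {
    stop("fewer than 2 points in the linear region; cannot fit", call. = FALSE)
  }
  fit_points(eps, f)
}

fit_points <- function(eps, f) {
  co <- stats::coef(stats::lm(f ~ eps))
  linear_segment(slope = unname(co[2L]), intercept = unname(co[1L]))
}

#' Evaluate a linear segment
#'
#' @param seg a [linear_segment()].
#' @param strain_pct strain in percent.
#' @return normalised force on the extrapolated line.
#' @export
eval_segment <- function(seg, strain_pct) {
  stopifnot(inherits(seg, "linear_segment"))
  seg$slope * strain_pct + seg$intercept
}

#' Calibrate a tendon family's stiffness to a target linear-region slope
#'
#' Solves the family's stiffness parameter (TMM: `eps0`; EHTM: `du_l`) so
#' that [fit_linear_region()] of the resulting curve matches `slope_pct`.
#' Used to construct family curves that reproduce a published linearised
#' stiffness when the native shape parameters are unknown.
#'
#' @param family `"TMM"` or `"EHTM"`.
#' @param slope_pct target slope in 1/% strain.
#' @param ... further arguments to the family constructor.
#' @return a calibrated `tendon_curve`.
#' @export
calibrate_tendon <- function(family = c("TMM", "EHTM"), slope_pct, ...) {
  family <- match.arg(family)
  stopifnot(is.numeric(slope_pct), slope_pct > 0)
  make <- function(p) {
    if (family == "TMM") tmm_tendon(eps0 = p, ...) else ehtm_tendon(du_l = p, ...)
  }
  obj <- function(p) fit_linear_region(make(p))$slope - slope_pct
  # upper bound keeps the fit interval inside the curve domain
  hi <- if (family == "TMM") 0.2 else 0.5
  root <- stats::uniroot(obj, interval = c(1e-3, hi), tol = 1e-12)
  make(root$root)
}
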