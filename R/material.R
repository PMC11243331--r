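#' Lorentz oscillator term of a dielectric model
#'
#' One underdamped resonance contributing
#' \deqn{\Delta\varepsilon(\nu) = S\,\nu_0^2 / (\nu_0^2 - \nu^2 - i\gamma\nu)}
#' to the relative permittivity.  Each oscillator produces an absorption peak
#' centred (to within a small fraction of \eqn{\gamma}) at \eqn{\nu_0} and an
#' S-shaped anomalous-dispersion feature in the refractive index.
#'
#' @param nu0_thz Centre frequency in THz, positive.
#' @param strength Dimensionless oscillator strength `S` (its contribution to
#'   the static relative permittivity), positive.
#' @param gamma_thz Damping full width in THz, positive and smaller than
#'   `nu0_thz` so that the resonance is underdamped and yields a distinct
#'   absorption peak.
#' @return An object of class `lorentz_oscillator`.
#' @export
lorentz_oscillator <- function(nu0_thz, strength, gamma_thz) {
  if (!is_number(nu0_thz) || nu0_thz <= 0)
    tds_stop("invalid_parameter", "nu0_thz must be positive")
  if (!is_number(strength) || strength <= 0)
    tds_stop("invalid_parameter", "oscillator strength must be positive")
  if (!is_number(gamma_thz) || gamma_thz <= 0)
    tds_stop("invalid_parameter", "gamma_thz must be positive")
  if (gamma_thz >= nu0_thz)
    tds_stop("invalid_parameter",
             "gamma_thz must be below nu0_thz (underdamped resonance)")
  structure(list(nu0_thz = nu0_thz, strength = strength,
                 gamma_thz = gamma_thz),
            class = "lorentz_oscillator")
}

#' Double-Debye parameter set for liquid water
#'
#' Two-relaxation-time dielectric model
#' \deqn{\varepsilon(\nu) = \varepsilon_\infty +
#'   \frac{\varepsilon_s - \varepsilon_1}{1 - i\,2\pi\nu\tau_1} +
#'   \frac{\varepsilon_1 - \varepsilon_\infty}{1 - i\,2\pi\nu\tau_2}}
#' reproducing liquid water's strong, broadband THz absorption (a few hundred
#' cm\eqn{^{-1}} across 0.2--2.6 THz at room temperature).  The defaults are
#' frozen literature-style room-temperature constants; they are deliberately
#' part of the package configuration so solution simulations are reproducible.
#'
#' @param eps_static Static relative permittivity \eqn{\varepsilon_s}.
#' @param eps_intermediate Intermediate permittivity \eqn{\varepsilon_1}
#'   between the slow and fast relaxations.
#' @param eps_inf_w High-frequency permittivity \eqn{\varepsilon_\infty}.
#' @param tau1_ps Slow (collective) relaxation time, ps.
#' @param tau2_ps Fast relaxation time, ps.
#' @return An object of class `debye_solvent`.
#' @export
debye_water <- function(eps_static = 78.36, eps_intermediate = 4.93,
                        eps_inf_w = 2.50, tau1_ps = 8.24, tau2_ps = 0.18) {
  for (v in c(eps_static, eps_intermediate, eps_inf_w, tau1_ps, tau2_ps))
    if (!is_number(v) || v <= 0)
      tds_stop("invalid_parameter", "Debye parameters must be positive numbers")
  structure(list(eps_static = eps_static,
                 eps_intermediate = eps_intermediate,
                 eps_inf_w = eps_inf_w,
                 tau1_ps = tau1_ps, tau2_ps = tau2_ps),
            class = "debye_solvent")
}

#' Dielectric model of a sample medium
#'
#' Combines a real high-frequency background permittivity, a set of Lorentz
#' oscillators, and (for solutions) a Debye solvent mixed linearly by volume
#' fraction:
#' \deqn{\varepsilon(\nu) = (1-\phi)\,\varepsilon_{Debye}(\nu) +
#'   \phi\,\varepsilon_\infty + \sum_k S_k \nu_{0k}^2 /
#'   (\nu_{0k}^2 - \nu^2 - i\gamma_k\nu)}
#' where \eqn{\phi} is the solute volume fraction.  Without a solvent the
#' background is simply \eqn{\varepsilon_\infty}.  The model is passive:
#' \eqn{\mathrm{Im}\,\varepsilon \ge 0} for \eqn{\nu > 0}.
#'
#' @param eps_inf Real high-frequency relative permittivity, at least 1.
#' @param oscillators List of [lorentz_oscillator()] terms (may be empty).
#' @param solvent Optional [debye_water()] parameter set.
#' @param solute_volume_fraction Volume fraction \eqn{\phi \in [0, 1]} of the
#'   solute; only meaningful together with `solvent`.
#' @return An object of class `material_model`.
#' @examples
#' m <- material_model(2.0, list(lorentz_oscillator(1.0, 0.01, 0.05)))
#' permittivity(m, c(0.5, 1.0, 1.5))
#' @export
material_model <- function(eps_inf, oscillators = list(), solvent = NULL,
                           solute_volume_fraction = NULL) {
  if (!is_number(eps_inf) || eps_inf < 1)
    tds_stop("invalid_parameter", "eps_inf must be a number >= 1")
  if (!is.list(oscillators) ||
      !all(vapply(oscillators, inherits, TRUE, "lorentz_oscillator")))
    tds_stop("invalid_parameter",
             "oscillators must be a list of lorentz_oscillator objects")
  if (!is.null(solvent) && !inherits(solvent, "debye_solvent"))
    tds_stop("invalid_parameter", "solvent must come from debye_water()")
  if (is.null(solvent)) {
    if (!is.null(solute_volume_fraction))
      tds_stop("invalid_parameter",
               "solute_volume_fraction requires a solvent")
  } else {
    if (is.null(solute_volume_fraction)) solute_volume_fraction <- 0
    if (!is_number(solute_volume_fraction) ||
        solute_volume_fraction < 0 || solute_volume_fraction > 1)
      tds_stop("invalid_parameter",
               "solute_volume_fraction must lie in [0, 1]")
  }
  structure(list(eps_inf = eps_inf, oscillators = oscillators,
                 solvent = solvent,
                 solute_volume_fraction = solute_volume_fraction),
            class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("<material_model> eps_inf = %g, %d oscillator(s)%s\n",
              x$eps_inf, length(x$oscillators),
              if (!is.null(x$solvent))
                sprintf(", Debye solvent (phi = %.3g)",
                        x$solute_volume_fraction) else ""))
  for (o in x$oscillators)
    cat(sprintf("  nu0 = %.3g THz  S = %.3g  gamma = %.3g THz\n",
                o$nu0_thz, o$strength, o$gamma_thz))
  invisible(x)
}

#' Propagation geometry of a measurement
#'
#' @param d_mm Propagation path through the material in millimetres
#'   (tablet thickness, or liquid-layer depth of the microfluidic cell).
#' @param kind Either `"tablet"` or `"liquid_cell"`.  For liquid cells the
#'   reference trace is interpreted as measured through the matched
#'   empty- or solvent-filled cell, so the window interfaces cancel.
#' @return An object of class `sample_geometry`.
#' @export
sample_geometry <- function(d_mm, kind = c("tablet", "liquid_cell")) {
  kind <- match.arg(kind)
  if (!is_number(d_mm) || d_mm <= 0)
    tds_stop("invalid_geometry", "d_mm must be positive")
  structure(list(d_mm = d_mm, kind = kind), class = "sample_geometry")
}

debye_permittivity <- function(solvent, nu_thz) {
  w1 <- 2 * pi * nu_thz * solvent$tau1_ps
  w2 <- 2 * pi * nu_thz * solvent$tau2_ps
  solvent$eps_inf_w +
    (solvent$eps_static - solvent$eps_intermediate) / complex(real = 1, imaginary = -w1) +
    (solvent$eps_intermediate - solvent$eps_inf_w) / complex(real = 1, imaginary = -w2)
}

#' Complex relative permittivity of a material model
#'
#' Evaluates the model dielectric function on a frequency grid.  The solvent
#' background (if any) is mixed linearly by volume fraction and the Lorentz
#' oscillator terms are added on top; the imaginary part is non-negative for
#' every positive frequency (passive medium).
#'
#' @param model A [material_model()].
#' @param nu_thz Frequency grid in THz, all entries positive.
#' @return Complex vector of \eqn{\varepsilon(\nu)}, same length as `nu_thz`.
#' @export
permittivity <- function(model, nu_thz) {
  stopifnot(inherits(model, "material_model"))
  if (length(nu_thz) == 0L)
    tds_stop("invalid_input", "empty frequency grid")
  if (!all(is.finite(nu_thz)) || any(nu_thz <= 0))
    tds_stop("invalid_input", "frequencies must be positive and finite")
  if (is.null(model$solvent)) {
    eps <- complex(real = rep(model$eps_inf, length(nu_thz)), imaginary = 0)
  } else {
    phi <- model$solute_volume_fraction
    eps <- (1 - phi) * debye_permittivity(model$solvent, nu_thz) +
      phi * model$eps_inf
  }
  for (o in model$oscillators) {
    denom <- complex(real = o$nu0_thz^2 - nu_thz^2,
                     imaginary = -o$gamma_thz * nu_thz)
    eps <- eps + o$strength * o$nu0_thz^2 / denom
  }
  eps
}

#' Model optical constants (for forward checks and oracles)
#'
#' `model_refractive_index` returns the complex refractive index
#' \eqn{\tilde n = \sqrt{\varepsilon}} with \eqn{\mathrm{Im}\,\tilde n \ge 0};
#' `model_absorption_cm` the corresponding power absorption coefficient
#' \eqn{\alpha = 2\,\mathrm{Im}\,\tilde n\,\omega/c} in cm\eqn{^{-1}}.
#'
#' @inheritParams permittivity
#' @return Complex (`model_refractive_index`) or numeric
#'   (`model_absorption_cm`) vector on the grid.
#' @export
model_refractive_index <- function(model, nu_thz) {
  eps <- permittivity(model, nu_thz)
  n <- sqrt(eps)
  # principal sqrt of a value with Im >= 0 already has Im >= 0, but guard
  # against rounding at Im == 0
  flip <- Im(n) < 0
  n[flip] <- -n[flip]
  n
}

#' @rdname model_refractive_index
#' @export
model_absorption_cm <- function(model, nu_thz) {
  n <- model_refractive_index(model, nu_thz)
  # alpha [1/m] = 2 * kappa * omega / c ; report in 1/cm
  2 * Im(n) * (2 * pi * nu_thz * 1e12) / C_M_S / 100
}
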