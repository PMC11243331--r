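#' Synthetic single-cycle THz reference pulse
#'
#' Generates the reference transient that stands in for a photoconductive /
#' electro-optic THz spectrometer: a first-derivative-of-Gaussian single-cycle
#' pulse with additive white Gaussian noise.  The default width gives usable
#' spectral content across the 0.2--2.6 THz band in which sugar-alcohol
#' absorption lines are reported, with margin on both sides.
#'
#' @param n_points Number of samples (at least 64).
#' @param dt_ps Sampling step in ps.  The default 0.05 ps puts the Nyquist
#'   frequency at 10 THz so the noise floor can be estimated above 5 THz.
#' @param t0_ps Pulse centre in ps.
#' @param width_ps Pulse width in ps; the underlying Gaussian has
#'   \eqn{\sigma =} `width_ps / 2`.
#' @param snr Amplitude signal-to-noise ratio: the noise standard deviation is
#'   `max(abs(signal)) / snr`.  Use `Inf` for a noise-free pulse.
#' @param seed Integer seed for the noise generator; identical arguments and
#'   seed give bit-identical traces (the global RNG state is untouched).
#' @return A [time_trace()] with the seed recorded.
#' @examples
#' ref <- generate_reference_pulse(seed = 42)
#' sp <- fft_spectrum(ref)
#' @export
generate_reference_pulse <- function(n_points = 8192, dt_ps = 0.05,
                                     t0_ps = 10, width_ps = 0.2,
                                     snr = 1000, seed = 42) {
  if (!is_number(n_points) || n_points < 64)
    tds_stop("invalid_parameter", "n_points must be at least 64")
  if (!is_number(dt_ps) || dt_ps <= 0)
    tds_stop("invalid_parameter", "dt_ps must be positive")
  if (!is_number(width_ps) || width_ps <= 0 || width_ps >= n_points * dt_ps)
    tds_stop("invalid_parameter",
             "width_ps must be positive and smaller than the trace span")
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    tds_stop("invalid_parameter", "snr must be positive (Inf for noise-free)")
  n_points <- as.integer(n_points)
  t <- (seq_len(n_points) - 1L) * dt_ps
  sigma <- width_ps / 2
  x <- t - t0_ps
  # derivative-of-Gaussian, analytically normalised to unit peak amplitude
  s <- -(x / sigma) * exp(0.5 - x^2 / (2 * sigma^2))
  if (is.finite(snr)) {
    sd_noise <- max(abs(s)) / snr
    noise <- withr::with_seed(as.integer(seed),
                              stats::rnorm(n_points, 0, sd_noise))
    s <- s + noise
  }
  time_trace(t, s, label = sprintf("reference pulse (width %.3g ps)", width_ps),
             seed = if (is.finite(snr)) as.integer(seed) else NULL)
}

#' Add seeded measurement noise to a trace
#'
#' @param trace A [time_trace()].
#' @param snr Amplitude signal-to-noise ratio relative to `reference_peak`
#'   (noise sd = `reference_peak / snr`).  `Inf` returns the trace unchanged.
#' @param seed Integer noise seed.
#' @param reference_peak Amplitude against which the SNR is defined; defaults
#'   to the trace's own peak.  Passing the reference pulse's peak emulates a
#'   detector whose noise is independent of the sample attenuation.
#' @return A [time_trace()].
#' @export
add_noise <- function(trace, snr, seed, reference_peak = max(abs(trace$e))) {
  stopifnot(inherits(trace, "tds_trace"))
  if (!is.numeric(snr) || snr <= 0)
    tds_stop("invalid_parameter", "snr must be positive")
  if (!is.finite(snr)) return(trace)
  sd_noise <- reference_peak / snr
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(trace$e), 0, sd_noise))
  out <- trace
  out$e <- trace$e + noise
  out$seed <- as.integer(seed)
  out
}

#' Propagate a reference pulse through a sample
#'
#' Applies the single-pass transmission function
#' \deqn{T(\omega) = \frac{4\tilde n}{(\tilde n + 1)^2}
#'   \exp\!\big(i(\tilde n - 1)\,\omega d / c\big)}
#' (evaluated in the package's \eqn{e^{-j\omega t}} spectral convention, i.e.
#' as the complex conjugate of the expression above so that the pulse is
#' delayed and attenuated) to the reference spectrum and returns the
#' transmitted transient on the same time axis.  There are no Fabry--Perot
#' echo terms: the model is the exact forward counterpart of the closed-form
#' extraction, which applies a single Fresnel correction.  For
#' `kind = "liquid_cell"` the reference is understood as measured through the
#' matched empty or solvent-filled cell, so the cell windows cancel and only
#' the liquid layer of depth `d_mm` appears in \eqn{T}.
#'
#' @param reference A [time_trace()] reference pulse.
#' @param model A [material_model()].
#' @param geometry A [sample_geometry()].
#' @return A [time_trace()] carrying `d_mm` from the geometry.
#' @examples
#' ref <- generate_reference_pulse(snr = Inf)
#' slab <- material_model(1.42^2)
#' sam <- transmit(ref, slab, sample_geometry(1.11, "tablet"))
#' # pulse delayed by (n - 1) d / c ~ 1.55 ps
#' sam$t_ps[which.max(sam$e)] - ref$t_ps[which.max(ref$e)]
#' @export
transmit <- function(reference, model, geometry) {
  stopifnot(inherits(reference, "tds_trace"),
            inherits(model, "material_model"),
            inherits(geometry, "sample_geometry"))
  n <- length(reference$e)
  dt <- dt_ps(reference)
  half <- n %/% 2
  nu_pos <- seq_len(half) / (n * dt)          # THz, includes Nyquist
  nt <- model_refractive_index(model, nu_pos)
  if (any(Re(nt) < 1e-6))
    tds_stop("degenerate_medium",
             "model refractive index is non-positive inside the band")
  omega <- 2 * pi * nu_pos                    # rad/ps
  # physics-convention transmission, then conjugated into the FFT convention
  tf <- Conj(4 * nt / (1 + nt)^2 *
               exp(1i * (nt - 1) * omega * geometry$d_mm / C_MM_PS))
  # DC bin: real lossless limit of the Fresnel factor
  t_dc <- Mod(4 * nt[1] / (1 + nt[1])^2)
  tfull <- complex(real = numeric(n))
  tfull[1] <- t_dc
  tfull[2:(half + 1)] <- tf
  if (half > 1)
    tfull[(half + 2):n] <- Conj(rev(tf[seq_len(half - 1)]))
  spec <- stats::fft(reference$e) * tfull
  e_out <- Re(stats::fft(spec, inverse = TRUE)) / n
  time_trace(reference$t_ps, e_out,
             label = sprintf("%s through %g mm %s", reference$label,
                             geometry$d_mm, geometry$kind),
             d_mm = geometry$d_mm)
}

load_preset_catalogue <- function() {
  path <- system.file("extdata", "presets.yaml", package = "teraspec")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "presets.yaml")
  yaml::read_yaml(path)
}

#' Packaged material and geometry presets
#'
#' Returns the dielectric model, measurement geometry, and recommended
#' extraction/detection settings for the packaged specimens.  Solid presets
#' place Lorentz oscillators at the published absorption-line frequencies of
#' crystalline mannitol and erythritol tablets (`mannitol_solid` carries all
#' six lines including the weak 1.23 THz feature; `mannitol_solid_fig3` the
#' five-line reading); solution presets combine a double-Debye water
#' background with solute oscillators at the published solution frequencies,
#' mixed by solute volume fraction \eqn{\phi = c / \rho_{solute}} with
#' \eqn{\rho_{solute} = 1.5} g/mL.  The catalogue lives in
#' `inst/extdata/presets.yaml`.
#'
#' @param name One of `"mannitol_solid"`, `"mannitol_solid_fig3"`,
#'   `"erythritol_solid"`, `"mannitol_solution"`, `"erythritol_solution"`,
#'   `"water"`.
#' @param concentration_g_ml Solute concentration in g/mL (solution presets
#'   only), within \[0, 1\].  At concentration 0 a solution preset degenerates
#'   to the pure-water model.
#' @return A list with elements `name`, `model` ([material_model()]),
#'   `geometry` ([sample_geometry()]), and `extraction` (a list of
#'   recommended pipeline settings for this geometry).
#' @examples
#' p <- tds_preset("mannitol_solid")
#' p$model
#' @export
tds_preset <- function(name, concentration_g_ml = 1.0) {
  cat <- load_preset_catalogue()
  if (!name %in% names(cat$presets))
    tds_stop("unknown_preset", sprintf(
      "unknown preset '%s' (available: %s)", name,
      paste(names(cat$presets), collapse = ", ")))
  p <- cat$presets[[name]]
  solventy <- identical(p$kind, "liquid_cell")
  centers <- as.numeric(p$centers_thz)
  strengths <- as.numeric(p$strengths)
  if (solventy) {
    if (!is_number(concentration_g_ml) ||
        concentration_g_ml < 0 || concentration_g_ml > 1)
      tds_stop("invalid_parameter",
               "concentration_g_ml must lie in [0, 1]")
    # pure solvent preset (no solute lines) has zero solute volume fraction
    phi <- if (length(centers) > 0)
      concentration_g_ml / cat$rho_solute_g_ml else 0
  }
  if (solventy && length(centers) > 0) strengths <- strengths * phi
  keep <- strengths > 0
  osc <- Map(function(c0, s) lorentz_oscillator(c0, s, p$gamma_thz),
             centers[keep], strengths[keep])
  w <- cat$water
  model <- material_model(
    eps_inf = p$eps_inf,
    oscillators = unname(osc),
    solvent = if (solventy)
      debye_water(w$eps_static, w$eps_intermediate, w$eps_inf_w,
                  w$tau1_ps, w$tau2_ps),
    solute_volume_fraction = if (solventy) phi)
  extraction <- cat$extraction_defaults[[p$kind]]
  extraction$anchor_band_thz <- as.numeric(extraction$anchor_band_thz)
  list(name = name, model = model,
       geometry = sample_geometry(p$d_mm, p$kind),
       extraction = extraction)
}

#' Simulate a full tablet or liquid-cell measurement
#'
#' Convenience wrappers producing matched reference/sample trace pairs the
#' way the spectrometer would: one clean pulse is propagated through the
#' reference path and through the specimen, and independent seeded detector
#' noise is added to each transient (reference uses `seed`, sample
#' `seed + 1`; the noise amplitude is defined against the reference peak).
#'
#' `simulate_tablet` references against the empty beam path.
#' `simulate_solution` references against the water-filled cell (differential
#' measurement: the cell windows and the bulk of the water background cancel
#' in the extracted spectra).  Set `reference = "empty"` to reference against
#' the empty cell instead, as used for raw concentration-series traces.
#'
#' @param preset Preset name (see [tds_preset()]) or the list returned by it.
#' @param snr Amplitude signal-to-noise ratio of the detector.
#' @param seed Root integer seed.
#' @param pulse Optional noise-free reference pulse; defaults to
#'   `generate_reference_pulse(snr = Inf)`.
#' @return A list with `reference` and `sample` traces, the `preset`, and
#'   `d_mm`.
#' @examples
#' m <- simulate_tablet("mannitol_solid", snr = 1000, seed = 42)
#' oc <- extract_optical_constants(m$sample, m$reference, m$d_mm,
#'                                 options = m$preset$extraction)
#' @export
simulate_tablet <- function(preset, snr = 1000, seed = 42, pulse = NULL) {
  if (is.character(preset)) preset <- tds_preset(preset)
  if (!identical(preset$geometry$kind, "tablet"))
    tds_stop("invalid_parameter", "simulate_tablet needs a tablet preset")
  if (is.null(pulse)) pulse <- generate_reference_pulse(snr = Inf)
  peak <- max(abs(pulse$e))
  sample_clean <- transmit(pulse, preset$model, preset$geometry)
  list(reference = add_noise(pulse, snr, seed, reference_peak = peak),
       sample = add_noise(sample_clean, snr, seed + 1L, reference_peak = peak),
       preset = preset, d_mm = preset$geometry$d_mm)
}

#' @rdname simulate_tablet
#' @param concentration_g_ml Solute concentration in g/mL.
#' @param reference `"water"` for the water-filled cell (default) or
#'   `"empty"` for the empty cell.
#' @export
simulate_solution <- function(preset, concentration_g_ml = 1.0, snr = 10000,
                              seed = 42, reference = c("water", "empty"),
                              pulse = NULL) {
  reference <- match.arg(reference)
  if (is.character(preset))
    preset <- tds_preset(preset, concentration_g_ml = concentration_g_ml)
  if (!identical(preset$geometry$kind, "liquid_cell"))
    tds_stop("invalid_parameter", "simulate_solution needs a liquid_cell preset")
  if (is.null(pulse)) pulse <- generate_reference_pulse(snr = Inf)
  peak <- max(abs(pulse$e))
  ref_clean <- if (reference == "water") {
    transmit(pulse, tds_preset("water")$model, preset$geometry)
  } else {
    pulse
  }
  sample_clean <- transmit(pulse, preset$model, preset$geometry)
  list(reference = add_noise(ref_clean, snr, seed, reference_peak = peak),
       sample = add_noise(sample_clean, snr, seed + 1L, reference_peak = peak),
       preset = preset, d_mm = preset$geometry$d_mm,
       reference_kind = reference)
}
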