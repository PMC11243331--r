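#' Frequency-domain representation of a transient
#'
#' Discrete analogue of the Fourier integral \eqn{F(j\omega) = \int f(t)
#' e^{-j\omega t}\,dt}: the FFT of the (optionally windowed, zero-padded)
#' trace scaled by the sampling step, restricted to the positive frequency
#' half.  The unwrapped spectral phase is attached.
#'
#' @param trace A [time_trace()] with at least 64 samples.
#' @param window `"none"` (rectangular, default) or `"hann"`.  The single-pass
#'   forward model has no echoes to suppress, and windowing biases peak
#'   amplitudes, so the rectangular window is the default.
#' @param pad_factor Zero-padding factor: the trace is padded to `pad_factor`
#'   times the next power of two.  One of 1, 2, 4, 8.
#' @return An object of class `tds_spectrum`: list with `nu_thz` (strictly
#'   increasing positive grid, step \eqn{1/(N_{pad}\,dt)}), complex `amp`,
#'   `phase_unwrapped`, and `dt_ps`.
#' @examples
#' sp <- fft_spectrum(generate_reference_pulse(snr = Inf))
#' sp$nu_thz[which.max(Mod(sp$amp))]  # spectral peak position
#' @export
fft_spectrum <- function(trace, window = c("none", "hann"), pad_factor = 4) {
  window <- match.arg(window)
  stopifnot(inherits(trace, "tds_trace"))
  if (length(trace$e) < 64L)
    tds_stop("insufficient_data", "need at least 64 samples")
  if (!pad_factor %in% c(1L, 2L, 4L, 8L))
    tds_stop("invalid_parameter", "pad_factor must be 1, 2, 4 or 8")
  n <- length(trace$e)
  dt <- dt_ps(trace)
  e <- trace$e
  if (window == "hann") {
    k <- seq_len(n) - 1L
    e <- e * 0.5 * (1 - cos(2 * pi * k / (n - 1)))
  }
  m <- pad_factor * 2^ceiling(log2(n))
  padded <- c(e, numeric(m - n))
  spec <- stats::fft(padded) * dt
  half <- m %/% 2
  idx <- 2:(half + 1)                       # positive frequencies only
  amp <- spec[idx]
  out <- list(nu_thz = seq_len(half) / (m * dt),
              amp = amp,
              phase_unwrapped = unwrap_phase(Arg(amp)),
              dt_ps = dt, window = window, pad_factor = pad_factor)
  class(out) <- "tds_spectrum"
  out
}

#' @export
print.tds_spectrum <- function(x, ...) {
  cat(sprintf("<tds_spectrum> %d points, %.4g - %.4g THz (step %.4g THz)\n",
              length(x$nu_thz), x$nu_thz[1], max(x$nu_thz),
              x$nu_thz[2] - x$nu_thz[1]))
  invisible(x)
}

## remove 2*pi jumps so adjacent differences stay below pi in magnitude
unwrap_phase <- function(p) {
  d <- diff(p)
  p - c(0, cumsum(round(d / (2 * pi)))) * 2 * pi
}

#' Spectral phase difference between sample and reference
#'
#' Computes the physical phase delay accumulated in the sample,
#' \eqn{\varphi(\omega) = (n_s(\omega) - 1)\,\omega d / c} for a transparent
#' slab.  The principal-value argument difference between the two spectra is
#' unwrapped along increasing frequency; because the package's FFT uses the
#' \eqn{e^{-j\omega t}} convention, a pure delay appears with a negative
#' argument, so the unwrapped difference is negated to make the delay of an
#' optically dense sample positive.  Finally the remaining \eqn{2\pi k}
#' ambiguity is anchored by fitting a straight line over a low-frequency band
#' and removing the multiple of \eqn{2\pi} closest to its zero-frequency
#' intercept (the true phase delay extrapolates to zero at DC).
#'
#' @param sample,reference [fft_spectrum()] objects on identical grids.
#' @param anchor_band_thz Two-element band (THz) over which the anchoring
#'   line is fitted; 0.2--0.4 THz by default, standard THz-TDS practice.
#' @return Numeric vector of unwrapped phase differences (radians) per grid
#'   point.
#' @export
phase_difference <- function(sample, reference, anchor_band_thz = c(0.2, 0.4)) {
  stopifnot(inherits(sample, "tds_spectrum"),
            inherits(reference, "tds_spectrum"))
  if (length(sample$nu_thz) != length(reference$nu_thz) ||
      max(abs(sample$nu_thz - reference$nu_thz)) > 1e-12 * max(sample$nu_thz))
    tds_stop("incompatible_spectra",
             "sample and reference spectra are on different grids")
  dphi <- Arg(sample$amp * Conj(reference$amp))
  phi <- -unwrap_phase(dphi)
  nu <- sample$nu_thz
  sel <- nu >= anchor_band_thz[1] & nu <= anchor_band_thz[2]
  if (sum(sel) >= 2) {
    fit <- stats::lm.fit(cbind(1, nu[sel]), phi[sel])
    intercept <- fit$coefficients[1]
    phi <- phi - 2 * pi * round(intercept / (2 * pi))
  }
  phi
}

#' Refractive index from the phase delay
#'
#' Inverts the slab phase delay: \eqn{n(\omega) = 1 + c\,\varphi(\omega) /
#' (\omega d)} with \eqn{\omega = 2\pi\nu}.  No clamping is applied; values
#' outside the validity band are reported as-is and flagged downstream.
#'
#' @param phi Unwrapped phase difference (radians) per grid point.
#' @param nu_thz Frequency grid in THz, positive.
#' @param d_mm Sample thickness in millimetres.
#' @return Numeric vector of the real refractive index per grid point.
#' @export
refractive_index <- function(phi, nu_thz, d_mm) {
  if (!is_number(d_mm) || d_mm <= 0)
    tds_stop("invalid_geometry", "thickness must be positive")
  if (any(nu_thz <= 0))
    tds_stop("invalid_input", "frequencies must be positive")
  1 + C_MM_PS * phi / (2 * pi * nu_thz * d_mm)
}

#' Fresnel-corrected power absorption coefficient
#'
#' \deqn{\alpha(\omega) = -\frac{2}{d}\,\ln\!\left[
#'   \frac{|E_{s}(\omega)|}{|E_{ref}(\omega)|}\cdot
#'   \frac{(n_s(\omega)+1)^2}{4 n_s(\omega)}\right]}
#' with \eqn{d} in cm, so \eqn{\alpha} is the power (intensity) absorption
#' coefficient in cm\eqn{^{-1}}; the field ratio of a lossy slab carries
#' \eqn{e^{-\alpha d/2}}.  When the amplitude ratio equals the two-interface
#' Fresnel factor \eqn{4n/(n+1)^2} the sample is lossless and \eqn{\alpha = 0}.
#'
#' @param amp_sample,amp_reference Spectral magnitudes on a common grid;
#'   `amp_reference` must be positive wherever evaluated.
#' @param n Real refractive index per grid point (from [refractive_index()]).
#' @param d_mm Sample thickness in millimetres.
#' @return Numeric vector, absorption coefficient in cm^-1 per grid point.
#' @export
absorption_coefficient <- function(amp_sample, amp_reference, n, d_mm) {
  if (!is_number(d_mm) || d_mm <= 0)
    tds_stop("invalid_geometry", "thickness must be positive")
  if (any(amp_reference <= 0))
    tds_stop("division_domain", "reference magnitude must be positive")
  d_cm <- d_mm / 10
  rho <- amp_sample / amp_reference
  # out-of-band points where n <= 0 give NaN; they are reported but flagged
  suppressWarnings(-(2 / d_cm) * log(rho * (n + 1)^2 / (4 * n)))
}

#' Dynamic-range validity band of a measurement
#'
#' Estimates the spectral noise floor as the median reference magnitude above
#' 5 THz (well beyond the pulse bandwidth) and returns the widest contiguous
#' frequency interval in which the reference magnitude exceeds that floor by
#' at least `floor_db` (amplitude decibels).  Optical constants and peak
#' reports are only trusted inside this interval.
#'
#' @param reference A [fft_spectrum()] of the reference trace.  The grid must
#'   extend beyond 5 THz (sampling step below 0.1 ps).
#' @param floor_db Required dynamic-range margin in dB (default 20).
#' @return Numeric `c(nu_min, nu_max)` in THz.
#' @export
valid_band <- function(reference, floor_db = 20) {
  stopifnot(inherits(reference, "tds_spectrum"))
  if (!is_number(floor_db) || floor_db <= 0)
    tds_stop("invalid_parameter", "floor_db must be positive")
  mag <- Mod(reference$amp)
  nu <- reference$nu_thz
  tail_sel <- nu > 5
  if (!any(tail_sel))
    tds_stop("invalid_input",
             "grid must extend beyond 5 THz to estimate the noise floor")
  floor_est <- stats::median(mag[tail_sel])
  thresh <- floor_est * 10^(floor_db / 20)
  ok <- mag > thresh
  if (!any(ok)) tds_stop("empty_band",
                         "no frequency clears the dynamic-range threshold")
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  widest <- runs[which.max(r$lengths[runs])]
  c(nu[starts[widest]], nu[ends[widest]])
}

#' Extracted optical constants
#'
#' Runs the full deterministic closed-form extraction chain on a matched
#' trace pair: FFT of both traces, unwrapped anchored phase difference,
#' refractive index from the phase delay, Fresnel-corrected absorption
#' coefficient, and the dynamic-range validity band.  All options are
#' recorded in the result's `options` element.
#'
#' @param sample,reference [time_trace()] objects on identical time axes.
#' @param d_mm Sample thickness in millimetres.
#' @param options Named list overriding the defaults `window = "none"`,
#'   `pad_factor = 4`, `anchor_band_thz = c(0.2, 0.4)`, `floor_db = 20`.
#'   Presets carry recommended values in `$extraction` (tablets 30 dB,
#'   liquid cells 40 dB: thin layers amplify amplitude noise in alpha by
#'   2/d, and the low-frequency band edge amplifies phase noise in n).
#'   Unrelated entries are ignored, so a preset's `$extraction` list can be
#'   passed unchanged.
#' @return An object of class `optical_constants`: list with `nu_thz`, `n`,
#'   `alpha_cm`, `in_band` (logical), `band` (`c(nu_min, nu_max)`), `d_mm`,
#'   `amp_sample`, `amp_reference`, and `options`.
#' @examples
#' m <- simulate_tablet("erythritol_solid", snr = 1000, seed = 42)
#' oc <- extract_optical_constants(m$sample, m$reference, m$d_mm,
#'                                 options = m$preset$extraction)
#' range(oc$n[oc$in_band])
#' @export
extract_optical_constants <- function(sample, reference, d_mm,
                                      options = list()) {
  stopifnot(inherits(sample, "tds_trace"), inherits(reference, "tds_trace"))
  if (length(sample$t_ps) != length(reference$t_ps) ||
      max(abs(sample$t_ps - reference$t_ps)) > 1e-9 * diff(range(reference$t_ps)))
    tds_stop("incompatible_traces", "traces must share one time axis")
  defaults <- list(window = "none", pad_factor = 4,
                   anchor_band_thz = c(0.2, 0.4), floor_db = 20)
  opt <- utils::modifyList(defaults, options[names(options) %in% names(defaults)])
  sp_s <- fft_spectrum(sample, window = opt$window, pad_factor = opt$pad_factor)
  sp_r <- fft_spectrum(reference, window = opt$window, pad_factor = opt$pad_factor)
  phi <- phase_difference(sp_s, sp_r, anchor_band_thz = opt$anchor_band_thz)
  n <- refractive_index(phi, sp_s$nu_thz, d_mm)
  alpha <- absorption_coefficient(Mod(sp_s$amp), Mod(sp_r$amp), n, d_mm)
  band <- valid_band(sp_r, floor_db = opt$floor_db)
  in_band <- sp_s$nu_thz >= band[1] & sp_s$nu_thz <= band[2]
  out <- list(nu_thz = sp_s$nu_thz, n = n, alpha_cm = alpha,
              in_band = in_band, band = band, d_mm = d_mm,
              amp_sample = Mod(sp_s$amp), amp_reference = Mod(sp_r$amp),
              options = opt)
  class(out) <- "optical_constants"
  out
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf(
    "<optical_constants> band %.3g - %.3g THz; n in [%.4g, %.4g], max alpha %.4g cm^-1 (in band)\n",
    x$band[1], x$band[2], min(x$n[x$in_band]), max(x$n[x$in_band]),
    max(x$alpha_cm[x$in_band])))
  invisible(x)
}

#' @export
plot.optical_constants <- function(x, what = c("alpha", "n"), ...) {
  what <- match.arg(what)
  sel <- x$in_band
  if (what == "alpha")
    plot(x$nu_thz[sel], x$alpha_cm[sel], type = "l",
         xlab = "frequency (THz)", ylab = expression(alpha ~ (cm^-1)), ...)
  else
    plot(x$nu_thz[sel], x$n[sel], type = "l",
         xlab = "frequency (THz)", ylab = "refractive index", ...)
  invisible(x)
}

#' Write extracted optical constants as CSV (+ JSON sidecar)
#'
#' Writes `nu_THz,n,alpha_cm,in_band` rows and, alongside, a `.json` sidecar
#' recording the extraction options, band and thickness.
#'
#' @param oc An `optical_constants` object.
#' @param path CSV output path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_optical_constants <- function(oc, path) {
  stopifnot(inherits(oc, "optical_constants"))
  df <- data.frame(nu_THz = oc$nu_thz, n = oc$n, alpha_cm = oc$alpha_cm,
                   in_band = oc$in_band)
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(list(d_mm = oc$d_mm, band_thz = oc$band,
                            options = oc$options),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
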