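#' Simulate one solution trace at a given concentration
#'
#' Builds the solution dielectric model at concentration `c` (solute volume
#' fraction \eqn{\phi = c/\rho_{solute}}, \eqn{\rho_{solute}} = 1.5 g/mL,
#' linear mixing), transmits the clean reference pulse through the liquid
#' cell, and adds seeded detector noise.  At concentration 0 the model -- and
#' hence the trace at the same seed -- is identical to the pure-water cell.
#'
#' @param concentration_g_ml Concentration in g/mL, within \[0, 1\].
#' @param solute `"mannitol_solution"` or `"erythritol_solution"`.
#' @param snr Amplitude signal-to-noise ratio (`Inf` for noise-free).
#' @param seed Integer noise seed.
#' @param pulse Optional noise-free reference pulse.
#' @return A [time_trace()].
#' @export
simulate_solution_trace <- function(concentration_g_ml, solute, snr = 1000,
                                    seed = 42, pulse = NULL) {
  preset <- tds_preset(solute, concentration_g_ml = concentration_g_ml)
  if (!identical(preset$geometry$kind, "liquid_cell"))
    tds_stop("invalid_parameter", "solute must name a solution preset")
  if (is.null(pulse)) pulse <- generate_reference_pulse(snr = Inf)
  tr <- transmit(pulse, preset$model, preset$geometry)
  tr <- add_noise(tr, snr, seed, reference_peak = max(abs(pulse$e)))
  tr$label <- sprintf("%s, %.3g g/mL", solute, concentration_g_ml)
  tr
}

#' Simulate a concentration series in the liquid cell
#'
#' One liquid-cell measurement per concentration against the shared
#' empty-cell reference (raw traces: absolute signal strength grows with
#' concentration because solute displaces the strongly absorbing water).
#' Noise is independent per trace but fully reproducible: trace `i` uses
#' seed `seed + i`.
#'
#' @param solute `"mannitol_solution"` or `"erythritol_solution"`.
#' @param concentrations_g_ml Strictly increasing concentrations in
#'   \[0, 1\] g/mL; default five equally spaced values 0.2--1.0.
#' @param snr Amplitude signal-to-noise ratio.
#' @param seed Root integer seed.
#' @return An object of class `concentration_series`: list with
#'   `concentrations_g_ml`, `traces` (list of [time_trace()]), `strengths`
#'   (peak-to-peak amplitude per trace), `reference` (the shared empty-cell
#'   reference pulse), and `solute`.
#' @examples
#' cs <- simulate_series("mannitol_solution", snr = 1000, seed = 42)
#' cbind(cs$concentrations_g_ml, cs$strengths)
#' @export
simulate_series <- function(solute,
                            concentrations_g_ml = seq(0.2, 1.0, by = 0.2),
                            snr = 1000, seed = 42) {
  conc <- as.numeric(concentrations_g_ml)
  if (length(conc) < 1 || any(!is.finite(conc)) ||
      any(conc < 0) || any(conc > 1))
    tds_stop("invalid_parameter", "concentrations must lie in [0, 1] g/mL")
  if (length(conc) > 1 && any(diff(conc) <= 0))
    tds_stop("invalid_parameter", "concentrations must be strictly increasing")
  pulse <- generate_reference_pulse(snr = Inf)
  traces <- lapply(seq_along(conc), function(i)
    simulate_solution_trace(conc[i], solute, snr = snr,
                            seed = as.integer(seed) + i, pulse = pulse))
  structure(list(concentrations_g_ml = conc, traces = traces,
                 strengths = vapply(traces, signal_strength, numeric(1)),
                 reference = pulse, solute = solute, snr = snr,
                 seed = as.integer(seed)),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> %s, %d concentrations\n",
              x$solute, length(x$concentrations_g_ml)))
  print(data.frame(conc_g_per_ml = x$concentrations_g_ml,
                   strength = x$strengths), row.names = FALSE, digits = 5)
  invisible(x)
}

#' Time-domain signal strength of a trace
#'
#' Peak-to-peak field amplitude, `max(e) - min(e)`: the raw per-trace signal
#' metric used to relate solution measurements across concentrations.  It is
#' homogeneous of degree one in the field and invariant under time-axis
#' shifts.
#'
#' @param trace A [time_trace()].
#' @return A scalar.
#' @export
signal_strength <- function(trace) {
  stopifnot(inherits(trace, "tds_trace"))
  max(trace$e) - min(trace$e)
}

#' Frequency-domain signal strength (alternative metric)
#'
#' Integrated spectral magnitude over a band; offered as an alternative to
#' the time-domain peak-to-peak metric.
#'
#' @param trace A [time_trace()].
#' @param band_thz Integration band, THz.
#' @return A scalar.
#' @export
spectral_strength <- function(trace, band_thz = c(0.2, 2.6)) {
  sp <- fft_spectrum(trace)
  sel <- sp$nu_thz >= band_thz[1] & sp$nu_thz <= band_thz[2]
  sum(Mod(sp$amp[sel])) * (sp$nu_thz[2] - sp$nu_thz[1])
}

#' Signal-strength versus concentration relationship
#'
#' Quantifies how the per-trace signal strength tracks concentration:
#' Spearman rank correlation, strict monotonicity, and the sign of the
#' linear-fit slope.  The series module deliberately reports raw signal
#' metrics rather than absorption coefficients: with water dominating the
#' in-band absorption, per-concentration alpha spectra are not compared.
#'
#' @param series A `concentration_series` with at least 3 concentrations.
#' @return List with `spearman_rho`, `monotone` (TRUE iff strengths are
#'   strictly increasing), and `slope_sign`.
#' @examples
#' cs <- simulate_series("mannitol_solution", snr = 1000, seed = 42)
#' strength_concentration_relation(cs)
#' @export
strength_concentration_relation <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  if (length(series$concentrations_g_ml) < 3)
    tds_stop("insufficient_series", "need at least 3 concentrations")
  rho <- stats::cor(series$concentrations_g_ml, series$strengths,
                    method = "spearman")
  slope <- stats::lm.fit(cbind(1, series$concentrations_g_ml),
                         series$strengths)$coefficients[2]
  list(spearman_rho = unname(rho),
       monotone = all(diff(series$strengths) > 0),
       slope_sign = unname(sign(slope)))
}

#' Write a concentration series to disk
#'
#' Writes one ASCII trace per concentration plus `series.csv`
#' (`conc_g_per_ml,strength`) and a JSON summary.
#'
#' @param series A `concentration_series`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "concentration_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(series$traces))
    write_trace(series$traces[[i]],
                file.path(dir, sprintf("trace_%02d.txt", i)))
  df <- data.frame(conc_g_per_ml = series$concentrations_g_ml,
                   strength = series$strengths)
  utils::write.csv(format(df, digits = 12, trim = TRUE),
                   file.path(dir, "series.csv"),
                   row.names = FALSE, quote = FALSE)
  rel <- strength_concentration_relation(series)
  jsonlite::write_json(c(list(solute = series$solute, snr = series$snr,
                              seed = series$seed), rel),
                       file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
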