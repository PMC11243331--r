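#' Construct a peak set
#'
#' A `peak_set` is an ordered list of spectral peaks, either detected from an
#' extracted spectrum or taken from a published table.  Centres must be
#' strictly increasing and no two centres may coincide within 1e-6 THz.
#'
#' @param center_thz Peak centre frequencies, THz.
#' @param height_cm1 Peak height above the local baseline, cm^-1 (`NA` for
#'   literature lists).
#' @param prominence_cm1 Topographic prominence, cm^-1 (`NA` for literature
#'   lists).
#' @param fwhm_thz Full width at half prominence, THz (`NA` for literature
#'   lists).
#' @param source One of `"extracted"`, `"literature"`, `"dft"`.
#' @param label Free text (include units when the list is not in THz, e.g.
#'   Raman shifts; no unit conversion is ever attempted).
#' @return An object of class `peak_set` with elements `peaks` (data frame),
#'   `source`, `label`.
#' @examples
#' peak_set(c(0.94, 1.73, 2.43), source = "literature", label = "example")
#' @export
peak_set <- function(center_thz, height_cm1 = NA_real_,
                     prominence_cm1 = NA_real_, fwhm_thz = NA_real_,
                     source = c("extracted", "literature", "dft"),
                     label = "") {
  source <- match.arg(source)
  center_thz <- as.numeric(center_thz)
  k <- length(center_thz)
  if (k > 1 && any(diff(center_thz) < 1e-6))
    tds_stop("invalid_peaks",
             "centres must be strictly increasing and separated by > 1e-6 THz")
  rep_len2 <- function(x) rep_len(as.numeric(x), k)
  pk <- data.frame(center_thz = center_thz,
                   height_cm1 = rep_len2(height_cm1),
                   prominence_cm1 = rep_len2(prominence_cm1),
                   fwhm_thz = rep_len2(fwhm_thz))
  bad <- function(v) any(!is.na(v) & v <= 0)
  if (bad(pk$prominence_cm1) || bad(pk$fwhm_thz) || bad(pk$center_thz))
    tds_stop("invalid_peaks", "centres, prominences and widths must be positive")
  structure(list(peaks = pk, source = source, label = as.character(label)[1]),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s), source = %s%s\n", nrow(x$peaks),
              x$source, if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  if (nrow(x$peaks) > 0) print(x$peaks, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
length.peak_set <- function(x) nrow(x$peaks)

## running minimum over a centred window of half_bins on each side
rolling_min <- function(y, half_bins) {
  n <- length(y)
  vapply(seq_len(n), function(i)
    min(y[max(1L, i - half_bins):min(n, i + half_bins)]), numeric(1))
}

## topographic prominence of the peak at index i of y (scipy convention):
## height above the higher of the two minima separating it from higher terrain
peak_prominence <- function(y, i) {
  side_min <- function(step) {
    j <- i + step
    m <- y[i]
    while (j >= 1L && j <= length(y) && y[j] <= y[i]) {
      if (y[j] < m) m <- y[j]
      j <- j + step
    }
    m
  }
  y[i] - max(side_min(-1L), side_min(1L))
}

## full width at half prominence by linear interpolation
peak_fwhm <- function(x, y, i, prominence) {
  level <- y[i] - prominence / 2
  cross <- function(step) {
    j <- i
    while (j + step >= 1L && j + step <= length(y) && y[j + step] > level)
      j <- j + step
    k <- j + step
    if (k < 1L || k > length(y)) return(x[j])
    # interpolate between samples j and k
    x[j] + (x[k] - x[j]) * (y[j] - level) / (y[j] - y[k])
  }
  abs(cross(1L) - cross(-1L))
}

#' Detect absorption peaks in an extracted spectrum
#'
#' Finds local maxima of the in-band absorption coefficient whose topographic
#' prominence exceeds a fraction of the in-band maximum, with optional
#' rolling-minimum baseline subtraction (required for solution spectra, where
#' the broadband water background otherwise dominates the prominence logic)
#' and optional Savitzky--Golay pre-smoothing (recommended: it suppresses
#' single-bin noise spikes near the band edges while leaving peaks, which are
#' orders of magnitude wider than a grid step, essentially untouched).
#' Detected centres are refined by parabolic interpolation through the three
#' samples around each maximum.
#'
#' @param oc An `optical_constants` object.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   in-band maximum of the (baseline-corrected) absorption; default 0.05.
#'   The threshold is relative, so detection is invariant under rescaling
#'   the spectrum.
#' @param baseline `"none"` or `"rolling_min"` (subtract the running minimum
#'   over a `baseline_window_thz` window before detection).  With
#'   `rolling_min` the baseline is undefined within half a window of the
#'   band edges, so no peaks are reported there.
#' @param baseline_window_thz Width of the rolling-minimum window, THz.
#' @param smooth_thz Savitzky--Golay (quadratic) smoothing window in THz;
#'   0 disables smoothing.
#' @return A `peak_set` with `source = "extracted"`.
#' @examples
#' m <- simulate_tablet("erythritol_solid", snr = 1000, seed = 42)
#' oc <- extract_optical_constants(m$sample, m$reference, m$d_mm,
#'                                 options = m$preset$extraction)
#' detect_peaks(oc, smooth_thz = 0.02)
#' @export
detect_peaks <- function(oc, min_prominence_frac = 0.05,
                         baseline = c("none", "rolling_min"),
                         baseline_window_thz = 0.4, smooth_thz = 0) {
  stopifnot(inherits(oc, "optical_constants"))
  baseline <- match.arg(baseline)
  if (!is_number(min_prominence_frac) ||
      min_prominence_frac <= 0 || min_prominence_frac >= 1)
    tds_stop("invalid_parameter", "min_prominence_frac must be in (0, 1)")
  if (!any(oc$in_band)) tds_stop("empty_band", "no in-band samples")
  x <- oc$nu_thz[oc$in_band]
  y <- oc$alpha_cm[oc$in_band]
  dnu <- x[2] - x[1]
  if (smooth_thz > 0) {
    bins <- round(smooth_thz / dnu)
    bins <- bins + (bins + 1L) %% 2L          # force odd
    if (bins >= 5 && bins < length(y))
      y <- signal::sgolayfilt(y, p = 2, n = bins)
  }
  # candidate lines must be local maxima of the (smoothed) absorption
  # itself; the baseline correction below only quantifies their prominence
  # against the broadband background, so a monotone background (e.g. pure
  # water) yields no candidates no matter how it is baselined
  y_raw <- y
  edge_half <- 0L
  if (baseline == "rolling_min") {
    half <- max(1L, round(baseline_window_thz / (2 * dnu)))
    y <- y - rolling_min(y, half)
    # the rolling-minimum baseline is undefined within half a window of the
    # band edges, so peaks are not reported in those margins
    edge_half <- half
  }
  n <- length(y)
  cand <- which(diff(sign(diff(y_raw))) < 0) + 1L   # strict local maxima
  cand <- cand[cand - 1L > edge_half & n - cand > edge_half]
  thresh <- min_prominence_frac * max(y)
  rows <- list()
  used <- integer(0)
  # a sloping baseline shifts the apex of the corrected curve by up to
  # ~0.01 THz relative to the raw curve; re-centre within a window well
  # below the minimum line separation
  recenter <- max(3L, round(0.025 / dnu))
  for (i in cand) {
    lo <- max(2L, i - recenter)
    hi <- min(n - 1L, i + recenter)
    i <- (lo:hi)[which.max(y[lo:hi])]
    if (i %in% used) next
    used <- c(used, i)
    prom <- peak_prominence(y, i)
    if (prom < thresh) next
    # parabolic refinement of the centre
    num <- y[i - 1] - y[i + 1]
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (den < 0) 0.5 * num / den else 0
    rows[[length(rows) + 1L]] <- data.frame(
      center_thz = x[i] + delta * dnu,
      height_cm1 = y[i],
      prominence_cm1 = prom,
      fwhm_thz = peak_fwhm(x, y, i, prom))
  }
  if (length(rows) == 0L)
    return(peak_set(numeric(0), source = "extracted", label = "no peaks"))
  df <- do.call(rbind, rows)
  df <- df[order(df$center_thz), , drop = FALSE]
  peak_set(df$center_thz, df$height_cm1, df$prominence_cm1, df$fwhm_thz,
           source = "extracted",
           label = sprintf("detected (baseline=%s, smooth=%g THz)",
                           baseline, smooth_thz))
}

#' Anomalous-dispersion check at each absorption peak
#'
#' Across a Lorentz-type resonance the refractive index decreases with
#' frequency (anomalous dispersion), a causality signature tied to the
#' absorption line by the Kramers--Kronig relations.  For every peak this
#' flags whether the least-squares slope of \eqn{n(\nu)} over the window
#' `center +/- w` is negative.
#'
#' @param oc An `optical_constants` object.
#' @param ps A `peak_set` of peaks inside the validity band.
#' @param window_thz Half-width `w` of the fit window; defaults per peak to
#'   `fwhm/2` with a floor of 0.02 THz.
#' @return Logical vector, one flag per peak (`NA`, with a warning, where
#'   the window extends outside the validity band).
#' @export
anomalous_dispersion_flags <- function(oc, ps, window_thz = NULL) {
  stopifnot(inherits(oc, "optical_constants"), inherits(ps, "peak_set"))
  if (!is.null(window_thz) && (!is_number(window_thz) || window_thz <= 0))
    tds_stop("invalid_parameter", "window_thz must be positive")
  pk <- ps$peaks
  flags <- logical(nrow(pk))
  if (nrow(pk) == 0L) return(flags)
  for (k in seq_len(nrow(pk))) {
    w <- if (!is.null(window_thz)) window_thz
         else max(pk$fwhm_thz[k] / 2, 0.02, na.rm = TRUE)
    lo <- pk$center_thz[k] - w
    hi <- pk$center_thz[k] + w
    if (lo < oc$band[1] || hi > oc$band[2]) {
      warning(sprintf("peak at %.3g THz: window extends outside band, skipped",
                      pk$center_thz[k]))
      flags[k] <- NA
      next
    }
    sel <- oc$nu_thz >= lo & oc$nu_thz <= hi
    fit <- stats::lm.fit(cbind(1, oc$nu_thz[sel]), oc$n[sel])
    flags[k] <- fit$coefficients[2] < 0
  }
  flags
}

#' Kramers--Kronig reconstruction of the refractive index
#'
#' Reconstructs \eqn{n(\nu)} from the measured absorption via the
#' subtractive Kramers--Kronig relation
#' \deqn{n_{KK}(\nu) = n_\infty + \frac{c}{2\pi^2}\,
#'   \mathcal{P}\!\int \frac{\alpha(\nu')}{\nu'^2 - \nu^2}\,d\nu'}
#' evaluated with the Maclaurin (alternating-point) principal-value
#' quadrature over the validity band: each output point uses only input
#' points of opposite grid parity, which skips the singular node exactly.
#' The integral is truncated to the band; the resulting bias is small when
#' all resonances lie well inside it and is quantified by the grid-doubling
#' self-convergence test in the package test-suite.
#'
#' @param oc An `optical_constants` object (uniform grid).
#' @param n_inf Asymptotic index; defaults to the extracted index at the
#'   high-frequency band edge (median of the last 11 in-band samples).
#' @return Numeric vector of \eqn{n_{KK}} per grid point (`NA` outside the
#'   validity band).
#' @examples
#' m <- simulate_tablet("mannitol_solid", snr = 1000, seed = 42)
#' oc <- extract_optical_constants(m$sample, m$reference, m$d_mm,
#'                                 options = m$preset$extraction)
#' nkk <- kk_refractive_index(oc)
#' mean(abs(nkk - oc$n), na.rm = TRUE)
#' @export
kk_refractive_index <- function(oc, n_inf = NULL) {
  stopifnot(inherits(oc, "optical_constants"))
  idx <- which(oc$in_band)
  if (length(idx) < 10L)
    tds_stop("insufficient_support",
             "validity band must contain at least 10 grid points")
  nu <- oc$nu_thz[idx] * 1e12                  # Hz
  alpha <- oc$alpha_cm[idx] * 100              # 1/m
  if (is.null(n_inf)) {
    tail_n <- oc$n[idx[max(1L, length(idx) - 10L):length(idx)]]
    n_inf <- stats::median(tail_n)
  }
  if (!is_number(n_inf) || n_inf < 1)
    tds_stop("invalid_parameter", "n_inf must be a number >= 1")
  h <- nu[2] - nu[1]
  m <- length(nu)
  nu2 <- nu^2
  odd <- seq(1L, m, 2L)
  even <- seq(2L, m, 2L)
  pref <- C_M_S / (2 * pi^2) * 2 * h
  s <- vapply(seq_len(m), function(i) {
    j <- if (i %% 2L == 0L) odd else even
    sum(alpha[j] / (nu2[j] - nu2[i]))
  }, numeric(1))
  out <- rep(NA_real_, length(oc$nu_thz))
  out[idx] <- n_inf + pref * s
  out
}

#' Read and write peak sets (JSON or flat CSV)
#'
#' JSON layout: `{label, source, peaks: [{center_thz, height_cm1,
#' prominence_cm1, fwhm_thz}, ...]}`.  CSV carries the same four columns;
#' label and source travel in `#` header comments.
#'
#' @param ps A `peak_set`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path` (`write_peak_set`) or a `peak_set` (`read_peak_set`).
#' @export
write_peak_set <- function(ps, path) {
  stopifnot(inherits(ps, "peak_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(label = ps$label, source = ps$source,
           peaks = ps$peaks),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  } else {
    con <- file(path, "w")
    writeLines(c(sprintf("# label: %s", ps$label),
                 sprintf("# source: %s", ps$source)), con)
    utils::write.table(ps$peaks, con, sep = ",", row.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  invisible(path)
}

#' @rdname write_peak_set
#' @export
read_peak_set <- function(path) {
  if (!file.exists(path)) tds_stop("io", sprintf("no such file: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pk <- as.data.frame(obj$peaks)
    if (nrow(pk) == 0)
      return(peak_set(numeric(0), source = obj$source, label = obj$label))
    peak_set(pk$center_thz, pk$height_cm1, pk$prominence_cm1, pk$fwhm_thz,
             source = obj$source, label = obj$label)
  } else {
    raw <- readLines(path)
    hdr <- grep("^#", raw, value = TRUE)
    get <- function(key, default) {
      ln <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
      if (length(ln)) sub(sprintf("^#\\s*%s:\\s*", key), "", ln[1]) else default
    }
    pk <- utils::read.table(text = raw[!grepl("^#", raw)], header = TRUE,
                            sep = ",")
    peak_set(pk$center_thz, pk$height_cm1, pk$prominence_cm1, pk$fwhm_thz,
             source = get("source", "literature"), label = get("label", ""))
  }
}
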