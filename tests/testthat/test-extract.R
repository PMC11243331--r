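test_that("fft_spectrum matches the naive discrete Fourier sum", {
  tr <- generate_reference_pulse(n_points = 512, dt_ps = 0.05,
                                 width_ps = 0.2, snr = Inf)
  sp <- fft_spectrum(tr, pad_factor = 1)
  # oracle: O(N^2) discrete Fourier sum at the same grid frequencies
  oracle <- naive_dft(tr$e, tr$t_ps, sp$nu_thz)
  expect_lt(max(Mod(sp$amp - oracle)) / max(Mod(oracle)), 1e-10)
})

test_that("fft_spectrum locates a pure tone and maps zero to zero", {
  t <- (0:511) * 0.05
  tone <- time_trace(t, cos(2 * pi * 1.0 * t))
  sp <- fft_spectrum(tone, window = "none", pad_factor = 1)
  expect_equal(sp$nu_thz[which.max(Mod(sp$amp))], 1.0,
               tolerance = (sp$nu_thz[2] - sp$nu_thz[1]) / 1.0)

  zero <- time_trace(t, numeric(512))
  expect_true(all(Mod(fft_spectrum(zero)$amp) == 0))

  short <- t[1:63]
  expect_error(time_trace(short, numeric(63)), class = "teraspec_invalid_trace")
  expect_error(fft_spectrum(tone, pad_factor = 3), class = "teraspec_invalid_parameter")
})

test_that("phase difference recovers a pure delay and unwraps continuously", {
  ref <- generate_reference_pulse(snr = Inf)
  sp_r <- fft_spectrum(ref)
  expect_equal(phase_difference(sp_r, sp_r), rep(0, length(sp_r$nu_thz)))

  # construct an exact spectral-domain delay of 1.554 ps
  dt_delay <- 1.554
  sp_s <- sp_r
  sp_s$amp <- sp_r$amp * exp(-2i * pi * sp_r$nu_thz * dt_delay)
  sp_s$phase_unwrapped <- NULL
  phi <- phase_difference(sp_s, sp_r)
  sel <- sp_r$nu_thz >= 0.2 & sp_r$nu_thz <= 0.4
  # oracle: analytic linear phase 2 pi nu dt of a delay
  expect_lt(max(abs(phi[sel] - 2 * pi * sp_r$nu_thz[sel] * dt_delay)), 1e-6)
  expect_true(all(abs(diff(phi)) < pi))

  other <- fft_spectrum(generate_reference_pulse(n_points = 4096, snr = Inf))
  expect_error(phase_difference(other, sp_r),
               class = "teraspec_incompatible_spectra")
})

test_that("refractive index inverts the slab phase algebraically", {
  nu <- seq(0.2, 3, by = 0.01)
  expect_equal(refractive_index(rep(0, length(nu)), nu, 1.11),
               rep(1, length(nu)))
  # oracle: algebraic inversion of phi = 2 pi nu d (n - 1) / c
  phi <- 2 * pi * nu * 1.11 * (1.42 - 1) / 0.299792458
  expect_equal(refractive_index(phi, nu, 1.11), rep(1.42, length(nu)),
               tolerance = 1e-12)
  expect_error(refractive_index(phi, nu, 0), class = "teraspec_invalid_geometry")
})

test_that("absorption coefficient obeys the Fresnel-corrected Beer-Lambert form", {
  n <- 1.5
  fres <- 4 * n / (n + 1)^2
  # lossless slab: amplitude ratio equals the Fresnel factor
  expect_equal(absorption_coefficient(fres, 1, n, 1.0), 0)
  # oracle: forward-evaluate the field ratio for alpha = 10 1/cm through 1 mm
  rho <- fres * exp(-0.5 * 10 * 0.1)
  expect_equal(absorption_coefficient(rho, 1, n, 1.0), 10, tolerance = 1e-9)
  # halving the ratio adds (2/d) ln 2
  a1 <- absorption_coefficient(rho, 1, n, 1.0)
  a2 <- absorption_coefficient(rho / 2, 1, n, 1.0)
  expect_equal(a2 - a1, 2 / 0.1 * log(2), tolerance = 1e-12)
  expect_error(absorption_coefficient(1, 0, n, 1.0),
               class = "teraspec_division_domain")
})

test_that("validity band covers the pulse bandwidth and respects the floor", {
  sp <- fft_spectrum(generate_reference_pulse(snr = Inf))
  band <- valid_band(sp, floor_db = 20)
  expect_lte(band[1], 0.3)
  expect_gte(band[2], 2.6)

  # raising the floor never widens the band
  b30 <- valid_band(sp, 30)
  expect_gte(b30[1], band[1])
  expect_lte(b30[2], band[2])

  noise <- time_trace((0:8191) * 0.05,
                      withr::with_seed(3, stats::rnorm(8192)))
  expect_error(valid_band(fft_spectrum(noise), 20),
               class = "teraspec_empty_band")
})

test_that("self-referencing yields vacuum constants; alpha is scale invariant", {
  ref <- generate_reference_pulse(snr = 1000, seed = 5)
  oc <- extract_optical_constants(ref, ref, 1.11)
  expect_true(all(abs(oc$n[oc$in_band] - 1) < 1e-12))
  expect_true(all(abs(oc$alpha_cm[oc$in_band]) < 1e-9))

  m <- cached_tablet_oc("erythritol_solid")
  sam2 <- m$meas$sample; sam2$e <- sam2$e * 7.3
  ref2 <- m$meas$reference; ref2$e <- ref2$e * 7.3
  oc2 <- extract_optical_constants(sam2, ref2, m$meas$d_mm,
                                   options = m$meas$preset$extraction)
  expect_equal(oc2$alpha_cm[oc2$in_band], m$oc$alpha_cm[m$oc$in_band],
               tolerance = 1e-12)
})

test_that("recovered index is stable under pad-factor doubling", {
  m <- cached_tablet_oc("mannitol_solid")
  opts <- m$meas$preset$extraction
  opts$pad_factor <- 8
  oc8 <- extract_optical_constants(m$meas$sample, m$meas$reference,
                                   m$meas$d_mm, options = opts)
  sel <- m$oc$in_band
  n8 <- stats::approx(oc8$nu_thz, oc8$n, m$oc$nu_thz[sel])$y
  expect_lt(max(abs(n8 - m$oc$n[sel])), 1e-4)
})

test_that("noise-free extraction inverts the forward model to high accuracy", {
  # sup-norm error vanishes in the high-SNR limit (checked at SNR 1e8)
  m <- cached_tablet_oc("mannitol_solid", snr = 1e8)
  sel <- m$oc$in_band & m$oc$nu_thz >= 0.3 & m$oc$nu_thz <= 3
  n_true <- Re(model_refractive_index(m$meas$preset$model, m$oc$nu_thz[sel]))
  # residual ~6e-5 systematic: the padded spectral grid interpolates the
  # transmission between simulation bins
  expect_lt(max(abs(m$oc$n[sel] - n_true)), 1e-4)
})
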