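test_that("reference pulse generation is seeded and noise-free at infinite SNR", {
  a <- generate_reference_pulse(snr = Inf, seed = 1)
  b <- generate_reference_pulse(snr = Inf, seed = 999)
  expect_identical(a$e, b$e)

  c1 <- generate_reference_pulse(snr = 500, seed = 7)
  c2 <- generate_reference_pulse(snr = 500, seed = 7)
  expect_identical(c1$e, c2$e)
  c3 <- generate_reference_pulse(snr = 500, seed = 8)
  expect_false(identical(c1$e, c3$e))

  expect_error(generate_reference_pulse(width_ps = -1), class = "teraspec_invalid_parameter")
  expect_error(generate_reference_pulse(dt_ps = 0), class = "teraspec_invalid_parameter")
  expect_error(generate_reference_pulse(snr = 0), class = "teraspec_invalid_parameter")
  expect_error(generate_reference_pulse(n_points = 32), class = "teraspec_invalid_parameter")
})

test_that("pulse magnitude spectrum stays within 30 dB of its peak over 0.2-2.6 THz", {
  tr <- generate_reference_pulse(n_points = 4096, dt_ps = 0.05,
                                 width_ps = 0.3, snr = Inf)
  # oracle: direct discrete Fourier sum of the analytic pulse
  nu <- seq(0.2, 2.6, by = 0.05)
  mag <- Mod(naive_dft(tr$e, tr$t_ps, nu))
  peak <- max(Mod(naive_dft(tr$e, tr$t_ps, seq(0.1, 5, by = 0.02))))
  expect_gt(min(20 * log10(mag / peak)), -30)
})

test_that("permittivity matches its closed form and limits", {
  m0 <- material_model(2.0)
  eps <- permittivity(m0, c(0.3, 1, 2.5))
  expect_equal(eps, complex(real = rep(2, 3), imaginary = 0))

  # single underdamped oscillator: Im eps peaks within gamma of nu0
  m1 <- material_model(2.0, list(lorentz_oscillator(1.3, 0.01, 0.04)))
  nu <- seq(0.5, 2.5, by = 1e-4)
  im <- Im(permittivity(m1, nu))
  expect_true(all(im >= 0))
  expect_lt(abs(nu[which.max(im)] - 1.3), 0.04)

  # high-frequency limit returns to the background
  far <- permittivity(m1, 130)
  expect_lt(Mod(far - 2.0), 1e-2 * 0.01)

  expect_error(permittivity(m1, numeric(0)), class = "teraspec_invalid_input")
  expect_error(permittivity(m1, c(1, -2)), class = "teraspec_invalid_input")
  expect_error(lorentz_oscillator(1, 0.01, 2), class = "teraspec_invalid_parameter")
})

test_that("vacuum transmission is the identity and a lossless slab delays the pulse", {
  ref <- generate_reference_pulse(snr = Inf)
  vac <- transmit(ref, material_model(1), sample_geometry(1.11, "tablet"))
  expect_lt(max(abs(vac$e - ref$e)), 1e-12 * max(abs(ref$e)))

  slab <- transmit(ref, material_model(1.42^2), sample_geometry(1.11, "tablet"))
  delay <- slab$t_ps[which.max(slab$e)] - ref$t_ps[which.max(ref$e)]
  # analytic delay (n-1) d / c = 1.5551 ps, located to within one sample
  expect_equal(delay, (1.42 - 1) * 1.11 / 0.299792458, tolerance = 0.05 / 1.55)
})

test_that("every preset is passive (|T| <= 1) and causal", {
  ref <- generate_reference_pulse(snr = Inf)
  sp_ref <- fft_spectrum(ref)
  for (name in c("mannitol_solid", "mannitol_solid_fig3", "erythritol_solid",
                 "mannitol_solution", "erythritol_solution", "water")) {
    p <- tds_preset(name)
    sam <- transmit(ref, p$model, p$geometry)
    sp_sam <- fft_spectrum(sam)
    ratio <- Mod(sp_sam$amp) / Mod(sp_ref$amp)
    sel <- sp_ref$nu_thz <= 9  # away from the empty Nyquist region
    expect_true(all(ratio[sel] <= 1 + 1e-9), label = paste(name, "passivity"))
    expect_gte(sam$t_ps[which.max(abs(sam$e))],
               ref$t_ps[which.max(abs(ref$e))])
  }
})

test_that("presets carry the published line counts and geometries", {
  man <- tds_preset("mannitol_solid")
  expect_length(man$model$oscillators, 6)
  expect_equal(man$geometry$d_mm, 1.11)
  expect_equal(vapply(man$model$oscillators, `[[`, 0, "nu0_thz"),
               c(0.94, 1.23, 1.73, 1.96, 2.17, 2.43))

  expect_length(tds_preset("mannitol_solid_fig3")$model$oscillators, 5)

  ery <- tds_preset("erythritol_solid")
  expect_length(ery$model$oscillators, 4)
  expect_equal(ery$geometry$d_mm, 1.15)

  sol <- tds_preset("mannitol_solution")
  expect_equal(sol$geometry$d_mm, 0.05)
  expect_equal(sol$geometry$kind, "liquid_cell")
  expect_length(sol$model$oscillators, 7)

  wat <- tds_preset("water")
  expect_length(wat$model$oscillators, 0)
  expect_s3_class(wat$model$solvent, "debye_solvent")
  # water absorption is large and grows over the band
  aw <- model_absorption_cm(wat$model, c(0.3, 0.6, 1, 1.5, 2, 2.6))
  expect_true(all(diff(aw) > 0))
  expect_gt(aw[3], 100)  # hundreds of 1/cm at 1 THz

  expect_error(tds_preset("sucrose"), class = "teraspec_unknown_preset")
})

test_that("preset model refractive index stays inside the published ranges", {
  nu <- seq(0.5, 2.6, by = 0.001)
  n_man <- Re(model_refractive_index(tds_preset("mannitol_solid")$model, nu))
  expect_true(all(n_man >= 1.40 & n_man <= 1.45))
  n_ery <- Re(model_refractive_index(tds_preset("erythritol_solid")$model, nu))
  expect_true(all(n_ery >= 1.30 & n_ery <= 1.40))
})

test_that("extraction inverts the forward model for a random two-oscillator medium", {
  set.seed(99)
  nu0 <- sort(runif(2, 0.8, 2.4))
  S <- runif(2, 0.001, 0.003)
  mod <- material_model(2.0, lapply(1:2, function(i)
    lorentz_oscillator(nu0[i], S[i], 0.05)))
  geom <- sample_geometry(1.11, "tablet")
  ref <- generate_reference_pulse(snr = Inf)
  sam <- transmit(ref, mod, geom)
  peak <- max(abs(ref$e))
  refn <- add_noise(ref, 1e4, 11)
  samn <- add_noise(sam, 1e4, 21, reference_peak = peak)
  oc <- extract_optical_constants(samn, refn, 1.11, options = list(floor_db = 30))
  # evaluate away from the band edges, where the phase noise amplification
  # c/(2 pi nu d) stays small (see the methods vignette)
  sel <- oc$in_band & oc$nu_thz >= 0.6 & oc$nu_thz <= 2.8
  n_true <- Re(model_refractive_index(mod, oc$nu_thz[sel]))
  expect_lt(max(abs(oc$n[sel] - n_true)), 1e-3)
  a_true <- model_absorption_cm(mod, oc$nu_thz[sel])
  strong <- a_true > 10
  expect_lt(max(abs(oc$alpha_cm[sel][strong] - a_true[strong]) / a_true[strong]),
            0.02)
})

test_that("degenerate media are rejected", {
  ref <- generate_reference_pulse(snr = Inf)
  expect_error(transmit(ref, material_model(1), sample_geometry(-1, "tablet")),
               class = "teraspec_invalid_geometry")
})
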