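# Independent oracles used across the suite.

# naive O(N^2) discrete Fourier sum with the e^{-i omega t} convention,
# matching the integral approximation |F| = dt * |sum e_k exp(-2pi i nu t_k)|
naive_dft <- function(e, t_ps, nu_thz) {
  dt <- mean(diff(t_ps))
  vapply(nu_thz, function(nu)
    dt * sum(e * exp(-2i * pi * nu * t_ps)), complex(1))
}

# brute-force optimal one-to-one matching: maximum number of pairs with
# |a_i - b_j| <= tol, by recursive enumeration (lists of <= 8 peaks)
brute_force_pairs <- function(a, b, tol) {
  best <- 0L
  recurse <- function(i, used_b, count) {
    if (i > length(a)) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1L, used_b, count)              # leave a_i unmatched
    for (j in seq_along(b)) {
      if (!used_b[j] && abs(a[i] - b[j]) <= tol) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L)
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(b)), 0L)
  best
}

# optical_constants object built directly from a dielectric model on a dense
# uniform grid -- lets peak/KK logic be tested against closed forms without
# running the simulator
model_oc <- function(model, nu) {
  structure(list(nu_thz = nu,
                 n = Re(model_refractive_index(model, nu)),
                 alpha_cm = model_absorption_cm(model, nu),
                 in_band = rep(TRUE, length(nu)),
                 band = range(nu), d_mm = 1,
                 amp_sample = NULL, amp_reference = NULL,
                 options = list()),
            class = "optical_constants")
}

# one shared extraction per preset/snr/seed so expensive stages run once
.sim_cache <- new.env(parent = emptyenv())
cached_tablet_oc <- function(preset, snr = 1000, seed = 42) {
  key <- paste(preset, snr, seed, sep = "|")
  if (is.null(.sim_cache[[key]])) {
    m <- simulate_tablet(preset, snr = snr, seed = seed)
    .sim_cache[[key]] <- list(
      meas = m,
      oc = extract_optical_constants(m$sample, m$reference, m$d_mm,
                                     options = m$preset$extraction))
  }
  .sim_cache[[key]]
}
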