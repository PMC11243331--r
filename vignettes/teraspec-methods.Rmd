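---
title: "teraspec: models, extraction chain, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{teraspec: models, extraction chain, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teraspec)
```

## What the package models

Terahertz time-domain spectroscopy (THz-TDS) measures the electric field of a
picosecond single-cycle pulse coherently, once through a reference path and
once through a specimen.  Because both amplitude and phase are recorded, the
complex optical constants follow in closed form: the refractive index from
the spectral phase delay, the absorption coefficient from the amplitude ratio
after a Fresnel interface correction.  The package implements that chain for
two measurement geometries used in the study of the sugar alcohols mannitol
and erythritol:

* **pressed tablets** (1.11 mm mannitol, 1.15 mm erythritol) measured against
  the empty beam path, and
* a **microfluidic liquid cell** with a 50 µm solution layer between
  THz-transparent COC windows, which makes transmission measurements possible
  despite liquid water's very strong THz absorption.

No raw instrument data are distributed with the publication this workflow
targets, so the package ships a synthetic measurement generator whose presets
are parameterised from the published quantities (line positions, index
ranges, geometries).  Everything downstream — extraction, peak detection,
dispersion and Kramers–Kronig checks, peak matching, concentration series —
is exercised against those synthetic measurements.  This is an
estimator-recovery design: it demonstrates that the analysis chain recovers
the quantities that generated the data, not that the forward model reproduces
a particular instrument.

## The forward model

**Reference pulse.**  A first derivative of a Gaussian,
$E(t) \propto -(t-t_0)\,e^{-(t-t_0)^2/2\sigma^2}$, the simplest analytic
single-cycle waveform.  Defaults: 8192 samples at $\Delta t = 0.05$ ps
(Nyquist 10 THz), $t_0 = 10$ ps, width $2\sigma = 0.2$ ps.  The width was
chosen once so that the usable dynamic range spans the 0.2–2.6 THz band in
which all published sugar-alcohol lines fall, while leaving the grid above
5 THz essentially free of pulse energy — that spectral tail is where the
noise floor is estimated, so pulse leakage there would bias the validity
band.  Noise is additive white Gaussian on the time-domain trace with
standard deviation $\max|E|/\mathrm{SNR}$ (default SNR 1000, default seed
42); every noise draw is seeded and the generator never touches the global
RNG state.

**Dielectric models.**  Solids are a real background $\varepsilon_\infty$
plus Lorentz oscillators,
$$\varepsilon(\nu) = \varepsilon_\infty + \sum_k
  \frac{S_k\,\nu_{0k}^2}{\nu_{0k}^2 - \nu^2 - i\gamma_k\nu},$$
with centres at the published line positions and $\gamma = 0.05$ THz.
Oscillator strengths are deliberately small ($S = 0.0018$; $0.0009$ for the
weak mannitol 1.23 THz feature) — they are *calibrated*, once, so that the
model index stays inside the published ranges (mannitol 1.40–1.45,
erythritol 1.30–1.40) over 0.5–2.6 THz while every line clears the default
detection threshold.  The background $\varepsilon_\infty$ places the
baseline index at the published values (1.42 / 1.35); for mannitol it is set
to 2.0320 so that the *extracted* index under the default noise level stays
inside 1.40–1.45 including the anomalous-dispersion swings around each line.

Solutions use a double-Debye water background
(frozen constants $\varepsilon_s = 78.36$, $\varepsilon_1 = 4.93$,
$\varepsilon_\infty = 2.50$, $\tau_1 = 8.24$ ps, $\tau_2 = 0.18$ ps — any
parameter set with water's qualitative THz behaviour would serve; these are
frozen in `inst/extdata/presets.yaml` for reproducibility), mixed linearly
by solute volume fraction $\phi$:
$$\varepsilon(\nu) = (1-\phi)\,\varepsilon_{\mathrm{Debye}}(\nu) +
  \phi\,\varepsilon_\infty^{\mathrm{solute}} + \textstyle\sum_k \phi\,
  S_k\,\nu_{0k}^2 / (\nu_{0k}^2 - \nu^2 - i\gamma_k\nu).$$
Concentration maps to volume fraction as $\phi = c/\rho_{\mathrm{solute}}$
with $\rho_{\mathrm{solute}}$ fixed at 1.5 g/mL — the published description
gives only the concentration range (0–1 g/mL, five values), so the mapping
is a package convention.  Solution lines are broader ($\gamma = 0.15$ THz),
reflecting the dynamic liquid environment, and their strengths
($S = 0.09$ per unit volume fraction) are set large enough that the solute
lines remain prominent on top of the water background at 1 g/mL.

**Transmission.**  Single pass only:
$$T(\omega) = \frac{4\tilde n}{(\tilde n + 1)^2}
  \exp\!\big(i(\tilde n - 1)\omega d/c\big),$$
applied in the spectral domain (conjugated into the package's
$e^{-j\omega t}$ FFT convention so the pulse is delayed and attenuated).
There are no Fabry–Pérot echo terms: the closed-form extraction applies a
single Fresnel correction, and the forward model is kept as its exact
inverse.  For the liquid cell the reference is defined as measured through
the matched cell, so the windows cancel and only the 50 µm liquid layer
enters $T$.

## The extraction chain

1. **FFT** of both traces with the $e^{-j\omega t}$ sign convention,
   rectangular window, zero-padding ×4 (a Hann window is available for
   noisy inputs but biases peak amplitudes and is off by default — the
   single-pass model has no echoes to suppress).
2. **Phase difference.**  The principal-value argument difference is
   unwrapped along increasing frequency.  In the $e^{-j\omega t}$
   convention a delay appears with negative argument, so the unwrapped
   difference is negated to make the phase delay of an optically dense
   sample positive.  The remaining $2\pi k$ ambiguity is anchored by
   fitting a line over 0.2–0.4 THz (standard THz-TDS practice) and removing
   the multiple of $2\pi$ nearest its DC intercept, since the true phase
   delay extrapolates to zero at DC.
3. **Index**: $n(\omega) = 1 + c\,\varphi(\omega)/(\omega d)$, the
   dimensionally consistent reading of the slab phase delay.  No clamping.
4. **Absorption**: $\alpha(\omega) = -(2/d)\ln\!\big[\rho\,(n+1)^2/(4n)\big]$
   with $\rho$ the field-amplitude ratio and $d$ in cm, i.e. $\alpha$ is the
   *power* absorption coefficient in cm⁻¹ (the field ratio carries
   $e^{-\alpha d/2}$).
5. **Validity band**: the widest contiguous interval where the reference
   magnitude exceeds the noise floor (median magnitude above 5 THz) by a
   dynamic-range margin.

### Why the margin depends on the geometry

The band-edge points sit, by construction, at amplitude SNR
$10^{f_{\mathrm{dB}}/20}$.  Noise propagates very differently into the two
optical constants:

* phase noise enters $n$ multiplied by $c/(2\pi\nu d)$ — harmless for a
  millimetre tablet at 1 THz, but divergent toward the low-frequency edge;
* amplitude noise enters $\alpha$ multiplied by $2/d$ — a factor 400 cm⁻¹
  per unit fractional noise for a 50 µm layer.

With the generic 20 dB default the edge regions are therefore dominated by
noise, as they are in real THz-TDS practice.  The presets consequently carry
stricter recommended margins: **30 dB for tablets** and **40 dB for liquid
cells**.  At the default study conditions this places the tablet band at
roughly 0.56–3.0 THz and the differential solution band at roughly
0.30–2.95 THz, both of which contain every published line with margin.
`valid_band()` itself keeps the permissive 20 dB default; the margins are
pipeline settings, recorded in each output's metadata.

The same noise propagation sets the accuracy profile of the inversion:
$\delta n(\nu) \approx \sqrt{2}\,\sigma_F/|F(\nu)| \cdot c/(2\pi\nu d)$.
At SNR $10^4$ the index is recovered to better than $10^{-3}$ above
~0.6 THz, while the absolute noise floor on $\alpha$ (~0.15 cm⁻¹ at these
settings) makes *relative* statements about $\alpha$ meaningful only above
~10 cm⁻¹.  The test-suite asserts exactly those calibrated bounds, and the
near-noise-free check (SNR $10^8$) shows the chain is the mathematical
inverse of the forward model up to a ~6×10⁻⁵ systematic from evaluating the
transmission on the padded spectral grid.

## Peak detection and the physical consistency checks

Candidate lines are strict local maxima of the (optionally Savitzky–Golay
smoothed) absorption spectrum.  Prominence is then measured on a
baseline-corrected curve: for solution spectra a rolling-minimum baseline
(0.4 THz window) removes the broadband water-differential background that
would otherwise swamp the relative prominence threshold (5 % of the in-band
maximum by default — chosen so that all published lines, including the weak
mannitol 1.23 THz feature, survive at default settings).  Three details
matter in practice:

* candidates come from the *raw* curve, not the baseline-corrected one — a
  monotone background (pure water) has inflection points that the
  rolling-minimum correction would otherwise turn into spurious maxima;
* no peaks are reported within half a baseline window of the band edges,
  where the rolling minimum is undefined;
* light smoothing (0.02 THz for tablets, 0.05 THz for solutions) suppresses
  single-bin noise spikes near the band edges while leaving lines — two
  orders of magnitude wider than a grid step — essentially untouched.

Centres are refined by parabolic interpolation through the three samples
around each maximum.  On the solution background the sloping baseline biases
centres by roughly $m\gamma^2/8h \approx 0.01$ THz downward, which is inside
the 0.03 THz agreement quoted for the solution lines.

Two causality checks tie the two spectra together.  At every detected line
the least-squares slope of $n(\nu)$ over ±fwhm/2 must be negative
(anomalous dispersion).  And the full index spectrum is reconstructed from
$\alpha$ alone via the subtractive Kramers–Kronig relation,
$$n_{KK}(\nu) = n_\infty + \frac{c}{2\pi^2}\,
  \mathcal{P}\!\!\int \frac{\alpha(\nu')}{\nu'^2-\nu^2}\,d\nu',$$
evaluated with the Maclaurin alternating-point quadrature (each output point
uses only input points of opposite grid parity, which skips the singular
node exactly; on an analytic Lorentz line the quadrature is accurate to
~10⁻⁶).  The integral is truncated to the validity band; with all
resonances well inside the band the truncation bias is absorbed almost
entirely into the $n_\infty$ anchor (taken from the extracted index at the
upper band edge), and the solid presets agree to better than 0.02 over the
central half-band.

## Peak matching

Lists are paired by centre distance.  One-to-one mode sorts candidate pairs
by $|\Delta\nu|$ and accepts greedily; a brute-force enumeration oracle in
the test-suite confirms that greedy pairing is optimal whenever inter-peak
spacing exceeds twice the tolerance, which covers the peak densities that
occur here.  Many-to-one mode maps every A peak to its nearest B peak within
tolerance — the mode needed when two close experimental lines appear merged
into a single computed mode (the mannitol 1.96/2.17 → 2.03 THz case).
Default tolerances are 0.10 THz (one-to-one) and 0.15 THz (many-to-one):
the smallest round values that reproduce every published correspondence,
including a 0.11 THz experiment-vs-computation offset and a 0.14 THz
solid-vs-solution offset.  They are defaults, not claims about the original
authors' intent, and are overridable everywhere.

## Concentration series

Raw solution traces are simulated against the *empty* cell so that absolute
signal strength is meaningful; strength is the time-domain peak-to-peak
amplitude (a frequency-domain integral is available behind
`spectral_strength()`).  Because the solute displaces strongly absorbing
water, transmitted amplitude rises strictly with concentration in the
noise-free limit, and at the study conditions (five concentrations
0.2–1.0 g/mL, SNR 1000) the per-step amplitude change (~10 %) dwarfs the
noise, so the measured series is strictly monotone with Spearman ρ = 1.
The series stage deliberately reports raw signal metrics rather than
per-concentration absorption coefficients: with water dominating the
in-band absorption, comparing α across concentrations would mostly compare
water content.

Two conventions were genuinely open and are package decisions, flagged in
output metadata: the *solution reference* is the water-filled cell for
optical-constant extraction (differential measurement — windows and the
bulk water background cancel exactly) but the empty cell for raw
concentration-series traces (absolute signal growth is the observable); and
the mannitol solid spectrum ships in both a six-line and a five-line
reading (`mannitol_solid` and `mannitol_solid_fig3`) because the published
account counts it both ways — the package does not adjudicate.

## What the synthetic data does and does not emulate

The generator reproduces: band-limited single-cycle pulses, realistic
dynamic range, Fresnel interface loss, causal Lorentz/Debye dispersion,
seeded white detector noise, and the geometry of both measurement modes.
It does **not** emulate: water-vapour rotational lines (measurements at
19.8 % relative humidity would show them; extracted spectra from real data
will carry narrow residual lines the presets lack), Fabry–Pérot echoes and
their windowing, frequency-dependent COC window dispersion, delay-stage
jitter or drift, temperature effects, or 1/f detector noise.  Passing tests
therefore demonstrate the correctness and calibration of the *analysis
chain* under controlled conditions, not instrument-level fidelity.

## Problem sizes and runtime

All shipped tests and the acceptance script run on single traces of 8192
samples (≈ 410 ps at 0.05 ps steps; padded FFT length 32768), the size at
which the spectral grid (0.6 GHz) comfortably resolves the narrowest solid
lines (γ = 0.05 THz ≈ 80 grid steps).  A full simulate–extract–detect pass
takes well under a second; the Kramers–Kronig quadrature on the ~4000-point
band is the most expensive step at roughly 0.1 s.
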