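# teraspec

Terahertz time-domain spectroscopy (THz-TDS) simulation and optical-constant
extraction for small-molecule solids and aqueous solutions, built around the
two sugar alcohols mannitol and erythritol.

THz-TDS records the electric field of a picosecond single-cycle pulse
coherently — once through a reference path, once through the specimen — so
both amplitude and phase are available and the complex optical constants
follow in closed form.  With the Fourier transform
`F(jω) = ∫ f(t) e^(−jωt) dt` of both traces, the refractive index comes from
the unwrapped spectral phase difference φ(ω),

    n(ω) = 1 + c φ(ω) / (ω d),

and the power absorption coefficient from the amplitude ratio after the
two-interface Fresnel correction,

    α(ω) = −(2/d) ln[ |E_s(ω)|/|E_ref(ω)| · (n+1)² / (4n) ],

with d the sample thickness (α in cm⁻¹).  The package implements this chain
for pressed tablets (1.11 / 1.15 mm) and for a 50 µm microfluidic liquid
cell that makes solution measurements possible despite water's strong THz
absorption, and surrounds it with:

* a **seeded synthetic measurement generator** (`forward` stage) —
  derivative-of-Gaussian reference pulses, Lorentz-oscillator solids,
  double-Debye water mixed with solute lines by volume fraction, single-pass
  Fresnel transmission — so the whole chain is testable without instrument
  data;
* **peak detection** with relative prominence, rolling-minimum baselining
  for solution spectra, and parabolic centre refinement, plus two causality
  checks: anomalous dispersion at every line and a Kramers–Kronig
  reconstruction of n(ν) from α(ν);
* **tolerance-based peak matching** (one-to-one and many-to-one, including
  the merged-line case) and publication-style correspondence tables;
* **concentration-series analysis** quantifying how transmitted signal
  strength grows with solute concentration in the liquid cell.

Who it is for: spectroscopists who want a reference implementation of the
closed-form THz-TDS extraction with honest validity-band and noise handling,
and method developers who need a controlled, fully seeded synthetic test bed
for peak-level analysis chains.

## Worked example

Simulate a mannitol tablet measurement (SNR 1000, seed 42), extract the
optical constants, detect and check the absorption lines:

```r
library(teraspec)

m  <- simulate_tablet("mannitol_solid", snr = 1000, seed = 42)
oc <- extract_optical_constants(m$sample, m$reference, m$d_mm,
                                options = m$preset$extraction)
oc
#> <optical_constants> band 0.559 - 3 THz; n in [1.404, 1.443], max alpha 34.06 cm^-1 (in band)

peaks <- detect_peaks(oc, smooth_thz = 0.02)
peaks
#> <peak_set> 6 peak(s), source = extracted [detected (baseline=none, smooth=0.02 THz)]
#>  center_thz height_cm1 prominence_cm1 fwhm_thz
#>      0.9392      4.865          4.912  0.04791
#>      1.2283      4.076          4.101  0.05405
#>      1.7303     16.405         14.723  0.04455
#>      1.9606     21.053         18.449  0.04401
#>      2.1703     25.775         23.648  0.04733
#>      2.4297     31.886         32.083  0.05129
```

The six detected centres sit on the published mannitol lines (0.94, 1.23,
1.73, 1.96, 2.17, 2.43 THz) to within a few GHz, and the extracted index
stays inside the published 1.40–1.45 range across the whole validity band.
The physical consistency checks pass at every line:

```r
anomalous_dispersion_flags(oc, peaks)   # n decreasing across each line
#> [1] TRUE TRUE TRUE TRUE TRUE TRUE

nkk <- kk_refractive_index(oc)          # n rebuilt from alpha alone
mean(abs(nkk - oc$n), na.rm = TRUE)
#> [1] 0.0029

match_peaks(peaks, reference_peaks("mannitol_solid_experiment"),
            tolerance_thz = 0.10)
#> <peak_match> one_to_one, tol 0.1 THz: 6 pair(s), 0/0 unmatched A/B
```

A five-point concentration series in the liquid cell shows the
solute-displaces-water effect — transmitted signal strength rises strictly
with concentration:

```r
cs <- simulate_series("mannitol_solution", snr = 1000, seed = 42)
cs
#> <concentration_series> mannitol_solution, 5 concentrations
#>  conc_g_per_ml strength
#>            0.2  0.76580
#>            0.4  0.80753
#>            0.6  0.85242
#>            0.8  0.88417
#>            1.0  0.91156
strength_concentration_relation(cs)$spearman_rho
#> [1] 1
```

`run_pipeline(tds_config("erythritol_solid"), mode = "solid", out_dir = "run")`
executes the whole chain and writes ASCII traces, an optical-constants CSV
with JSON sidecar, and peaks/match JSON, each stamped with the configuration
fingerprint.  A thin command-line front end with the same stages lives in
`inst/cli/teraspec`.

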