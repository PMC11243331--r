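# Preset catalogue: dielectric models and geometries used by the synthetic
# measurement generator, plus recommended extraction/detection settings per
# geometry.  Frequencies in THz, thicknesses in mm, relaxation times in ps.
#
# Solid presets: baseline index n_inf = sqrt(eps_inf) equals the centre of
# the published refractive-index range (mannitol 1.42, erythritol 1.35);
# oscillator strengths are calibrated so the model index stays inside the
# published range over 0.5-2.6 THz while every absorption line remains
# detectable at the default prominence threshold.
#
# Solution presets: oscillator strengths are quoted per unit solute volume
# fraction; the builder multiplies them by phi = concentration / rho_solute.

rho_solute_g_ml: 1.5

water:
  eps_static: 78.36
  eps_intermediate: 4.93
  eps_inf_w: 2.50
  tau1_ps: 8.24
  tau2_ps: 0.18

extraction_defaults:
  tablet:
    window: none
    pad_factor: 4
    anchor_band_thz: [0.2, 0.4]
    floor_db: 30
    baseline: none
    smooth_thz: 0.02
    min_prominence_frac: 0.05
  liquid_cell:
    window: none
    pad_factor: 4
    anchor_band_thz: [0.2, 0.4]
    floor_db: 40
    baseline: rolling_min
    baseline_window_thz: 0.4
    smooth_thz: 0.05
    min_prominence_frac: 0.05

presets:
  mannitol_solid:
    kind: tablet
    d_mm: 1.11
    eps_inf: 2.0320
    gamma_thz: 0.05
    centers_thz:  [0.94,   1.23,   1.73,   1.96,   2.17,   2.43]
    strengths:    [0.0018, 0.0009, 0.0018, 0.0018, 0.0018, 0.0018]
  # five-line variant of the solid spectrum (without the weak 1.23 THz line)
  mannitol_solid_fig3:
    kind: tablet
    d_mm: 1.11
    eps_inf: 2.0320
    gamma_thz: 0.05
    centers_thz:  [0.94,   1.73,   1.96,   2.17,   2.43]
    strengths:    [0.0018, 0.0018, 0.0018, 0.0018, 0.0018]
  erythritol_solid:
    kind: tablet
    d_mm: 1.15
    eps_inf: 1.8225
    gamma_thz: 0.05
    centers_thz:  [1.81,   1.96,   2.02,   2.43]
    strengths:    [0.0018, 0.0018, 0.0018, 0.0018]
  mannitol_solution:
    kind: liquid_cell
    d_mm: 0.050
    eps_inf: 2.0164
    gamma_thz: 0.15
    centers_thz:  [0.98, 1.46, 1.84, 1.96, 2.13, 2.25, 2.43]
    strengths:    [0.09, 0.09, 0.09, 0.09, 0.09, 0.09, 0.09]
  erythritol_solution:
    kind: liquid_cell
    d_mm: 0.050
    eps_inf: 1.8225
    gamma_thz: 0.15
    centers_thz:  [1.51, 1.73, 1.82, 1.96, 2.16, 2.5]
    strengths:    [0.09, 0.09, 0.09, 0.09, 0.09, 0.09]
  water:
    kind: liquid_cell
    d_mm: 0.050
    eps_inf: 1.0
    centers_thz: []
    strengths: []
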