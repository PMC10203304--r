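# Synthetic stratified-granule scenario: net oxygen production in the outer
# 500 um, an inert middle band, and a weakly respiring core. Rates are
# zero-order volumetric rates in umol L-1 s-1 (positive = production).
radius_um: 1800
bulk_umol_per_L: 250
analyte: oxygen
noise_sd_umol_per_L: 2
seed: 20260928
layers:
  - r_inner_um: 1300
    r_outer_um: 1800
    rate_umol_per_L_s: 0.4
  - r_inner_um: 600
    r_outer_um: 1300
    rate_umol_per_L_s: 0.0
  - r_inner_um: 0
    r_outer_um: 600
    rate_umol_per_L_s: -0.1
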