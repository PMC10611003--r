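# Two sets of epoxy-resin phantoms (TiO2 scatterers, Nigrosin absorber) at
# 633 nm. Uncertainties are standard deviations of three measurements at
# different sample positions. The anisotropy factor g of the TiO2 particles
# is not part of the characterization; 0.6 is the package default and must
# be treated as an explicit modeling parameter.
set_name: table1
defaults:
  g: 0.6
  n_slab: 1.552
  n_ambient: 1.0
phantoms:
  - id: "1.1"
    d_mm: 0.395
    d_sd_mm: 0.009
    mus_prime_per_mm: 3.688
    mus_prime_sd_per_mm: 0.005
    mua_per_mm: 0.0034
    mua_sd_per_mm: 0.0003
  - id: "1.2"
    d_mm: 0.947
    d_sd_mm: 0.004
    mus_prime_per_mm: 3.781
    mus_prime_sd_per_mm: 0.002
    mua_per_mm: 0.0020
    mua_sd_per_mm: 0.0001
  - id: "1.3"
    d_mm: 1.514
    d_sd_mm: 0.009
    mus_prime_per_mm: 3.841
    mus_prime_sd_per_mm: 0.004
    mua_per_mm: 0.0020
    mua_sd_per_mm: 0.0001
  - id: "1.4"
    d_mm: 1.987
    d_sd_mm: 0.003
    mus_prime_per_mm: 3.817
    mus_prime_sd_per_mm: 0.005
    mua_per_mm: 0.0019
    mua_sd_per_mm: 0.0001
  - id: "2.1"
    d_mm: 0.901
    d_sd_mm: 0.008
    mus_prime_per_mm: 2.724
    mus_prime_sd_per_mm: 0.003
    mua_per_mm: 0.0213
    mua_sd_per_mm: 0.0001
  - id: "2.2"
    d_mm: 1.045
    d_sd_mm: 0.003
    mus_prime_per_mm: 2.757
    mus_prime_sd_per_mm: 0.001
    mua_per_mm: 0.0598
    mua_sd_per_mm: 0.0001
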