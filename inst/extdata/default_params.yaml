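# Default physiological constants for the six phytoplankton functional types
# and the shared community (grazing / recycling) parameters.
#
# Units:
#   mu_max   : 1/day        maximum growth rate at the 20 C reference temperature
#   k_no3    : umol/kg      half-saturation for nitrogen (NO3 + NH4)
#   k_fe     : nmol/kg      half-saturation for dissolved iron
#   k_si     : umol/kg      half-saturation for silicate (diatoms only)
#   k_e      : mol photons m-2 d-1   half-saturation irradiance for growth
#   w0       : m/day        reference sinking speed (at 31 C)
#   r_n_chl  : umol/kg N consumed per (mg Chl m-3) produced (includes the
#              seawater volume-to-mass conversion for a mixed-layer box)
#   r_si_chl : umol/kg Si per (mg Chl m-3), diatoms only
#   r_fe_chl : nmol/kg Fe per (mg Chl m-3)
#
# Values are declared model defaults chosen to respect the documented order
# relations among groups: diatoms have the largest mu_max and the largest
# nutrient half-saturations; dinoflagellates grow at 90% of the diatom rate
# and share the diatom nitrogen and iron half-saturations but need no
# silicate; coccolithophores have a low light half-saturation and low
# nutrient half-saturations; cyanobacteria have the slowest growth and the
# highest nutrient affinity (smallest k); diatoms carry the largest iron
# demand per unit chlorophyll (large, heavily silicified cells).
pfts:
  diatoms:
    mu_max: 1.50
    k_no3: 1.00
    k_fe: 0.50
    k_si: 0.90
    k_e: 3.0
    w0: 0.75
    r_n_chl: 0.80
    r_si_chl: 0.80
    r_fe_chl: 0.05
  coccolithophores:
    mu_max: 1.30
    k_no3: 0.85
    k_fe: 0.44
    k_e: 2.5
    w0: 0.50
    r_n_chl: 0.80
    r_fe_chl: 0.02
  chlorophytes:
    mu_max: 1.38
    k_no3: 0.92
    k_fe: 0.46
    k_e: 3.6
    w0: 0.25
    r_n_chl: 0.80
    r_fe_chl: 0.02
  dinoflagellates:
    mu_max: 1.35
    k_no3: 1.00
    k_fe: 0.50
    k_e: 2.8
    w0: 0.15
    r_n_chl: 0.80
    r_fe_chl: 0.02
  cyanobacteria:
    mu_max: 1.22
    k_no3: 0.80
    k_fe: 0.40
    k_e: 5.0
    w0: 0.02
    r_n_chl: 0.80
    r_fe_chl: 0.02
  phaeocystis:
    mu_max: 1.40
    k_no3: 0.95
    k_fe: 0.48
    k_e: 4.2
    w0: 0.35
    r_n_chl: 0.80
    r_fe_chl: 0.02
community:
  gamma_m: 0.35        # 1/day, maximum grazing rate at 20 C
  ivlev_lambda: 1.0    # (mg Chl m-3)^-1, Ivlev saturation constant
  recycle_frac: 0.75   # share of grazed N / Fe returned to NH4 / Fe pools
  background_fractions:  # used only to reseed a zero-biomass state
    diatoms: 0.1666666666666667
    coccolithophores: 0.1666666666666667
    chlorophytes: 0.1666666666666667
    dinoflagellates: 0.1666666666666667
    cyanobacteria: 0.1666666666666666
    phaeocystis: 0.1666666666666667
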