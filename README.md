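# pftbox

Six-group phytoplankton competition in a seasonally forced mixed-layer
box, with sequential chlorophyll assimilation and the anomaly machinery
used to diagnose marine-heatwave impacts on community composition.

## The problem

Pacific marine heatwaves ("the Blob" in the Gulf of Alaska, the 2015–2016
El Niño in the equatorial Pacific) warm the surface ocean and weaken the
wind-driven supply of nutrients to the mixed layer. Bulk chlorophyll
responds, but the ecologically decisive changes are in *community
composition*: which phytoplankton functional type (PFT) dominates the
biomass. `pftbox` is for modellers and students of ocean biogeochemistry
who want a transparent, fully testable desk-scale implementation of that
mechanism chain: physical forcing → nutrient supply → multi-nutrient
competition → community shift → anomaly diagnostics.

## The model

Total chlorophyll is the sum over six PFTs (diatoms, coccolithophores,
chlorophytes, dinoflagellates, cyanobacteria, phaeocystis). Each group
grows at

    mu_i = mu_max_i * min[ f(Nut_i), f(E_i) ] * R(T),      R(T) = 1.066^(T-20)

with Liebig-minimum Monod limitation over nitrogen (NO3 + NH4), iron and
(diatoms only) silicate, f(X) = X / (k_X + X), and a Monod light term in
the Beer–Lambert mean mixed-layer PAR, with attenuation derived from
chlorophyll via Kd490 = 0.0166 + 0.0773 Chl^0.6715 and
KdPAR = 0.0864 + 0.884 Kd490 − 0.00137/Kd490. Losses are
temperature-dependent Stokes sinking, w_i = w0_i (0.451 + 0.0178 T), and
Ivlev grazing gamma = gamma_m (0.06 e^{0.1T} + 0.7)(1 − e^{−Λ ΣP}),
applied as a uniform specific rate so grazing never alters composition.
Nutrient pools relax toward deep reservoirs at an exchange rate and are
drawn down by uptake through fixed nutrient-to-chlorophyll ratios, with
partial recycling of grazed N and Fe to ammonium and iron.

On top of the forward model the package provides: a synthetic
seasonal-forcing generator with "blob"/"elnino" heatwave scenarios, noisy
gappy satellite-like chlorophyll observations, composition-preserving
sequential assimilation, deseasonalized monthly anomalies and
nutrient-limitation-term anomalies, wind-stress-curl Ekman vertical
velocity, dominance classification, and median percent-error skill
metrics. See the vignette (`vignettes/heatwave-pft-dynamics.Rmd`) for the
full formulation and design rationale.

## Worked example

Halve the silicate supply to a subarctic (Gulf-of-Alaska-like) mixed
layer for eight months and compare against the paired baseline run:

```r
library(pftbox)
blob <- scenario_spec("blob", onset = as.Date("2003-05-01"),
                      duration_months = 8, supply_factor_si = 0.5,
                      ramp_months = 1)
run_experiment(blob, "subarctic", seed = 1)
```

```
Heatwave experiment: blob scenario, subarctic profile
Event window: 2003-05-01 to 2003-12-31
(anomalies referenced to the paired baseline run's climatology)
In-window mean chlorophyll anomaly: +0.1%
In-window mean iron anomaly: +0.00863 nmol/kg
Biomass-fraction change (percentage points):
         diatoms coccolithophores     chlorophytes  dinoflagellates
           -7.07             7.04             0.00             0.03
   cyanobacteria      phaeocystis
            0.00             0.00
Diatom binding-nutrient frequency in window:
  N  Fe  Si
554 327  96
```

Diatoms lose ~7 percentage points of the biomass share while
dinoflagellates — which need no silicate but otherwise match diatom
physiology — gain, and the iron anomaly is positive because the heaviest
iron consumers are silicate-starved. The equatorial El Niño counterpart
(`supply_factor_no3 = 0.2`, `sst_amplitude = 4`) yields an in-window
chlorophyll anomaly near −50% with diatoms the strongest fractional
losers:

```
In-window mean chlorophyll anomaly: -49.4%
Biomass-fraction change (percentage points):
         diatoms coccolithophores     chlorophytes  dinoflagellates
           -5.44             0.03             5.39             0.00
```

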