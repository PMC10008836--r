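Package: pftbox
Title: Six-Group Phytoplankton Mixed-Layer Box Model with Chlorophyll
    Assimilation and Marine-Heatwave Scenario Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A mixed-layer box model of competition among six phytoplankton
    functional types (diatoms, coccolithophores, chlorophytes,
    dinoflagellates, cyanobacteria, phaeocystis) driven by temperature,
    nutrients (nitrate + ammonium, silicate, iron) and light, with Monod
    uptake limitation, Liebig minimum growth, temperature-dependent Stokes
    sinking and Ivlev grazing. Includes a synthetic seasonal-forcing
    generator with "Blob" and "El Nino" heatwave scenarios, sequential
    nudging assimilation of (synthetic) satellite chlorophyll that preserves
    community composition and adjusts nutrients by nutrient-to-chlorophyll
    ratios, deseasonalized anomaly and nutrient-limitation-term analysis,
    wind-stress-curl Ekman vertical velocity, dominance classification, and
    median-based percent-error skill metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
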