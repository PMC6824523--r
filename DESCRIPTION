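Package: pasam
Title: Passive Aerosol Sampler Microscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for badge-type passive aerosol samplers read out
    by scanning electron microscopy: maximum-Renyi-entropy thresholding and
    connected-component extraction of particles from SEM tile images,
    conversion of projected areas to volume-equivalent and aerodynamic
    diameters and masses through shape factors and Cunningham slip
    correction, deposition-velocity and mesh-cap efficiency models that
    invert deposited mass into PM2.5/PM10 air concentrations, field-blank
    correction and duration-weighted campaign averages, gravimetric impactor
    and optical-particle-counter reference computations, and a synthetic
    deposition generator that renders particle populations onto SEM-like
    tiles so the whole chain can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
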