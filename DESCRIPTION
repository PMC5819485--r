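Package: vegbiophys
Title: Potential Biophysical Effects of Vegetation Cover Change from
    Space-for-Time Compositional Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives maps of the potential local biophysical effects of
    vegetation cover change from co-registered cover-fraction and surface
    variable rasters using a space-for-time substitution. Within 5x5 moving
    windows, mixed-pixel surface variables (albedo, latent heat flux, land
    surface temperatures, clear-sky upwelling longwave) are unmixed by a
    centred singular-value-decomposition regression on the cover-fraction
    composition, yielding pure-class predictions with full covariance and
    per-transition differences with uncertainties. Unreliable windows are
    masked by a vegetation co-occurrence index and by topographic-relief
    indicators, estimates are aggregated to 1-degree cells with
    generalized-least-squares weights that account for window overlap, and
    the surface energy balance is closed to obtain the residual sensible
    plus ground heat flux. Includes a seeded synthetic-scene generator with
    known per-class ground truth, netCDF product encoding, and an
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ncdf4
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'schemes.R'
    'transitions.R'
    'synthetic.R'
    'preprocess.R'
    'unmix.R'
    'mask.R'
    'aggregate.R'
    'energy-balance.R'
    'dataset-io.R'
    'pipeline.R'
    'vegbiophys-package.R'
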