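# vegbiophys

Potential biophysical effects of vegetation cover change, estimated by
space-for-time compositional unmixing of satellite surface variables.

## What it does, and for whom

Changing vegetation cover (e.g. forest → cropland) alters albedo,
evapotranspiration and surface temperature, warming or cooling the local
climate independently of carbon emissions. Quantifying these effects
observationally requires comparing co-existing covers under the same
climate rather than watching a conversion happen. `vegbiophys` implements
that space-for-time substitution as a reusable R pipeline for researchers
in land–climate interactions who want the full method — unmixing, masking,
aggregation, energy-balance closure, product encoding — as tested,
composable functions, exercised end-to-end on synthetic scenes with known
ground truth.

The core model: within each 5×5 moving window of 0.05° pixels, monthly
surface variables *y* (albedo α, latent heat LE, day/night LST, clear-sky
upwelling longwave LW↑\*) are linear mixtures of unknown pure-class values
through the cover-fraction matrix **X** (rows sum to 1):

    y = Xβ + ε

Compositions are closed, so **X** is centred and reduced by SVD before an
ordinary least-squares fit; "dummy pixels" fully covered by one vegetated
class are then predicted with full covariance Σ = Zₚ Var[β] Zₚᵗ. A
transition A→B gets Δy = y_B − y_A and sd √(σ²_A + σ²_B − 2σ_AB). Windows
with < 10 distinct compositions are skipped; windows with poor class
co-occurrence (index I_c < 0.5) or strong relief (v₁ ≥ 50 m, v₂/v₃ ≥ 100 m)
are masked. Estimates are aggregated to 1° cells with generalized
least-squares weights built from the window-overlap matrix (up to 400×400),
filtered (≥ 20 samples, 3·IQR fence), and the surface energy balance is
closed per cell and month:

    Δ(H+G) = −(Δα)·SW↓ − (LW_C↑ / LW*_C↑)·ΔLW↑* − ΔLE

Products are netCDF files on dimensions (lat, lon, mon, iTr) holding
`Delta_Z`, `SD_Delta_Z` and `N_Z`, with transitions encoded as concatenated
class codes (iTr = 19: class 1 → class 9; 45 transitions for the detailed
10-class scheme, 6 for the generic 4-class scheme).

## Worked example

A 40×40-pixel synthetic scene (2×2 one-degree cells), two months, generic
4-class scheme, run end to end:

```r
library(vegbiophys)
cfg <- pipelineConfig(n_rows = 40, n_cols = 40, months = c(1L, 7L), seed = 1)
res <- runPipeline(cfg, out_dir = "products", quiet = TRUE)
res$products$albedo
#> BiophysicalDataset 'albedo' [IGBPgen]: 2 lat x 2 lon x 2 mon x 6 iTr
#>   non-missing Delta values: 45

i <- which(transitionCodes(res$products$albedo) == 13)  # FOR -> C+G
deltaLayer(res$products$albedo)[1, 1, 1, i]        # 0.0301
uncertaintyLayer(res$products$albedo)[1, 1, 1, i]  # 0.0060
sampleCount(res$products$albedo)[1, 1, 1, i]       # 61
deltaLayer(res$products$HG)[1, 1, 1, i]            # 14.54
```

Reading: converting forest to crops/grasses in that cell in January would
raise albedo by 0.030 ± 0.006 (61 fine-resolution estimates survived the
masks there), and the residual sensible-plus-ground heat flux would rise by
about 14.5 W m⁻². The scene's ground truth for that cell is an albedo
change of 0.022 — within 1.4 reported standard deviations. Eight product
files (`albedo_IGBPgen.nc` … `HG_IGBPgen.nc`) are written to `products/`;
the four derived flux changes satisfy
ΔSW↑ + ΔLW↑ + ΔLE + Δ(H+G) = 0 exactly on every complete cell.

A thin command-line front end is installed at
`system.file("scripts", "vegbiophys.R", package = "vegbiophys")` with
subcommands `simulate`, `run-all` and `validate`.

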