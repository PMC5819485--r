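---
title: "Space-for-time unmixing of vegetation biophysics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-for-time unmixing of vegetation biophysics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegbiophys)
```

## The problem

Converting one vegetation cover to another (say forest to cropland) changes
the biophysical properties of the land surface — albedo, evapotranspiration,
surface temperature, emitted radiation — and hence the local climate,
independently of any carbon-cycle effect. Direct observation of such effects
would require watching the same place before and after conversion under the
same climate. `vegbiophys` instead implements a *space-for-time
substitution*: within a small moving window, co-existing pixels with
different cover compositions are compared, and the difference a full
conversion would make is inferred by compositional unmixing.

The package provides the complete processing chain as reusable, tested
functions: unmixing, masking, uncertainty-aware aggregation,
energy-balance closure and product encoding, together with a seeded
synthetic-scene generator so every stage can be verified against known
ground truth without any external data.

## The local unmixing model

For each 5×5-pixel window (0.25°, about 25 km, over which the local climate
is assumed uniform), each calendar month and each surface variable $y$, the
observed pixel values are modelled as linear mixtures of unknown pure-class
values through the cover-fraction matrix $X$ (25 rows, one column per class,
rows summing to one):

$$ y = X\beta + \varepsilon. $$

Because compositions are *closed* (each row sums to one), $X$ is rank
deficient on the simplex and must not be regressed directly. The package
centres the columns by their means $M$, applies an SVD
$(X - M) = U D V^t$, and retains the numerically nonzero dimensions. The
reduced predictors $Z = (X - M)V_z$, augmented with an intercept column,
enter an ordinary least-squares fit $\hat\beta = (Z^tZ)^{-1}Z^ty$ with
coefficient covariance $s^2 (Z^tZ)^{-1}$, where $s^2$ is the unbiased
residual variance with $n - (r+1)$ degrees of freedom ($r$ retained
dimensions).

Pure-class values are predicted for "dummy pixels" fully covered by one
vegetated class: the dummy compositions are centred on the same $M$,
projected on the same $V_z$, and predicted, with full covariance
$\Sigma = Z_p\,\mathrm{Var}[\hat\beta]\,Z_p^t$. The transition effect for an
ordered class pair is $\Delta y_{A\to B} = y_B - y_A$ with standard
deviation $\sqrt{\sigma_A^2 + \sigma_B^2 - 2\sigma_{AB}}$ — the covariance
matters because both predictions come from the same regression. Only pairs
from a lower to a higher class code are emitted (45 for the detailed
10-class scheme, 6 for the generic 4-class scheme); the reverse transition
is the sign flip.

Non-vegetated classes (urban, water, snow/ice, bare soil — plus wetlands in
the generic scheme, which its crosswalk keeps as a separate column) enter
the regression as part of the composition but are never predicted.

### Numerical choices

* **"Conserve 100 % of the variation"** is implemented as retaining exactly
  the numerically nonzero singular values, $d_i > \texttt{rtol}\cdot d_1$
  with `rtol = 1e-8`: the purpose of the rule is rank reduction (removing
  locally redundant dimensions), not variance thresholding.
* **Distinct-composition gate.** A window is only fitted when it contains at
  least 10 distinct compositions; distinctness is judged after rounding
  fractions to 6 decimals, since fraction inputs carry limited precision.
  The gate is evaluated on all 25 rows, after the completeness check (the
  ordering is not specified by the method description; windows with any
  missing value are skipped regardless).
* **Degenerate fits** (singular $Z^tZ$ after retention) produce a
  window-skip signal, not an error, so a global map run never aborts.
* **Negative variances** from floating-point cancellation in the transition
  variance and on the diagonal of $\Sigma$ are clipped to zero.
* **Windows never shrink or wrap**: the two-pixel rim of the map carries no
  estimates, and a window is only used when all 25 pixels have data.

## Masking

Two pixel-level masks remove windows in which the regression is unreliable.

**Co-occurrence.** The index $I_c$ scores how well the presences of the two
classes of a pair span the compositional range: $n_q$ ideal points are
spread evenly on the segment $B = 1 - A$; for each, the distance to the
nearest observed presence pair is summed and normalised by the worst case
(all presences at the origin): $I_c = 1 - \sum d_{min} / \sum d_{max}$,
clipped to $[0,1]$. Windows with $I_c < 0.5$ are masked, per pair. The
number of ideal points is not prescribed by the method; the package default
is `n_q = 11` (finer spacing than the 25 available window pixels adds
nothing), exposed as a configuration knob. The index is computed on the raw
presences of the two classes, ignoring the other classes. Note that
$I_c = 0.5$ corresponds *by definition* to $\sum d_{min} = \tfrac12 \sum
d_{max}$; placing all presences at half the ideal distances along their
rays does **not** realise this for $n_q > 2$, because the nearest presence
to an ideal point is generally a neighbouring scaled point reached
perpendicularly — the test suite constructs exact half-distance
configurations instead.

**Topography.** Sub-window climate gradients from relief are screened with
three indicators computed from per-pixel elevation mean $\mu_h$ and
standard deviation $\sigma_h$ over the same 5×5 window: $v_1$ the window
mean of $\sigma_h$; $v_2$ the absolute difference between the centre
pixel's $\mu_h$ and the window mean; $v_3$ the absolute difference between
the centre's $\sigma_h$ and $v_1$. A pixel is kept only under the strict
bounds $v_1 < 50$ m, $v_2 < 100$ m, $v_3 < 100$ m.

## Aggregation

Fine estimates are aggregated to aligned 20×20-pixel blocks (0.05° → 1°; no
partial cells). Neighbouring estimates are correlated because their windows
share up to 20 of 25 pixels, so plain inverse-variance weighting would be
overconfident. The package builds, from the surviving members of each cell,
the overlap matrix $R_a$ (up to 400×400) and the covariance
$\Sigma_a = D_a R_a D_a^t$ with $D_a$ the diagonal of member standard
deviations, and uses the best linear unbiased weights
$w = \Sigma_a^{-1}\mathbf 1 / (\mathbf 1^t\Sigma_a^{-1}\mathbf 1)$, with
aggregated variance $1/(\mathbf 1^t\Sigma_a^{-1}\mathbf 1)$ (the printed
form of the weight equation in the method description is typographically
garbled; this is the standard GLS solution consistent with its stated
variance). With $R_a = I$ this reduces exactly to inverse-variance
weighting.

Numerical choices: member standard deviations are floored at `1e-9` (zero
residual variance occurs in noiseless scenes); a numerically singular
$\Sigma_a$ receives one ridge of $10^{-10}\,\mathrm{tr}(\Sigma_a)/n$ and is
otherwise dropped; both algebraic forms of the aggregated variance are
computed and checked to agree to 1e-8 relative.

A caution on intuition: with *equal* member uncertainties, window overlap
can only inflate the aggregated uncertainty relative to independent
estimates, and the tests assert this. With heterogeneous uncertainties the
inequality can genuinely reverse — GLS may exploit the correlation between
a precise and an imprecise member to cancel shared noise — so no such
ordering is asserted in general.

After aggregation, cells backed by fewer than 20 fine samples are removed
(inclusive bound: 20 survives), then, per transition, values outside
$[Q_1 - 3\,\mathrm{IQR},\ Q_3 + 3\,\mathrm{IQR}]$ of the pooled
all-cells/all-months distribution are removed. The outlier rule is not
prescribed beyond "statistical outliers of the entire dataset"; a 3·IQR
fence was chosen as robust and parameter-light, applied in the printed
order (sample floor first), with removal counts logged.

## Energy-balance closure

Unmixing applies only to the variables available at 0.05° (albedo $\alpha$,
latent heat $LE$, clear-sky upwelling longwave $LW_\uparrow^*$, day/night
LST). The remaining terms of the perturbed surface energy balance
$\Delta SW_\downarrow - \Delta SW_\uparrow + \Delta LW_\downarrow -
\Delta LW_\uparrow = \Delta H + \Delta LE + \Delta G$ are closed per 1°
cell and month under $\Delta SW_\downarrow = \Delta LW_\downarrow = 0$
(pixel-scale conversions are assumed too small to alter the cloud regime):

* $\Delta SW_\uparrow = \Delta\alpha \times SW_\downarrow$;
* $\Delta LW_\uparrow = (LW_{C\uparrow}/LW^*_{C\uparrow})\,\Delta
  LW^*_\uparrow$ — the clear-sky estimate scaled by the all-sky/clear-sky
  ratio of the coarse radiation climatology as a cloudiness proxy (the
  ratio is read as a scalar climatological field, not a ratio of changes);
* $\Delta(H{+}G) = -\Delta SW_\uparrow - \Delta LW_\uparrow - \Delta LE$.

These definitions make the four flux changes sum to zero identically, which
the tests assert to machine precision. The uncertainty of the residual is
propagated in quadrature treating the three aggregated inputs as
independent — each variable is regressed separately, so no cross-variable
covariances exist upstream; whether the released real-data product used the
same propagation for its residual layer is unknown, so this operation is an
interpretation.

## The synthetic scenes

The generator emulates every input the chain consumes, with known truth:

* **Fractions**: one smooth latent Gaussian field per class (separable
  Gaussian filtering of white noise, length scale `smoothness_scale`
  pixels, default 2), mapped to the simplex by a softmax with gain
  `contrast` (default 2.5). This guarantees exact closure and spatial
  coherence without claiming any land-cover realism, and the default gain
  produces the well-spread window compositions the regression needs.
  Deterministic checkerboard and edge-gradient fixtures exercise the
  co-occurrence extremes and window-edge behaviour.
* **Ground truth**: per class, pixel and month, a base level plus an evenly
  spaced class offset, a class-phased annual sinusoid, and an optional
  smooth spatial component (`truth_spatial_sd`). Per-variable presets give
  realistic levels (albedo ≈ 0.16, LE ≈ 80 W m⁻², LST ≈ 285–300 K).
* **Surface variables**: exact mixtures of truth through the fractions plus
  Gaussian observation noise; the configuration's `noise_sd` is quoted on
  the albedo scale (default 0.01) and scaled by each variable's dynamic
  range (×400 for LE, ×40 for the LSTs).
* **DEM**: a smooth mean-elevation field of chosen amplitude, with
  $\sigma_h$ proportional to the local slope magnitude; amplitude 0 gives
  perfectly flat terrain.
* **Coarse radiation**: constant (or smoothly modulated) 1° fields of
  $SW_\downarrow$ (default 200 W m⁻², a typical annual mean) and of the
  all-sky/clear-sky longwave pair (default clear-sky 400 W m⁻², ratio 0.9).

Everything is deterministic given the configuration seed.

**What passing tests do and do not show.** The recovery tests use
`truth_spatial_sd = 0`: spatially uniform pure values make the
uniform-local-climate assumption hold *exactly*, which is the only regime
in which noiseless unmixing can be exact (with spatially varying truth the
mixture is no longer linear in the fractions). Real scenes violate the
assumption smoothly; the generator can emulate that (the default for
general scenes is a spatial component at 10 % of the class spread), but no
sub-1e-8 recovery is then expected or asserted. Similarly, clear-sky
upwelling longwave computed from mixed LSTs via $\varepsilon_B\sigma T^4$
is nonlinear in the fractions, so exact recovery applies to albedo, LE and
the LSTs but not to it — true of the real product as well. Synthetic scenes
also have none of the spatially structured retrieval errors, missing-data
patterns or class-fraction biases of real satellite products, so the tests
demonstrate correctness of the algorithms, not skill on real data.

## Test problem sizes

The suite verifies noiseless recovery on a 60×60-pixel, 12-month scene with
the generic scheme (about 37 600 fitted windows; maximum absolute error
against truth below 1e-8), calibrates uncertainties over 600 noisy
refits of a fixed window (sampling SD of the transition estimate within
10 % of the mean reported SD) and 12 000 Monte-Carlo redraws (prediction
covariance within 5 % in Frobenius norm), and runs the full pipeline to
products on 40×40 scenes. These sizes were chosen to exercise every code
path at comfortable statistical resolution while keeping the default test
run fast.

## Known limitations

* The pipeline operates on synthetic or pre-prepared rasters; reading
  native satellite archives (HDF tiles, 300 m class maps, DEM tiles) is out
  of scope, as is any real-data validation such as paired flux-tower
  comparison.
* Regression is ordinary least squares; no robust or weighted variants.
* Aggregation ignores covariance across coarse-cell boundaries.
* The co-occurrence ideal-point count, the SVD tolerance and the outlier
  fence are interpretations where the method description is silent; all
  three are configuration knobs and are echoed into product metadata.
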