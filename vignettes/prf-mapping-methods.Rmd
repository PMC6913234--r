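---
title: "Methods: Gaussian pRF mapping, noise ceilings, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian pRF mapping, noise ceilings, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfmap)
```

## The model

A population receptive field (pRF) is modelled as an isotropic 2D
Gaussian in visual-field coordinates (x rightward, y upward, origin at
fixation, units degrees of visual angle):

$$ g(x, y) = \exp\!\left(-\frac{(x - x_0)^2 + (y - y_0)^2}{2\sigma^2}\right). $$

For a binary stimulus aperture movie $M_t$ (one mask per second), the
modelled neural response is the per-frame overlap
$n_t = \sum_{\text{pixels}} M_t \, g$, which is convolved with a causal
double-gamma haemodynamic response function (HRF) and z-standardised to
give the predicted BOLD series. Two assumptions are baked in and worth
stating:

- **Linear spatial summation.** The response is the plain mask-profile
  inner product; no compressive exponent, surround suppression, or
  elliptical shape. This is the standard first-order pRF model.
- **Fixed canonical HRF.** A double-gamma with peak delay 6 s,
  undershoot delay 16 s, unit dispersions, undershoot ratio 1/6, 32 s
  support (`hrf_spec()`), sampled at the TR and scaled to peak 1.
  Individualised HRFs have small effects on pRF parameters, so a single
  canonical form is used for all simulated vertices. The kernel is
  causal ($h(0) = 0$) and its default support carries > 99% of its mass.

Because the fit maximises a Pearson correlation and the betas are fit
afterwards by ordinary least squares, the estimated $(x_0, y_0, \sigma)$
are invariant to any affine transform of the observed series — the pRF
model is amplitude-scale-invariant. This is verified to $10^{-6}$ in the
test suite.

## Stimulus design

The default `bar_design()` encodes the mapping protocol: a 0.53-degree
wide bar inside a 19-degree circular aperture, eight 25-step sweeps (one
step per second), the first moving bottom-to-top and each subsequent
sweep rotated 45 degrees clockwise, 25 s baselines after sweeps 4 and 8,
and 10 leading dummy frames (260 volumes per run in total, 250 after
dummy removal). Masks are binary, pixel centres at
$(i + 0.5)\,\Delta - 9.5$ with $\Delta = 19/\text{resolution}$; a pixel
is on iff its centre lies in the bar strip, inside the circle, and
outside a 0.53-degree central fixation hole. Contrast ramps at the bar
edge and around fixation are not representable in a binary mask and are
deliberately collapsed to hard edges.

**Step size.** The protocol text implies two incompatible readings: 25
steps of 0.38 degrees traverse only 9.5 of the aperture's 19 degrees.
Both are implemented. `step_mode = "full-coverage"` (default) uses
diameter/steps = 0.76 degrees so a sweep crosses the whole aperture —
appropriate when the goal is a map covering the full stimulated field.
`step_mode = "literal"` uses 0.38 degrees exactly as printed. The choice
matters quantitatively for the filtering experiment (below), because a
temporal blur of SD $s$ seconds is equivalent to a spatial blur of
$s \times$ bar speed along the sweep axis.

## Two-stage fitting

1. **Coarse fit.** The observed series is correlated against
   precomputed, z-scored predictions for a grid of candidates. The grid
   is the Cartesian product of 30 polar angles (12-degree spacing), 17
   log-spaced eccentricities in [0.25, 9.5] degrees and 15 log-spaced
   sigmas in [0.1, 5] degrees — 7,650 candidates. Only the product is
   protocol-fixed; the factorisation is a configurable choice
   (`grid_spec()`) with log spacing reflecting the roughly
   multiplicative scaling of pRF size and cortical magnification with
   eccentricity. Ties in the correlation are broken by the first
   candidate in grid order, making the argmax deterministic.
2. **Gate.** The winning candidate proceeds only if $r^2 > 0.01$. This
   gate is deliberately permissive: the maximum over thousands of
   candidates almost always exceeds it even for pure noise (at 250
   frames, $r^2 = 0.01$ is about 1.6 standard errors), so it rejects
   only degenerate or grossly unresponsive vertices. Meaningful
   selection happens later, at the map-display (0.10) and
   summary-inclusion (0.15) thresholds. All three thresholds are
   distinct named constants in `pipeline_config()`.
3. **Fine fit.** Nelder-Mead maximisation of the correlation over
   $(x_0, y_0, \log\sigma)$; the log-reparameterisation keeps $\sigma$
   positive without constraint handling. Controls: `maxit = 400`,
   `reltol = 1e-6`. If the optimizer errors or fails to improve on the
   start, the coarse candidate is returned and the vertex is labelled
   `coarse-only`; the refined correlation is never allowed to be worse
   than the coarse one.
4. **Betas.** $\beta_1$ (amplitude) and $\beta_0$ (baseline) come from
   OLS of the raw observed series on the final z-scored prediction.

**Degenerate inputs** are values, not errors, throughout: a prediction
with zero variance (pRF outside the stimulated region), a constant
observed series, or an exact-ramp series after detrending are returned
as flagged zero vectors (`is_degenerate()`), skipped silently by the
grid search, and reported as `stage = "failed"` rows — never as
spurious perfect fits.

## Preprocessing and temporal filtering

The pipeline order is fixed: per-run linear detrend, z-standardise,
average runs, then (optionally) low-pass filter, then fit. The low-pass
filter is a discrete Gaussian of SD 1 or 2 s, truncated at ±3 SD and
renormalised to unit sum (so constants pass unchanged), applied with
reflection padding to avoid endpoint attenuation. Only the **data** are
filtered, never the model prediction: the size bias of interest arises
precisely because a blurred measurement is matched against an unblurred
predictor, so the mismatch is resolved by inflating $\sigma$.

## The filtering-bias experiment

`filtering_bias_experiment()` simulates vertex ensembles at fixed true
sizes (defaults 0.5 and 2.5 degrees), fits each under no filtering and
kernels of SD 1 and 2 s, and reports the median fitted size and median
$R^2$ per condition plus the size ratio relative to the unfiltered fit.

The experiment defaults to the **literal** 0.38-degree step. The
mechanism under study is temporal blur masquerading as spatial pooling:
a kernel of SD $s$ blurs bar positions $s \times \text{speed}$ apart
into one response. At 0.38 degrees/s, a 2 s kernel mixes positions
roughly 0.76 degrees apart — devastating for a 0.5-degree pRF, almost
invisible to a 2.5-degree pRF that already integrates those positions.
Doubling the step to 0.76 degrees/s doubles the induced blur and makes
even large pRFs inflate appreciably, which contradicts the observed
phenomenology the experiment is meant to reproduce (small pRFs inflate,
large ones barely move). Simulated vertices default to eccentricities
of 0.5-4 degrees, inside the region the literal-mode bar actually
sweeps. This was decided once, on the mechanism above, and is
configurable.

## Noise ceiling

Runs are split into even- and odd-numbered halves (by run index, for
determinism; a seeded random split is available), each half averaged,
and the per-vertex Pearson correlation $r'$ between the halves corrected
to the full-set reliability by the Spearman-Brown prophecy formula with
doubling factor 2: $r_{obs} = 2r'/(1+r')$. Assuming perfectly reliable
predictors and a perfect hypothetical model-data correlation, the
maximum observable $R^2$ (the noise ceiling) equals $r_{obs}$.
Non-positive reliabilities are reported as undefined (`NA`) rather than
clamped — clamping would silently bias averages of the ceiling upward —
and their count is attached to the result. Normalised goodness-of-fit
($R^2 / \rho_o^2$) may exceed 1 under sampling noise; values above 1.5
are flagged, not clipped.

The ceiling is an upper bound **in expectation**: for a correctly
specified model both the ceiling and the achieved $R^2$ estimate the
same explainable-variance fraction, so on synthetic data roughly half
of individual vertices land above their ceiling by sampling noise. The
tests therefore check the paired mean difference, not a per-vertex
inequality.

## Surface metrics

Cortical magnification (CMF) follows the neighbour-polygon construction:
for each interior mesh vertex, the one-ring neighbours are ordered by
angle around the vertex in the cortical patch plane, the shoelace area
of their cortical positions and of their pRF centres is computed, and
CMF = $\sqrt{A_{cortex}}/\sqrt{A_{visual}}$ (mm/degree). Boundary
vertices (detected as vertices on an edge used by only one triangle),
rings smaller than three, rings containing unfitted vertices, and zero
visual areas all yield `NA`. Noisy maps can produce self-intersecting
visual polygons; the absolute shoelace area is used as-is and such
vertices are flagged (`inconsistent_winding`) so downstream summaries
can exclude them. Map smoothing uses Gaussian weights (FWHM in mm,
truncated at 3 SD, renormalised, `NA` neighbours dropped) on Euclidean
distance in the flat patch — geodesic or spherical distances belong to
the surface-reconstruction toolchain, which is out of scope here.

Eccentricity-binned summaries use half-open 1-degree bands from 0.5 to
9.5 degrees (final band closed, so no value is double-counted or
dropped), the mean for pRF size and the median for other statistics,
percentile bootstrap intervals (1,000 resamples, central 95%), and the
$R^2 > 0.15$ inclusion rule for size and CMF. Map comparison restricts
to vertices above $R^2 = 0.1$ in **both** maps and uses the Fisher-Lee
circular correlation for polar angle (rotation-invariant; the specific
circular-correlation variant is a package choice, as several exist) and
Spearman's rank correlation for eccentricity.

## Synthetic data: what it emulates and what it does not

`make_truth_layout()` places vertices uniformly per unit area of an
annulus and assigns sizes by a linear law $\sigma = a + b\,e$ (defaults
$a = 0.3$, $b = 0.34$, chosen so sizes span roughly 0.5-3 degrees over
eccentricities 0.5-8, the range early visual areas show). Each
simulated run is

$$ y_t = A\,\hat p_t + \text{drift}_t + \varepsilon_t,
   \qquad \varepsilon_t \sim N(0, s^2), $$

where $\hat p$ is the **z-scored** noiseless prediction. Scaling the
standardised prediction (rather than the raw overlap sum) makes the
per-vertex signal SD exactly $A$, so the single-run explainable-variance
fraction is $A^2/(A^2 + s^2)$ in closed form — the property the
reliability tests are built on. The default noise SD $\sqrt{14}$ with
$A = 1$ puts the six-run average at $R^2 \approx 0.3$, the low
goodness-of-fit regime characteristic of 1 s TR acquisitions where
high-frequency noise dominates. Drift defaults to a linear ramp
(removed exactly by detrending); a sinusoidal drift with random phase
is available to stress the pipeline but is off by default, and
autocorrelated noise is deliberately not modelled — the generator's
noise is white.

What passing tests on this generator do **not** show: robustness to
physiological (cardiac/respiratory) noise spectra, spatial correlation
of noise across vertices, BOLD nonlinearity, HRF variability across
cortex, or surface-projection artifacts. Results here characterise the
estimator, not the scanner.

At the default noise level the estimator spread is substantial — the
acceptance script computes median position errors of roughly half a
degree and median size errors around 20% for 200 vertices — and this is
a property of the information content of 250 frames at that
signal-to-noise ratio, not of the optimizer: the fitted correlation
meets or exceeds the true-parameter correlation for every vertex in the
suite's recovery runs. Precision claims at low $R^2$ should be made
accordingly.

## Problem sizes and determinism

Simulation experiments default to 50x50 masks (100x100 for fidelity
runs), 250 frames, 6 runs and 100-200 vertices; the full grid build and
a 200-vertex recovery run complete in about a minute on one CPU. Every
stochastic function takes a mandatory integer seed; there is no hidden
RNG state, and rerunning any experiment with the same seed and
configuration reproduces its outputs byte-for-byte (checked in the
pipeline tests via file checksums). `run_pipeline()` writes a manifest
(config JSON, its MD5, seed, package version, artifact list) sufficient
to regenerate every artifact.

## Known limitations

- Isotropic Gaussian pRFs only; no compressive summation, no
  difference-of-Gaussians, no per-vertex HRF estimation.
- Binary apertures: contrast ramps and the carrier pattern are not
  modelled.
- Flat-patch geometry for smoothing and CMF; no spherical meshes.
- The coarse grid's axis factorisation is a reconstruction — only the
  candidate total is protocol-fixed.
- White noise is an explicit stand-in for real fMRI noise spectra.
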