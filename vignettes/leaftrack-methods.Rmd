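---
title: "Methods: differential motion tracking and circadian period estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential motion tracking and circadian period estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaftrack)
```

`leaftrack` turns a directory of time-lapse plant images into per-plant
circadian period estimates. This vignette documents the models, the
parameters that matter, the numerical choices, and what the simulation-based
validation does and does not establish.

## The motion model and its assumptions

Between consecutive frames the plant region is assumed to translate
rigidly: brightness constancy plus a first-order Taylor expansion of the
squared-error objective yields the linear system `v = M⁻¹ b`, where `M` is
the 2×2 sum of spatial-gradient outer products over the region of interest
and `b` the sum of gradient–temporal-derivative products. Derivatives use
matched separable 2-tap filters, `d = (0.5, −0.5)` for differentiation and
`p = (0.5, 0.5)` for prefiltering; spatial derivatives are taken on the
average of the two frames, the temporal derivative on half their
difference. Convolution is restricted to the valid region (there is no
principled boundary rule for a 2-tap stencil, so no padding is invented);
each derivative field is one pixel smaller than the frame in each axis.

The assumptions this buys, and their consequences:

* **Small motion.** The linearization is accurate for sub-pixel to ~1 px
  steps and degrades beyond ~2 px (`test-motion.R` documents the monotone
  error growth). At 20-min sampling, leaf movement is comfortably inside
  this regime; the synthetic scene generator enforces it and refuses scenes
  whose implied per-step displacement exceeds 2 px. No coarse-to-fine
  pyramid is applied: the one-shot solve is the method, and a pyramid would
  be an extension point, not default behavior.
* **Single translation per plant.** Leaves moving antagonistically within
  one crop partially cancel; the method reads out the net vertical motion
  of the cropped region. This is a feature for whole-plant rhythm readout,
  but it means the trace amplitude is not a per-leaf amplitude.
* **Textured region.** `M` is invertible only with gradients in both axes.
  The solve is declared ill-conditioned when the smallest eigenvalue of `M`
  falls below `1e-9 ×` (ROI pixel count); such pairs are recorded as
  missing, linearly interpolated from neighboring pairs, and flagged.
  Interpolation (rather than ridge regularization or zeroing) preserves the
  uniform time grid the FFT needs without biasing well-conditioned solves.
  A stack with no trackable pair at all is an error.

Sign conventions: image y grows downward, and `v_y` is the displacement of
the pattern from the earlier to the later frame (+1 px downward motion ⇒
`v_y = +1`). Plots of "upward leaf movement" can negate the series for
display; the stored data never flips. The per-pair velocity series itself
(not its cumulative sum) is the rhythm signal — its period is the same and
its baseline is better behaved.

## Period estimation

Three steps, exposed individually and composed by `estimate_period()`:

1. **Detrend** (`detrend_trace()`): subtract the OLS line. Removes net
   drift (growth) that otherwise dominates low frequencies.
2. **FFT initial guess** (`initial_period_fft()`): zero-pad to 4× the trace
   length, take the magnitude-maximal non-DC bin within the plausible band,
   default 16–36 h. A raw 120-h window has ~4.8 h resolution near 24 h —
   too coarse to start a local optimizer reliably; 4× padding refines the
   grid to ~1.2 h. The band is deliberately wider than the downstream QC
   bounds (18–32 h) so the estimator is not clipped before QC sees it.
3. **Nelder-Mead refinement** (`refine_fit()`): minimize the RMS misfit of
   `c + A·cos(2πt/τ + φ)` over `(τ, φ, A, c)`, started at τ₀ with `A` and
   `φ` from the complex Fourier coefficient at `1/τ₀` evaluated on the
   actual time grid. Settings: relative objective tolerance `1e-10`,
   max 2000 iterations (the optimizer is named by the method; the settings
   are this package's choice, and the fit reports `converged`). A constant
   offset is refined even though detrending centers the data: it converges
   to ~0 and guards against residual baseline. Because refinement starts
   from the initialization's own cosine, the refined RMS error never
   exceeds the initial one (asserted on every fit in the tests).

### Estimator bias: whole-cycle windows vs. leakage

On a window containing a whole number of cycles, detrending removes
(numerically) nothing from a pure cosine and the estimator is exact on its
model class — the test suite demonstrates recovery to < 0.01 h for
noise-free periods 16–36 h on 5-cycle windows. On a fixed 120-h window,
periods that do not divide the window (everything except 20 and 24 h)
suffer line-fit leakage: the OLS line absorbs part of the cosine, the
residual is no longer exactly sinusoidal, and the fitted period shifts by
up to ~0.1 h. This deterministic leakage, not noise, is why the simulation
grid recovers 20 h and 24 h essentially exactly while neighboring periods
carry a small bias — a pattern any detrend-then-fit single-cosine method
shares. The QC gates are far wider than this bias.

## The synthetic-data generator

The generator defines the validation conditions; it is not a tuning knob.

**1-D traces** (`simulate_trace()`): `y_i = exp(−r·i)·cos(2πt_i/τ) + ε_i`
with unit initial amplitude; amplitude trends I/II/III set the per-sample
decay rate `r` to 0, 0.001, 0.002, and noise levels A/B/C set the iid
Gaussian sd to 0.2, 0.6, 1.0. Defaults: 20-min sampling, 120-h duration
(5 imaging days). Decisions made where the design left room: the decay is
per sample (at `r = 0.002`, 360 samples, the envelope halves over the
trace — a visually plausible damping for leaf movement as petiole growth
slows), the envelope is exponential, and the noise is Gaussian; a numeric
decay rate or noise sd can be passed directly in place of the enum levels.
Replicate `k` of a set draws from a stream derived deterministically from
`(seed, k)`, so factorial sets are reproducible cell-by-cell.

**2-D sequences** (`blob_scene()`, `simulate_image_sequence()`): a
separable Gaussian-profile blob on a dark background, vertical center
`y₀ + A·cos(2πt/τ)`, rendered analytically at pixel centers so sub-pixel
positions are exact, with optional Gaussian pixel noise. Defaults: 120×120
px frames (above the ~100×100 px per-plant footprint the imaging protocol
recommends), 6 px amplitude, 20-min frames, 120 h. Sub-pixel rendering
conserves blob mass to < 1%, and scenes violating the small-motion bound or
a 5× contrast-to-noise floor are rejected at construction.

What the simulations emulate: a single smooth high-contrast moving object,
stationary camera, constant illumination, stationary rhythm parameters.
What they do not: leaf shape change and growth, multiple leaves with
different phases, illumination flicker, shadows, soil movement, camera
compression artifacts, amplitude and period drift. Passing the recovery
suite therefore validates the estimator chain and its implementation — not
robustness to every field condition; the QC filters exist precisely because
real traces fail in ways these simulations do not.

## Quality control

Filtering follows the two published gates, in this order (the order is a
package decision; both removals are logged): per-plant periods below 18 h
or above 32 h are removed — "below/above" read strictly, so 18.0 h and
32.0 h are retained — then per-line SEM (sample sd with `n−1`, divided by
`√n`) above 0.50 h excludes the line. Single-estimate lines are excluded
rather than passed with SEM 0: the SEM is the precision gate and is
undefined at `n = 1`.

## Interfaces and sizes

Traces are two-column CSVs (`time_hours,value`); motion traces add
`plant_id` and an `interpolated_flag`; grids are five-column CSVs in
0-based, half-open pixel coordinates (x right, y down — unambiguous
tiling). The CLI (`inst/exec/leaftrack`) wires `simulate`, `crop`, `track`,
`period`, and `all` over these files and writes a provenance record per
run.

Validation sizes used throughout the package: the factorial recovery grid
is 9 periods × 3 trends × 3 noise levels × 10 replicates (270 traces of 360
samples); full-pipeline checks render 120-h, 360-frame sequences at 120×120
px; oracle cross-checks of the translation solve use 50 random sub-pixel
shifts against a coarse-to-fine SSD grid search over analytically
re-rendered frames.

## Known limitations

* One translation per crop: two plants in a cell, or a plant crossing the
  cell border, corrupt the trace. Draw grid cells against the first *and*
  last frame.
* No rotation/affine motion, no dense flow output; the motion field
  visualization is a debugging aid, not a measurement.
* A single fitted frequency: multi-component rhythms (e.g. strong 12-h
  harmonics) bias the fit toward the dominant component only. The motion
  CSVs are deliberately plain so external rhythm-analysis tools can be used
  on the same traces.
* Period estimates on windows much shorter than two cycles are refused by
  the trace simulator and unreliable in general; the estimator itself
  requires only that the FFT band contains a bin.
* Uniform sampling is assumed everywhere; dropped frames must be filled
  upstream (the tracker's interpolation handles ill-conditioned pairs, not
  missing files).
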