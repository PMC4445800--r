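# leaftrack

Automated measurement of circadian rhythms in plants from time-lapse
photography.

A classic output of the plant circadian clock is the daily up-and-down
movement of cotyledons and leaves. Imaging seedlings every 10–20 minutes for
several days under constant light, then extracting the rhythm of leaf
movement, gives a per-plant estimate of free-running circadian period — a
phenotype used to screen clock mutants, compare species, and map natural
variation in mapping populations. Traditional analyses require drawing a
region around every individual leaf and tracking it by hand, which does not
scale to hundreds of plants. `leaftrack` replaces that bottleneck with a
fully automated pipeline: each plant is cropped once with a fixed grid, the
plant's whole-frame motion is summarized by one displacement vector per
frame pair, and the period of the vertical motion series is estimated by
spectral initialization plus nonlinear refinement.

## Method

**Motion estimation.** For consecutive frames *f*(*x*, *y*, *t*) and
*f*(*x*, *y*, *t*−1), the motion over a region Ω is modeled as a single 2-D
translation **v** = (*v*ₓ, *v*ᵧ). Linearizing the brightness-constancy error
E(**v**) = Σ_Ω [*f*ₜ − **f**ₛᵀ**v**]² with a first-order Taylor expansion
gives the closed-form normal-equation solution

    v = M⁻¹ b,   M = Σ_Ω f_s f_sᵀ,   b = Σ_Ω f_s f_t,

where **f**ₛ = (*f*ₓ, *f*ᵧ) are spatial derivatives and *f*ₜ the temporal
derivative, computed with separable 2-tap filters d = (0.5, −0.5) and
p = (0.5, 0.5) applied to the temporal average (spatial terms) or the
temporal half-difference (temporal term) of the frame pair. The 2×2 matrix
M must be well-conditioned — guaranteed in practice by cropping each plant
so Ω contains real texture; degenerate pairs are flagged, skipped, and
interpolated. The per-pair vertical component *v*ᵧ(*t*) (pixels per frame
step, positive downward) is the rhythm signal.

**Period estimation.** The series *v*ᵧ(*t*) is detrended by removing its
OLS line, the FFT periodogram (zero-padded 4×) supplies an initial period
τ₀ as the in-band magnitude peak, and Nelder-Mead then minimizes the RMS
misfit of a single cosine *c* + *A* cos(2π*t*/τ + φ) over (τ, φ, *A*, *c*).
This is FFT-NLLS restricted to one frequency, which suffices because the
motion signal is dominated by a single circadian component.

**Quality control.** Per-plant periods outside [18, 32] h are removed;
per-line means are gated on the standard error of the mean (lines with
SEM > 0.50 h, i.e. 30 min, are excluded).

**Validation by simulation.** The package ships its own synthetic-data
module: 1-D decaying noisy cosine traces on a factorial design (periods
20–28 h × amplitude-decay trends 0/0.001/0.002 per sample × noise sd
0.2/0.6/1.0 × amplitude, 10 replicates each) and fully rendered 2-D image
sequences of a Gaussian blob oscillating vertically with known period, so
both the estimator alone and the complete image pipeline are checked by
parameter recovery.

## Worked example

Estimate the period of a simulated noisy trace (true period 24.5 h,
decaying amplitude, noise sd 0.6 × amplitude):

```r
library(leaftrack)

tr  <- simulate_trace(24.5, trend = "II", noise = "B", seed = 7)
fit <- estimate_period(tr)
tidy(fit)
#> # A tibble: 1 × 7
#>   period_h phase_rad amplitude offset rms_error tau0_h converged
#>      <dbl>     <dbl>     <dbl>  <dbl>     <dbl>  <dbl> <lgl>
#> 1     24.7    0.0498     0.884 0.0215     0.595     24 TRUE
```

The FFT lands on the 24 h padded bin; refinement moves the estimate to
24.66 h, within the dispersion expected at this noise level. `rms_error`
is in trace units (here the noise floor ≈ 0.6), and `autoplot(fit)` overlays
the fitted cosine on the detrended data.

Run the full image pipeline on a rendered oscillating-blob sequence
(true period 25 h, 6 px amplitude, 20-min frames for 5 days):

```r
stack <- simulate_image_sequence(blob_scene(period_h = 25,
                                            oscillation_amplitude_px = 6))
trace <- track_stack(stack)          # one (v_x, v_y) per frame pair
tidy(estimate_period(trace, value_col = "v_y"))
#> # A tibble: 1 × 7
#>   period_h phase_rad amplitude offset rms_error tau0_h converged
#>      <dbl>     <dbl>     <dbl>  <dbl>     <dbl>  <dbl> <lgl>
#> 1     25.0      1.58     0.496 0.0133    0.0368   25.2 TRUE
```

The recovered period is 25.04 h. The fitted amplitude ≈ 0.50 px/step is the
peak frame-to-frame velocity implied by the scene (6 px × 2π × ⅓ h / 25 h).

A shell interface wraps the same functions
(`system.file("exec", "leaftrack", package = "leaftrack")`):

```sh
leaftrack simulate --what video --period 24 --amp-px 6 --out frames/
leaftrack all --in frames/ --grid grid.csv --interval 20 --out run/
```

Each command writes a `provenance.json` (parameters, seed, version) beside
its outputs; identical configuration and seed give byte-identical CSVs.

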