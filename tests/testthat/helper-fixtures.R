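# Shared fixtures: small blob scenes and the brute-force SSD oracle used to
# cross-check the differential translation estimator.

test_scene <- function(frame = 64, sd_x = 7, sd_y = 6, amplitude = 4,
                       period_h = 24, duration_h = 120, noise_sd = 0,
                       seed = 1) {
  blob_scene(frame_width = frame, frame_height = frame,
             sd_x = sd_x, sd_y = sd_y,
             oscillation_amplitude_px = amplitude, period_h = period_h,
             duration_h = duration_h, noise_sd = noise_sd, seed = seed)
}

# a frame pair whose true translation is exactly (dx, dy): both rendered
# analytically at sub-pixel centers
shifted_pair <- function(scene, dx, dy) {
  list(
    prev = render_blob_frame(scene),
    cur = render_blob_frame(scene,
                            center_y = scene$center_y + dy,
                            center_x = scene$center_x + dx)
  )
}

# Brute-force SSD oracle: find the translation whose analytic re-rendering
# of the blob best matches `target`, by coarse-to-fine grid search over a
# dense grid of candidate sub-pixel translations. Independent of the
# derivative-based estimator.
oracle_translation <- function(scene, target, span = 1.5) {
  best <- c(0, 0)
  step <- 0.1
  for (pass in 1:3) {
    dxs <- seq(best[1] - span, best[1] + span, by = step)
    dys <- seq(best[2] - span, best[2] + span, by = step)
    ssd <- matrix(NA_real_, length(dys), length(dxs))
    for (i in seq_along(dys)) {
      for (j in seq_along(dxs)) {
        f <- render_blob_frame(scene,
                               center_y = scene$center_y + dys[i],
                               center_x = scene$center_x + dxs[j])
        ssd[i, j] <- sum((target - f)^2)
      }
    }
    idx <- arrayInd(which.min(ssd), dim(ssd))
    best <- c(dxs[idx[2]], dys[idx[1]])
    span <- 2 * step
    step <- step / 10
  }
  best
}

# dense periodogram oracle: period of maximal spectral magnitude on a fine
# continuous frequency grid (no FFT binning)
oracle_periodogram_peak <- function(trace, band = c(16, 36), n_grid = 4000) {
  periods <- seq(band[1], band[2], length.out = n_grid)
  mag <- vapply(periods, function(p) {
    Mod(sum(trace$value * exp(-2i * pi * trace$time_hr / p)))
  }, numeric(1))
  periods[which.max(mag)]
}
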