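#' Specify a synthetic oscillating-blob scene
#'
#' Describes a 2-D image sequence of a smooth plant-like blob (a Gaussian
#' intensity profile on a dark background) whose vertical center oscillates
#' as \eqn{y(t) = y_0 + A \cos(2\pi t / \tau)}. Rendering is analytic at
#' pixel centers, so sub-pixel positions are exact; the sequence serves as a
#' ground-truth input for the motion-estimation and period pipeline.
#'
#' The per-step displacement implied by the oscillation,
#' \eqn{A \cdot 2\pi \Delta t / \tau}, must stay at or below 2 px: the
#' differential motion estimator linearizes the image around small
#' translations and larger steps leave that regime.
#'
#' @param frame_width,frame_height Frame size in pixels (default 120 x 120,
#'   above the 100 x 100 px minimum plant footprint the imaging protocol
#'   assumes).
#' @param center_x,center_y Blob rest center, pixels (default frame center).
#' @param sd_x,sd_y Gaussian profile widths, pixels.
#' @param oscillation_amplitude_px Vertical oscillation amplitude, pixels.
#' @param period_h Oscillation period, hours.
#' @param background,foreground Background and peak foreground intensity in
#'   \[0, 1\]; contrast must exceed 5 x `noise_sd`.
#' @param noise_sd Additive Gaussian pixel-noise sd, intensity units.
#' @param sampling_interval_min Frame interval, minutes.
#' @param duration_h Sequence duration, hours.
#' @param seed Integer seed for pixel noise.
#' @return An object of class `blob_scene`.
#' @examples
#' sc <- blob_scene(period_h = 24, oscillation_amplitude_px = 6)
#' @export
blob_scene <- function(frame_width = 120, frame_height = 120,
                       center_x = frame_width / 2,
                       center_y = frame_height / 2,
                       sd_x = 10, sd_y = 8,
                       oscillation_amplitude_px = 6,
                       period_h = 24,
                       background = 0.05, foreground = 0.9,
                       noise_sd = 0,
                       sampling_interval_min = 20, duration_h = 120,
                       seed = 1) {
  if (period_h <= 0 || sampling_interval_min <= 0 || duration_h <= 0) {
    abort("period, interval, and duration must be positive",
          class = "leaftrack_error_spec")
  }
  dt_h <- sampling_interval_min / 60
  max_step <- abs(oscillation_amplitude_px) * 2 * pi * dt_h / period_h
  if (max_step > 2) {
    abort(
      paste0("maximum per-step displacement ", round(max_step, 3),
             " px exceeds 2 px: the differential motion model assumes ",
             "small inter-frame translations (reduce the amplitude or ",
             "shorten the frame interval)"),
      class = "leaftrack_error_spec"
    )
  }
  if (foreground - background <= 5 * noise_sd) {
    abort("foreground/background contrast must exceed 5x the pixel noise sd",
          class = "leaftrack_error_spec")
  }
  structure(
    list(frame_width = frame_width, frame_height = frame_height,
         center_x = center_x, center_y = center_y, sd_x = sd_x, sd_y = sd_y,
         oscillation_amplitude_px = oscillation_amplitude_px,
         period_h = period_h, background = background,
         foreground = foreground, noise_sd = noise_sd,
         sampling_interval_min = sampling_interval_min,
         duration_h = duration_h, seed = seed),
    class = "blob_scene"
  )
}

#' Render one frame of a blob scene
#'
#' Evaluates the separable Gaussian profile at pixel centers (pixel (i, j)
#' covers \[j-1, j\) x \[i-1, i\) with center (j - 0.5, i - 0.5) in 0-based
#' image coordinates), for an arbitrary sub-pixel blob center.
#'
#' @param scene A [blob_scene].
#' @param center_y,center_x Blob center for this frame, pixels; default the
#'   scene's rest center.
#' @return A `frame_height` x `frame_width` numeric matrix (no noise).
#' @export
render_blob_frame <- function(scene, center_y = scene$center_y,
                              center_x = scene$center_x) {
  px <- seq_len(scene$frame_width) - 0.5
  py <- seq_len(scene$frame_height) - 0.5
  gx <- exp(-((px - center_x)^2) / (2 * scene$sd_x^2))
  gy <- exp(-((py - center_y)^2) / (2 * scene$sd_y^2))
  scene$background + (scene$foreground - scene$background) * (gy %o% gx)
}

#' Simulate a synthetic oscillating-blob image sequence
#'
#' Renders the scene at each frame time, with the blob's vertical center at
#' \eqn{y_0 + A \cos(2\pi t / \tau)}, and adds optional iid Gaussian pixel
#' noise (clipped to \[0, 1\]). Deterministic given the scene seed.
#'
#' @param scene A [blob_scene].
#' @return An [image_stack].
#' @examples
#' stack <- simulate_image_sequence(
#'   blob_scene(period_h = 24, duration_h = 48)
#' )
#' stack
#' @export
simulate_image_sequence <- function(scene) {
  stopifnot(inherits(scene, "blob_scene"))
  dt_h <- scene$sampling_interval_min / 60
  n <- floor(scene$duration_h / dt_h)
  t_hr <- (seq_len(n) - 1) * dt_h
  cy <- scene$center_y +
    scene$oscillation_amplitude_px * cos(2 * pi * t_hr / scene$period_h)
  frames <- with_seed(scene$seed, {
    lapply(seq_len(n), function(k) {
      f <- render_blob_frame(scene, center_y = cy[k])
      if (scene$noise_sd > 0) {
        f <- f + matrix(rnorm(length(f), sd = scene$noise_sd),
                        nrow = nrow(f))
        f <- pmin(pmax(f, 0), 1)
      }
      f
    })
  })
  image_stack(frames, scene$sampling_interval_min,
              source_ids = sprintf("frame_%03d", seq_len(n) - 1))
}

#' Write an image stack as numbered PNG frames plus a JSON sidecar
#'
#' Frames are written as `frame_000.png`, `frame_001.png`, ... and a
#' `stack.json` sidecar records the sampling interval plus any extra
#' metadata supplied (e.g. the true period and seed of a synthetic scene).
#'
#' @param stack An [image_stack].
#' @param directory Output directory (created if missing).
#' @param metadata Named list of extra fields for the sidecar.
#' @return `directory`, invisibly.
#' @export
write_stack <- function(stack, directory, metadata = list()) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- length(stack$frames)
  paths <- file.path(directory, sprintf("frame_%03d.png", seq_len(n) - 1))
  for (k in seq_len(n)) {
    png::writePNG(pmin(pmax(stack$frames[[k]], 0), 1), paths[k])
  }
  sidecar <- c(
    list(n_frames = n,
         sampling_interval_min = stack$sampling_interval_min,
         frame_height = nrow(stack$frames[[1]]),
         frame_width = ncol(stack$frames[[1]])),
    metadata
  )
  jsonlite::write_json(sidecar, file.path(directory, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}
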