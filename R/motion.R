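#' Spatial and temporal image derivatives for a frame pair
#'
#' Approximates the derivatives needed by the differential motion model from
#' two consecutive frames, using separable 2-tap filters: a derivative
#' filter `d = (0.5, -0.5)` and a matching prefilter (averager)
#' `p = (0.5, 0.5)`. The spatial derivatives are taken on the temporal
#' average of the two frames and smoothed with `p` along the other axis; the
#' temporal derivative is half the frame difference smoothed with `p` along
#' both axes:
#' \deqn{f_x = (0.5 f_t + 0.5 f_{t-1}) \star d(x) \star p(y)}
#' \deqn{f_y = (0.5 f_t + 0.5 f_{t-1}) \star p(x) \star d(y)}
#' \deqn{f_t = (0.5 f_t - 0.5 f_{t-1}) \star p(x) \star p(y)}
#' Convolution is valid-region only (no boundary padding), so each output is
#' one row and one column smaller than the input. The derivative filter is
#' oriented so that an intensity ramp increasing with x gives positive
#' `f_x` (forward-difference sense): for `f(x, y) = x`, `f_x = 0.5`.
#'
#' @param frame_t,frame_prev Numeric matrices of identical size (>= 2 x 2);
#'   `frame_t` is the later frame.
#' @return A list with matrices `f_x`, `f_y`, `f_t`, each
#'   `(nrow - 1) x (ncol - 1)`.
#' @export
compute_derivatives <- function(frame_t, frame_prev) {
  if (!is.matrix(frame_t) || !is.matrix(frame_prev) ||
      !identical(dim(frame_t), dim(frame_prev))) {
    abort("frames must be numeric matrices of identical dimensions",
          class = "leaftrack_error_motion")
  }
  if (nrow(frame_t) < 2 || ncol(frame_t) < 2) {
    abort("frames must be at least 2x2", class = "leaftrack_error_motion")
  }
  avg <- 0.5 * (frame_t + frame_prev)
  dif <- 0.5 * (frame_t - frame_prev)
  nr <- nrow(avg)
  nc <- ncol(avg)
  # 2x2 valid-region stencils; sub-block shorthand: 11 = (i, j),
  # 12 = (i, j+1), 21 = (i+1, j), 22 = (i+1, j+1)
  blk <- function(a) {
    list(a11 = a[-nr, -nc], a12 = a[-nr, -1],
         a21 = a[-1, -nc], a22 = a[-1, -1])
  }
  a <- blk(avg)
  d <- blk(dif)
  list(
    f_x = 0.25 * ((a$a12 - a$a11) + (a$a22 - a$a21)),
    f_y = 0.25 * ((a$a21 - a$a11) + (a$a22 - a$a12)),
    f_t = 0.25 * (d$a11 + d$a12 + d$a21 + d$a22)
  )
}

#' Estimate a single 2-D translation from a derivative field
#'
#' Solves the normal equations of the linearized brightness-constancy model:
#' gradient outer products are summed over the region of interest to form
#' the 2 x 2 structure matrix `M` and right-hand side `b`, and the
#' translation is the solution of the 2 x 2 system. The sign convention is
#' that a pattern moving +1 px in image x (rightward) and +1 px in image y
#' (downward) between `frame_prev` and `frame_t` yields
#' `(v_x, v_y) = (1, 1)`.
#'
#' A unique solve needs `M` well-conditioned, i.e. image texture with
#' gradients in both directions inside the ROI. When the smallest eigenvalue
#' of `M` falls below `eigen_floor` x (ROI pixel count), `condition_ok` is
#' `FALSE` and the estimate is `NA`.
#'
#' @param deriv Output of [compute_derivatives].
#' @param roi Optional ROI as `c(x_min, y_min, width, height)` in 0-based
#'   pixel coordinates of the valid region, or `NULL` for the full valid
#'   region (the natural default once frames are cropped per plant).
#' @param min_pixels Minimum ROI pixel count.
#' @param eigen_floor Per-pixel floor for the smallest eigenvalue of `M`.
#' @return A one-row tibble: `v_x`, `v_y`, `condition_ok`.
#' @export
estimate_translation <- function(deriv, roi = NULL, min_pixels = 16,
                                 eigen_floor = 1e-9) {
  fx <- deriv$f_x
  fy <- deriv$f_y
  ft <- deriv$f_t
  if (!is.null(roi)) {
    rows <- (roi[2] + 1):(roi[2] + roi[4])
    cols <- (roi[1] + 1):(roi[1] + roi[3])
    if (min(rows) < 1 || min(cols) < 1 ||
        max(rows) > nrow(fx) || max(cols) > ncol(fx)) {
      abort("ROI lies outside the valid derivative region",
            class = "leaftrack_error_motion")
    }
    fx <- fx[rows, cols]
    fy <- fy[rows, cols]
    ft <- ft[rows, cols]
  }
  npix <- length(fx)
  if (npix < min_pixels) {
    abort(paste0("ROI has ", npix, " px, fewer than the minimum of ",
                 min_pixels), class = "leaftrack_error_motion")
  }
  if (!all(is.finite(fx)) || !all(is.finite(fy)) || !all(is.finite(ft))) {
    abort("derivative fields contain non-finite values",
          class = "leaftrack_error_motion")
  }
  m11 <- sum(fx * fx)
  m12 <- sum(fx * fy)
  m22 <- sum(fy * fy)
  b1 <- sum(fx * ft)
  b2 <- sum(fy * ft)
  # eigenvalues of the symmetric 2x2 structure matrix
  tr <- m11 + m22
  det_m <- m11 * m22 - m12 * m12
  disc <- sqrt(max((m11 - m22)^2 / 4 + m12^2, 0))
  lambda_min <- tr / 2 - disc
  if (!is.finite(lambda_min) || lambda_min < eigen_floor * npix) {
    return(tibble(v_x = NA_real_, v_y = NA_real_, condition_ok = FALSE))
  }
  # the linearized model gives f_t = -(v . grad f) under the displacement
  # convention, hence the negation of the solve
  v <- -c(m22 * b1 - m12 * b2, m11 * b2 - m12 * b1) / det_m
  tibble(v_x = v[1], v_y = v[2], condition_ok = TRUE)
}

#' Track inter-frame motion across an image stack
#'
#' Runs the derivative + translation solve on every consecutive frame pair,
#' returning the horizontal and vertical motion series. Pairs whose
#' structure matrix is ill-conditioned (no trackable texture) are recorded
#' as missing, linearly interpolated from neighboring pairs, and flagged,
#' so the series keeps its uniform time grid for spectral analysis. The
#' vertical series `v_y` (positive = downward in image coordinates) is the
#' rhythm signal used for period estimation.
#'
#' @param stack An [image_stack] (>= 2 frames), typically one cropped plant.
#' @param roi Optional ROI passed to [estimate_translation]; default the
#'   full valid region of each frame pair.
#' @param plant_id Optional identifier carried into the output.
#' @inheritParams estimate_translation
#' @return A tibble with one row per frame pair: `time_hr` (pair midpoint),
#'   `v_x`, `v_y` (pixels per frame step), `interpolated`.
#' @examples
#' stack <- simulate_image_sequence(
#'   blob_scene(period_h = 24, duration_h = 48)
#' )
#' trace <- track_stack(stack)
#' head(trace)
#' @export
track_stack <- function(stack, roi = NULL, plant_id = NULL,
                        min_pixels = 16, eigen_floor = 1e-9) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  if (n < 2) {
    abort("stack must have at least 2 frames",
          class = "leaftrack_error_motion")
  }
  dt_h <- stack$sampling_interval_min / 60
  vx <- vy <- rep(NA_real_, n - 1)
  for (k in 2:n) {
    deriv <- compute_derivatives(stack$frames[[k]], stack$frames[[k - 1]])
    est <- estimate_translation(deriv, roi = roi, min_pixels = min_pixels,
                                eigen_floor = eigen_floor)
    if (est$condition_ok) {
      vx[k - 1] <- est$v_x
      vy[k - 1] <- est$v_y
    }
  }
  bad <- is.na(vy)
  if (all(bad)) {
    abort("no trackable content: every frame pair was ill-conditioned",
          class = "leaftrack_error_motion")
  }
  if (any(bad)) {
    idx <- seq_len(n - 1)
    vx <- stats::approx(idx[!bad], vx[!bad], xout = idx, rule = 2)$y
    vy <- stats::approx(idx[!bad], vy[!bad], xout = idx, rule = 2)$y
  }
  out <- tibble(
    time_hr = (seq_len(n - 1) - 0.5) * dt_h,
    v_x = vx, v_y = vy,
    interpolated = bad
  )
  if (!is.null(plant_id)) {
    out <- mutate(out, plant_id = plant_id, .before = 1)
  }
  out
}

#' Track every plant of a gridded stack
#'
#' Convenience wrapper: [crop_stack] then [track_stack] per plant.
#'
#' @inheritParams crop_stack
#' @inheritParams track_stack
#' @return A tibble of per-plant motion traces bound by row, with a
#'   `plant_id` column.
#' @export
track_plants <- function(stack, grid, min_pixels = 10000, ...) {
  plants <- crop_stack(stack, grid, min_pixels = min_pixels)
  bind_rows(imap(plants, function(s, id) track_stack(s, plant_id = id, ...)))
}

#' Write a motion trace CSV
#'
#' Columns: `plant_id,time_hours,v_x,v_y,interpolated_flag`.
#'
#' @param trace Output of [track_stack] (with a `plant_id` column, or
#'   supply `plant_id`).
#' @param path File path.
#' @param plant_id Identifier used if the trace lacks a `plant_id` column.
#' @return `path`, invisibly.
#' @export
write_motion_trace <- function(trace, path, plant_id = "plant") {
  id <- if ("plant_id" %in% names(trace)) trace$plant_id else plant_id
  out <- data.frame(
    plant_id = id,
    time_hours = trace$time_hr,
    v_x = trace$v_x,
    v_y = trace$v_y,
    interpolated_flag = as.integer(trace$interpolated)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "time_hours", "v_x", "v_y", "interpolated_flag")
  if (!all(need %in% names(df))) {
    abort(paste0("not a motion-trace CSV: ", path),
          class = "leaftrack_error_io")
  }
  tibble(plant_id = df$plant_id, time_hr = df$time_hours,
         v_x = df$v_x, v_y = df$v_y,
         interpolated = as.logical(df$interpolated_flag))
}
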