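#' Remove a linear trend from a trace
#'
#' Subtracts the ordinary least-squares line fit to `(time_hr, value)`. The
#' output has zero mean and zero linear trend (to floating tolerance), which
#' keeps slow drift — e.g. net growth superimposed on the leaf-movement
#' rhythm — from dominating the low-frequency end of the periodogram.
#'
#' @param trace A trace tibble (`time_hr`, `value`) with >= 3 samples.
#' @return The detrended trace tibble.
#' @examples
#' tr <- tibble::tibble(time_hr = 0:9, value = 3 + 0.5 * (0:9))
#' detrend_trace(tr)$value  # all ~0
#' @export
detrend_trace <- function(trace) {
  assert_trace(trace)
  if (nrow(trace) < 3) {
    abort("detrending needs at least 3 samples",
          class = "leaftrack_error_period")
  }
  t <- trace$time_hr
  y <- trace$value
  tc <- t - mean(t)
  slope <- sum(tc * (y - mean(y))) / sum(tc * tc)
  mutate(trace, value = y - mean(y) - slope * tc)
}

#' Initial period guess from the FFT periodogram
#'
#' Computes the discrete Fourier transform of the (detrended, uniformly
#' sampled) trace, zero-padded to `pad_factor` times its length to refine
#' the frequency grid, and returns the period of the non-DC bin with maximal
#' spectral magnitude within the plausible circadian band.
#'
#' @param trace A detrended trace tibble.
#' @param band Plausible period band in hours (default 16-36 h, slightly
#'   wider than the downstream quality-control bounds of 18-32 h so the
#'   estimator is not clipped before QC).
#' @param pad_factor Zero-padding factor; with a 120-h window the raw grid
#'   near 24 h is ~4.8 h coarse, 4x padding brings it near 1.2 h.
#' @return Initial period estimate `tau0` in hours.
#' @export
initial_period_fft <- function(trace, band = c(16, 36), pad_factor = 4) {
  assert_trace(trace)
  dt_h <- trace_interval_hr(trace$time_hr)
  y <- trace$value
  n <- length(y)
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    abort("trace is constant: all spectral mass at DC",
          class = "leaftrack_error_period")
  }
  n_pad <- as.integer(pad_factor * n)
  spec <- stats::fft(c(y, rep(0, n_pad - n)))
  k <- seq_len(floor(n_pad / 2))          # non-DC bins up to Nyquist
  freq <- k / (n_pad * dt_h)              # cycles per hour
  period <- 1 / freq
  in_band <- period >= band[1] & period <= band[2]
  if (!any(in_band)) {
    abort(paste0("no FFT bins inside the period band [", band[1], ", ",
                 band[2], "] h; the trace may be too short"),
          class = "leaftrack_error_period")
  }
  mag <- Mod(spec[k + 1])
  period[in_band][which.max(mag[in_band])]
}

# single-cosine model and its RMS misfit
cosine_model <- function(t, period, phase, amplitude, offset) {
  offset + amplitude * cos(2 * pi * t / period + phase)
}

cosine_rms <- function(par, t, y) {
  if (par[1] <= 0) return(.Machine$double.xmax)
  sqrt(mean((y - cosine_model(t, par[1], par[2], par[3], par[4]))^2))
}

#' Refine a period estimate by Nelder-Mead single-cosine fitting
#'
#' Minimizes the root-mean-square misfit of the model
#' \deqn{y(t) = c + A \cos(2\pi t / \tau + \phi)}
#' over \eqn{(\tau, \phi, A, c)} with Nelder-Mead, started at `tau0` with
#' phase and amplitude initialized from the complex Fourier coefficient of
#' the trace at frequency `1/tau0`. This is a single-frequency analogue of
#' FFT-NLLS rhythm fitting: the motion signal is clean enough that one
#' frequency suffices. The constant offset is retained even though
#' detrending centers the trace; it converges to ~0 and guards against
#' residual baseline.
#'
#' @param trace A detrended trace tibble.
#' @param tau0 Initial period, hours (from [initial_period_fft]).
#' @param reltol Relative convergence tolerance on the objective.
#' @param maxit Maximum Nelder-Mead iterations.
#' @return A `period_fit` object; see [tidy.period_fit].
#' @export
refine_fit <- function(trace, tau0, reltol = 1e-10, maxit = 2000) {
  assert_trace(trace)
  t <- trace$time_hr
  y <- trace$value
  n <- length(y)
  # complex Fourier coefficient at 1/tau0 on the actual time grid:
  # y ~ A cos(wt + phi)  =>  sum y e^{-iwt} ~ (n/2) A e^{i phi}
  co <- sum(y * exp(-2i * pi * t / tau0))
  a0 <- 2 * Mod(co) / n
  phi0 <- Arg(co)
  par0 <- c(tau0, phi0, a0, 0)
  rms0 <- cosine_rms(par0, t, y)
  opt <- stats::optim(par0, cosine_rms, t = t, y = y,
                      method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  par <- opt$par
  # canonical form: positive amplitude, phase in (-pi, pi]
  if (par[3] < 0) {
    par[3] <- -par[3]
    par[2] <- par[2] + pi
  }
  par[2] <- ((par[2] + pi) %% (2 * pi)) - pi
  structure(
    list(period_h = par[1], phase_rad = par[2], amplitude = par[3],
         offset = par[4], rms_error = opt$value,
         initial_rms_error = rms0, tau0_h = tau0,
         converged = opt$convergence == 0, n = n, trace = trace),
    class = "period_fit"
  )
}

#' Estimate circadian period from a motion trace
#'
#' The one-call estimator: linear detrend ([detrend_trace]), FFT periodogram
#' initial guess ([initial_period_fft]), Nelder-Mead single-cosine
#' refinement ([refine_fit]).
#'
#' @inheritParams initial_period_fft
#' @inheritParams refine_fit
#' @param value_col Column of `trace` holding the signal (default
#'   `"value"`; use `"v_y"` for the output of [track_stack]).
#' @return A `period_fit` object.
#' @examples
#' tr <- simulate_trace(24, trend = "I", noise = "A", seed = 42)
#' fit <- estimate_period(tr)
#' fit
#' generics::tidy(fit)
#' @export
estimate_period <- function(trace, band = c(16, 36), pad_factor = 4,
                            value_col = "value",
                            reltol = 1e-10, maxit = 2000) {
  if (!value_col %in% names(trace)) {
    abort(paste0("column ", sQuote(value_col), " not found in trace"),
          class = "leaftrack_error_period")
  }
  tr <- tibble(time_hr = trace$time_hr, value = trace[[value_col]])
  tr <- detrend_trace(tr)
  tau0 <- initial_period_fft(tr, band = band, pad_factor = pad_factor)
  refine_fit(tr, tau0, reltol = reltol, maxit = maxit)
}

#' Estimate periods for many plants at once
#'
#' Groups a long table of traces by plant, runs [estimate_period] on each,
#' and returns one tidy row per plant.
#'
#' @param traces A tibble with columns `plant_id`, `time_hr`, and the
#'   signal column.
#' @param value_col Signal column name (default `"v_y"`, the vertical
#'   motion series from [track_stack]).
#' @inheritParams estimate_period
#' @return A tibble with columns `plant_id`, `period_h`, `phase_rad`,
#'   `amplitude`, `offset`, `rms_error`, `tau0_h`, `converged`.
#' @export
estimate_periods <- function(traces, value_col = "v_y", band = c(16, 36),
                             pad_factor = 4) {
  if (!all(c("plant_id", "time_hr") %in% names(traces))) {
    abort("`traces` needs columns plant_id and time_hr",
          class = "leaftrack_error_period")
  }
  traces |>
    tidyr::nest(data = -"plant_id") |>
    mutate(fit = map(.data$data, function(d) {
      generics::tidy(estimate_period(d, band = band, pad_factor = pad_factor,
                                     value_col = value_col))
    })) |>
    select(-"data") |>
    tidyr::unnest("fit")
}

#' @export
print.period_fit <- function(x, ...) {
  cat("<period_fit> period ", format(x$period_h, digits = 6),
      " h (FFT start ", format(x$tau0_h, digits = 4),
      " h), amplitude ", format(x$amplitude, digits = 3),
      ", rms error ", format(x$rms_error, digits = 3),
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted single-cosine period model
#'
#' @param x A `period_fit`.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble of the fitted parameters. `glance()`:
#'   a one-row tibble of fit diagnostics.
#' @exportS3Method generics::tidy
#' @export
tidy.period_fit <- function(x, ...) {
  tibble(period_h = x$period_h, phase_rad = x$phase_rad,
         amplitude = x$amplitude, offset = x$offset,
         rms_error = x$rms_error, tau0_h = x$tau0_h,
         converged = x$converged)
}

#' @rdname tidy.period_fit
#' @exportS3Method generics::glance
#' @export
glance.period_fit <- function(x, ...) {
  tibble(rms_error = x$rms_error, initial_rms_error = x$initial_rms_error,
         n = x$n, converged = x$converged)
}

#' Plot a fitted period model over its trace
#'
#' @param object A `period_fit`.
#' @param ... Unused.
#' @return A ggplot: detrended trace points and fitted cosine line.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.period_fit <- function(object, ...) {
  tr <- object$trace
  grid <- tibble(
    time_hr = seq(min(tr$time_hr), max(tr$time_hr), length.out = 400)
  )
  grid$value <- cosine_model(grid$time_hr, object$period_h,
                             object$phase_rad, object$amplitude,
                             object$offset)
  ggplot2::ggplot(tr, ggplot2::aes(.data$time_hr, .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = grid, color = "#2166ac") +
    ggplot2::labs(
      x = "time (h)", y = "detrended motion",
      title = sprintf("fitted period %.2f h", object$period_h)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
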