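#' Amplitude-trend decay rates and noise scales for simulated traces
#'
#' The simulated validation traces use three amplitude trends (the per-sample
#' exponential decay rate of the signal envelope) and three noise levels (the
#' standard deviation of additive white Gaussian noise, in units of the
#' initial amplitude):
#'
#' * trends `I`, `II`, `III`: decay rates 0, 0.001, 0.002 per sample
#' * noise levels `A`, `B`, `C`: noise sd 0.2, 0.6, 1.0 x amplitude
#'
#' @format Named numeric vectors.
#' @name trace_design
NULL

#' @rdname trace_design
#' @export
trend_decay_rates <- c(I = 0, II = 0.001, III = 0.002)

#' @rdname trace_design
#' @export
noise_levels <- c(A = 0.2, B = 0.6, C = 1.0)

#' Simulate a noisy decaying cosine trace
#'
#' Generates one synthetic circadian trace
#' \deqn{y_i = e^{-r i} \cos(2\pi t_i / \tau) + \epsilon_i,}
#' where \eqn{r} is the per-sample decay rate of the amplitude trend,
#' \eqn{\tau} the true period in hours, and \eqn{\epsilon_i} iid Gaussian
#' noise with sd equal to the noise level times the initial (unit) amplitude.
#' Samples are taken at `t_i = i * sampling_interval` for
#' `i = 0, ..., n - 1` with `n = duration / sampling_interval`.
#'
#' The trace is deterministic given `(seed, replicate)`: replicate `k` draws
#' from its own RNG stream, so repeated simulation sets are reproducible
#' replicate-by-replicate.
#'
#' @param period_h True period in hours (> 0).
#' @param trend Amplitude trend, one of `"I"`, `"II"`, `"III"`
#'   (see [trend_decay_rates]), or a numeric decay rate per sample.
#' @param noise Noise level, one of `"A"`, `"B"`, `"C"` (see [noise_levels]),
#'   or a numeric noise sd in units of the initial amplitude.
#' @param sampling_interval_min Sampling interval in minutes (default 20).
#' @param duration_h Trace duration in hours (default 120); must cover at
#'   least two full periods.
#' @param seed Integer seed for the noise stream.
#' @param replicate Replicate index (>= 1); combined with `seed` to derive
#'   the RNG stream.
#' @return A tibble with columns `time_hr` and `value`.
#' @examples
#' tr <- simulate_trace(24, trend = "I", noise = "A", seed = 1)
#' head(tr)
#' @export
simulate_trace <- function(period_h, trend = "I", noise = "A",
                           sampling_interval_min = 20, duration_h = 120,
                           seed = 1, replicate = 1) {
  decay <- resolve_level(trend, trend_decay_rates, "trend")
  noise_sd <- resolve_level(noise, noise_levels, "noise")
  if (!is.numeric(period_h) || length(period_h) != 1 || period_h <= 0) {
    abort("`period_h` must be a single positive number",
          class = "leaftrack_error_spec")
  }
  if (sampling_interval_min <= 0) {
    abort("`sampling_interval_min` must be positive",
          class = "leaftrack_error_spec")
  }
  if (duration_h < 2 * period_h) {
    abort(
      paste0("`duration_h` (", duration_h, " h) must cover at least two ",
             "full periods (", 2 * period_h, " h): period estimation is ",
             "unreliable on shorter windows"),
      class = "leaftrack_error_spec"
    )
  }
  dt_h <- sampling_interval_min / 60
  n <- floor(duration_h / dt_h)
  if (n < 8) {
    abort("trace must have at least 8 samples", class = "leaftrack_error_spec")
  }
  i <- seq_len(n) - 1
  t_hr <- i * dt_h
  env <- exp(-decay * i)
  eps <- with_seed(replicate_seed(seed, replicate), rnorm(n, sd = noise_sd))
  tibble(time_hr = t_hr, value = env * cos(2 * pi * t_hr / period_h) + eps)
}

resolve_level <- function(x, table, what) {
  if (is.numeric(x) && length(x) == 1 && x >= 0) return(x)
  if (is.character(x) && length(x) == 1 && x %in% names(table)) {
    return(unname(table[[x]]))
  }
  abort(paste0("invalid ", what, " level: must be one of ",
               paste(sQuote(names(table)), collapse = ", "),
               " or a non-negative number"),
        class = "leaftrack_error_spec")
}

#' Simulate a full factorial grid of replicate traces
#'
#' Expands the factorial design of true periods x amplitude trends x noise
#' levels, with `n_replicates` independent traces per condition, and returns
#' one row per trace with the trace itself in a list column. The default
#' arguments reproduce the validation design used throughout the package:
#' periods 20-28 h, trends I-III, noise levels A-C, 10 replicates, 20-min
#' sampling over 120 h.
#'
#' @param periods_h Numeric vector of true periods in hours.
#' @param trends Character vector of amplitude trends.
#' @param noises Character vector of noise levels.
#' @param n_replicates Replicates per condition.
#' @inheritParams simulate_trace
#' @return A tibble with columns `period_h`, `trend`, `noise`, `replicate`,
#'   and a list column `trace` of tibbles.
#' @examples
#' grid <- simulate_trace_grid(periods_h = 24, n_replicates = 2, seed = 1)
#' grid
#' @export
simulate_trace_grid <- function(periods_h = 20:28,
                                trends = c("I", "II", "III"),
                                noises = c("A", "B", "C"),
                                n_replicates = 10,
                                sampling_interval_min = 20,
                                duration_h = 120,
                                seed = 1) {
  design <- tidyr::expand_grid(
    period_h = periods_h, trend = trends, noise = noises,
    replicate = seq_len(n_replicates)
  )
  # every (condition, replicate) cell gets its own stream so conditions are
  # independent and the set is reproducible cell-by-cell
  design$cell <- seq_len(nrow(design))
  design$trace <- pmap(
    design[c("period_h", "trend", "noise", "cell")],
    function(period_h, trend, noise, cell) {
      simulate_trace(period_h, trend, noise,
                     sampling_interval_min = sampling_interval_min,
                     duration_h = duration_h,
                     seed = seed, replicate = cell)
    }
  )
  design$cell <- NULL
  design
}

#' Read and write trace CSV files
#'
#' Traces are stored as two-column CSV (`time_hours`, `value`) with a
#' one-line header.
#'
#' @param trace A trace tibble (`time_hr`, `value`).
#' @param path File path.
#' @return `read_trace()` returns a trace tibble; `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  assert_trace(trace)
  out <- data.frame(time_hours = trace$time_hr, value = trace$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  time_col <- intersect(c("time_hours", "time_hr", "time"), names(df))[1]
  if (is.na(time_col) || !"value" %in% names(df)) {
    abort(paste0("not a trace CSV (need columns time_hours,value): ", path),
          class = "leaftrack_error_io")
  }
  tibble(time_hr = as.numeric(df[[time_col]]), value = as.numeric(df$value))
}
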