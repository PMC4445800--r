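#' @importFrom rlang abort .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate select bind_rows
#' @importFrom purrr map pmap imap walk
NULL

# uniform sampling interval of a trace, in hours; errors if the grid is not
# (numerically) uniform
trace_interval_hr <- function(time_hr, tol = 1e-8) {
  if (length(time_hr) < 2) {
    abort("trace must have at least 2 samples", class = "leaftrack_error_trace")
  }
  dt <- diff(time_hr)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > tol * max(dt[1], 1)) {
    abort("trace times must be strictly increasing with a uniform step",
          class = "leaftrack_error_trace")
  }
  dt[1]
}

assert_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time_hr", "value") %in% names(trace))) {
    abort("a trace is a data frame with columns `time_hr` and `value`",
          class = "leaftrack_error_trace")
  }
  if (!all(is.finite(trace$value))) {
    abort("trace values must be finite", class = "leaftrack_error_trace")
  }
  invisible(trace)
}

# deterministic per-replicate RNG stream: a small integer seed derived from
# (seed, replicate), kept within the 32-bit integer range
replicate_seed <- function(seed, replicate) {
  s <- (abs(as.double(seed)) %% 1e6) * 2039 + as.double(replicate) * 130003
  as.integer(s %% 2147483647)
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
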