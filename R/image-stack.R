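#' Ordered grayscale image stacks
#'
#' An `image_stack` holds an ordered sequence of grayscale frames (numeric
#' matrices with values in \[0, 1\], rows = image y growing downward,
#' columns = image x growing rightward) together with the sampling interval
#' of the time-lapse and per-frame provenance.
#'
#' @param frames List of numeric matrices, all of identical dimensions.
#' @param sampling_interval_min Sampling interval between frames, in minutes.
#' @param source_ids Optional character vector of per-frame identifiers
#'   (typically source filenames).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, sampling_interval_min, source_ids = NULL) {
  if (!is.list(frames) || length(frames) == 0) {
    abort("`frames` must be a non-empty list of matrices",
          class = "leaftrack_error_stack")
  }
  dims <- dim(frames[[1]])
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || !is.numeric(f)) {
      abort(paste0("frame ", k, " is not a numeric matrix"),
            class = "leaftrack_error_stack")
    }
    if (!identical(dim(f), dims)) {
      abort(paste0("frame dimensions differ: frame ", k, " is ",
                   nrow(f), "x", ncol(f), " but frame 1 is ",
                   dims[1], "x", dims[2]),
            class = "leaftrack_error_stack")
    }
  }
  if (!is.numeric(sampling_interval_min) || sampling_interval_min <= 0) {
    abort("`sampling_interval_min` must be positive",
          class = "leaftrack_error_stack")
  }
  if (is.null(source_ids)) {
    source_ids <- sprintf("frame_%03d", seq_along(frames) - 1)
  }
  structure(
    list(frames = frames,
         sampling_interval_min = sampling_interval_min,
         source_ids = as.character(source_ids)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("<image_stack> ", length(x$frames), " frames of ", d[1], "x", d[2],
      " px, ", x$sampling_interval_min, "-min interval\n", sep = "")
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Frame timestamps of a stack, in hours
#'
#' @param stack An [image_stack].
#' @return Numeric vector, hours since the first frame.
#' @export
stack_times_hr <- function(stack) {
  (seq_along(stack$frames) - 1) * stack$sampling_interval_min / 60
}
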