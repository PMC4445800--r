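#' Load a directory of time-lapse frames as an image stack
#'
#' Reads every PNG/JPEG in `directory` in sorted-filename order (filenames
#' must sort chronologically, e.g. zero-padded frame numbers), converts to
#' grayscale (luminance weights 0.299/0.587/0.114 for RGB input), and
#' normalizes intensities to \[0, 1\].
#'
#' @param directory Directory containing >= 2 frames of identical size.
#' @param sampling_interval_min Sampling interval in minutes. The imaging
#'   rig, not the image files, defines this, so it must be given.
#' @return An [image_stack].
#' @export
load_stack <- function(directory, sampling_interval_min) {
  if (!dir.exists(directory)) {
    abort(paste0("directory not found: ", directory),
          class = "leaftrack_error_io")
  }
  files <- list.files(directory, pattern = "\\.(png|jpe?g)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  if (length(files) < 2) {
    abort(paste0("need at least 2 frames, found ", length(files),
                 " in ", directory),
          class = "leaftrack_error_io")
  }
  frames <- vector("list", length(files))
  for (k in seq_along(files)) {
    frames[[k]] <- read_frame(files[k])
    if (k > 1 && !identical(dim(frames[[k]]), dim(frames[[1]]))) {
      abort(paste0("frame dimensions differ: ", basename(files[k]), " is ",
                   nrow(frames[[k]]), "x", ncol(frames[[k]]),
                   " but ", basename(files[1]), " is ",
                   nrow(frames[[1]]), "x", ncol(frames[[1]])),
            class = "leaftrack_error_stack")
    }
  }
  image_stack(frames, sampling_interval_min, source_ids = basename(files))
}

read_frame <- function(path) {
  img <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      png::readPNG(path)
    } else {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        abort("the jpeg package is required to read JPEG frames",
              class = "leaftrack_error_io")
      }
      jpeg::readJPEG(path)
    }
  }, error = function(e) {
    abort(paste0("could not read frame ", basename(path), ": ",
                 conditionMessage(e)),
          class = "leaftrack_error_io")
  })
  to_gray(img)
}

# grayscale in [0,1]; rows = y (down), cols = x (right)
to_gray <- function(img) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Read and write a crop-grid specification
#'
#' A grid is a CSV with header `plant_id,x_min,y_min,width,height` giving one
#' rectangle per plant in 0-based pixel coordinates (x right, y down);
#' rectangles are half-open: `[x_min, x_min + width) x [y_min, y_min +
#' height)`. Draw cells against both the first and last frame of a series so
#' the plant stays inside its cell as it grows.
#'
#' @param path CSV file path.
#' @param grid A grid tibble.
#' @return `read_grid()` returns a tibble with the five grid columns.
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "x_min", "y_min", "width", "height")
  if (!all(need %in% names(df))) {
    abort(paste0("grid CSV must have columns ",
                 paste(need, collapse = ","), ": ", path),
          class = "leaftrack_error_io")
  }
  as_tibble(df[need])
}

#' @rdname read_grid
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Crop an image stack into per-plant sub-stacks
#'
#' Applies each grid rectangle to every frame, producing one sub-stack per
#' plant. Crops are pixel-exact: each sub-frame is the untouched rectangle of
#' the parent frame, with the parent's frame count and sampling interval.
#'
#' @param stack An [image_stack].
#' @param grid Grid tibble (`plant_id,x_min,y_min,width,height`; see
#'   [read_grid]) in 0-based half-open pixel coordinates.
#' @param min_pixels Minimum rectangle area in pixels; the default 10000
#'   (100 x 100) is the minimum per-plant footprint the imaging protocol
#'   recommends for reliable motion estimation.
#' @return A named list of [image_stack] objects, one per `plant_id`.
#' @export
crop_stack <- function(stack, grid, min_pixels = 10000) {
  stopifnot(inherits(stack, "image_stack"))
  need <- c("plant_id", "x_min", "y_min", "width", "height")
  if (!is.data.frame(grid) || !all(need %in% names(grid))) {
    abort("`grid` must have columns plant_id,x_min,y_min,width,height",
          class = "leaftrack_error_grid")
  }
  if (anyDuplicated(grid$plant_id)) {
    abort("grid plant_ids must be unique", class = "leaftrack_error_grid")
  }
  nr <- nrow(stack$frames[[1]])
  nc <- ncol(stack$frames[[1]])
  out <- vector("list", nrow(grid))
  names(out) <- grid$plant_id
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    if (g$width <= 0 || g$height <= 0 || g$x_min < 0 || g$y_min < 0 ||
        g$x_min + g$width > nc || g$y_min + g$height > nr) {
      abort(paste0("grid cell for plant ", sQuote(g$plant_id),
                   " lies outside the ", nr, "x", nc, " frame: [",
                   g$x_min, ", ", g$x_min + g$width, ") x [",
                   g$y_min, ", ", g$y_min + g$height, ")"),
            class = "leaftrack_error_grid")
    }
    if (g$width * g$height < min_pixels) {
      abort(paste0("grid cell for plant ", sQuote(g$plant_id), " has ",
                   g$width * g$height, " px, below the minimum of ",
                   min_pixels, " (set `min_pixels` to override)"),
            class = "leaftrack_error_grid")
    }
    rows <- (g$y_min + 1):(g$y_min + g$height)
    cols <- (g$x_min + 1):(g$x_min + g$width)
    out[[k]] <- image_stack(
      lapply(stack$frames, function(f) f[rows, cols, drop = FALSE]),
      stack$sampling_interval_min,
      source_ids = stack$source_ids
    )
  }
  out
}
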