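#' Read a raster image from disk
#'
#' Reads a PNG, TIFF or JPEG file into a numeric pixel array with intensities
#' in \[0, 1\]. Grayscale files yield an `H x W` matrix, colour files an
#' `H x W x C` array. Alpha channels are dropped.
#'
#' @param path Path to a PNG, TIFF or JPEG file (extension decides the codec).
#' @return A numeric array of class `raster_image` with attribute
#'   `source_path`.
#' @seealso [to_grayscale()], [vectorize()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read image: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      stop("unsupported image format '.", ext, "' for ", path, call. = FALSE)
    ),
    error = function(e) {
      stop("failed to decode image ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(dim(px)) == 3L && dim(px)[3L] %in% c(2L, 4L)) {
    # drop alpha (last channel); 2-channel = gray+alpha
    px <- px[, , seq_len(dim(px)[3L] - 1L), drop = (dim(px)[3L] == 2L)]
  }
  new_raster_image(px, path)
}

new_raster_image <- function(pixels, source_path = NA_character_) {
  d <- dim(pixels)
  if (is.null(d) || length(d) < 2L || d[1L] < 2L || d[2L] < 2L) {
    stop("raster image must be at least 2x2", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("raster image contains non-finite intensities", call. = FALSE)
  }
  structure(pixels, source_path = source_path, class = "raster_image")
}

n_channels <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) 1L else d[3L]
}

#' Convert a raster image to grayscale
#'
#' Colour (3-channel) images are combined with the ITU-R BT.601 luma weights
#' (0.2989, 0.5870, 0.1140); single-channel images pass through unchanged.
#' Intensities are kept as real numbers (no re-quantization).
#'
#' @param img A `raster_image` (from [load_image()]) or a numeric matrix /
#'   `H x W x 3` array.
#' @return An `M x N` numeric matrix (class `gray_image`).
#' @export
to_grayscale <- function(img) {
  d <- dim(img)
  C <- n_channels(img)
  if (!C %in% c(1L, 3L)) {
    stop("unsupported channel count ", C, ": expected 1 (gray) or 3 (RGB)",
         call. = FALSE)
  }
  g <- if (C == 1L) {
    if (length(d) == 3L) img[, , 1L] else unclass(img)
  } else {
    0.2989 * img[, , 1L] + 0.5870 * img[, , 2L] + 0.1140 * img[, , 3L]
  }
  g <- matrix(as.numeric(g), nrow = d[1L], ncol = d[2L])
  structure(g, source_path = attr(img, "source_path"), class = "gray_image")
}

# 1-D resampling helper along the rows of `x` (columns handled by transpose).
# Upsizing: linear interpolation at output-pixel centres mapped into input
# coordinates. Downsizing: area (box) averaging, i.e. antialiased.
resample_rows <- function(x, target) {
  n <- nrow(x)
  if (target == n) return(x)
  if (target < n) {
    scale <- n / target
    out <- matrix(0, target, ncol(x))
    for (i in seq_len(target)) {
      lo <- (i - 1) * scale
      hi <- i * scale
      j0 <- floor(lo) + 1L
      j1 <- ceiling(hi)
      w <- rep(1, j1 - j0 + 1L)
      w[1L] <- j0 - lo               # fractional coverage of first source row
      w[length(w)] <- 1 - (j1 - hi)  # and of the last
      if (length(w) == 1L) w <- hi - lo
      out[i, ] <- crossprod(w, x[j0:j1, , drop = FALSE]) / (hi - lo)
    }
    out
  } else {
    scale <- n / target
    src <- (seq_len(target) - 0.5) * scale + 0.5
    src <- pmin(pmax(src, 1), n)
    j0 <- pmin(floor(src), n - 1L)
    frac <- src - j0
    x[j0, , drop = FALSE] * (1 - frac) + x[j0 + 1L, , drop = FALSE] * frac
  }
}

#' Resize a grayscale image
#'
#' Separable resampling: linear interpolation when enlarging a dimension and
#' area averaging (an antialiasing box filter) when shrinking it. A constant
#' image stays constant and resizing to the original shape is the identity.
#'
#' @param img An `M x N` numeric matrix (e.g. from [to_grayscale()]).
#' @param rows,cols Target dimensions (integers >= 2).
#' @return The resized matrix (class `gray_image`).
#' @export
resize_image <- function(img, rows, cols) {
  if (rows < 2L || cols < 2L) {
    stop("target dimensions must be at least 2x2", call. = FALSE)
  }
  x <- unclass(img)
  x <- resample_rows(x, as.integer(rows))
  x <- t(resample_rows(t(x), as.integer(cols)))
  structure(x, source_path = attr(img, "source_path"), class = "gray_image")
}

#' Vectorize an image into a time series
#'
#' Stacks the columns of an `M x N` grayscale image on top of one another
#' (column-major order: down the first column, then the second, ...), giving a
#' length-`MN` series treated as a signal with nominal sampling frequency
#' `fs`. The sampling frequency carries no physical meaning for images; it
#' fixes the frequency axis of the time-frequency features.
#'
#' @param img An `M x N` numeric matrix.
#' @param fs Nominal sampling frequency in Hz (default 300).
#' @return A `signal_series` object: list with `values`, `fs` and the source
#'   image dimensions `dim`.
#' @export
vectorize <- function(img, fs = 300) {
  x <- unclass(img)
  if (!is.matrix(x)) stop("vectorize() expects a 2-D grayscale matrix",
                          call. = FALSE)
  signal_series(as.vector(x), fs = fs, dim = dim(x),
                source = attr(img, "source_path"))
}

#' Construct a signal series
#'
#' @param values Numeric vector of samples.
#' @param fs Sampling frequency in Hz (> 0).
#' @param dim Optional `c(M, N)` dimensions of the source image.
#' @param source Optional source path or id.
#' @return A `signal_series` object.
#' @export
signal_series <- function(values, fs = 300, dim = NULL, source = NULL) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("series contains non-finite values",
                                    call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive number", call. = FALSE)
  }
  structure(list(values = values, fs = fs, dim = dim, source = source),
            class = "signal_series")
}

#' @export
print.signal_series <- function(x, ...) {
  cat("signal series: ", length(x$values), " samples, fs = ", x$fs, " Hz",
      if (!is.null(x$dim)) paste0(" (from ", x$dim[1L], "x", x$dim[2L],
                                  " image)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.signal_series <- function(x) length(x$values)

#' Write a signal series to CSV
#'
#' Writes a single-column CSV (header `value`) and a sidecar JSON with the
#' sampling frequency, source and image dimensions.
#'
#' @param series A `signal_series`.
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(data.frame(value = series$values), path, row.names = FALSE)
  meta <- list(fs = series$fs,
               source = if (is.null(series$source)) NA else series$source,
               M = if (is.null(series$dim)) NA else series$dim[1L],
               N = if (is.null(series$dim)) NA else series$dim[2L])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
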