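# Synthetic texture images with controllable, class-separating spectral
# structure. They stand in for tissue textures in tests and examples: a
# grating whose rows oscillate with a chosen period yields, after
# column-major vectorization, a near-sinusoidal series whose dominant
# frequency is fs / period — directly measurable by the time-frequency
# features.

#' Synthetic sinusoidal grating image
#'
#' `I[m, n] = 0.5 + 0.4 sin(2 pi m / period + phase) + noise`, clipped to
#' `[0, 1]`. The pattern varies along rows only, so the column-stacked series
#' is periodic with period `period` samples; at sampling frequency `fs` its
#' dominant frequency is `fs / period` Hz.
#'
#' @param size Image side length in pixels (square image, `>= period`).
#' @param period Spatial period in pixels (>= 2).
#' @param phase Phase offset in radians (default 0).
#' @param noise_sd Standard deviation of additive Gaussian noise (default 0).
#' @param seed Optional seed for the noise (deterministic when given).
#' @return A `size x size` matrix of class `gray_image` in `[0, 1]`.
#' @export
generate_grating <- function(size, period, phase = 0, noise_sd = 0,
                             seed = NULL) {
  if (period < 2 || size < period) {
    stop("need size >= period >= 2", call. = FALSE)
  }
  base <- matrix(0.5 + 0.4 * sin(2 * pi * seq_len(size) / period + phase),
                 nrow = size, ncol = size)
  img <- add_noise(base, noise_sd, seed)
  structure(img, class = "gray_image")
}

#' Synthetic checkerboard image
#'
#' Alternating blocks of side `period` pixels at intensities 0.1 and 0.9,
#' plus optional Gaussian noise, clipped to `[0, 1]`.
#'
#' @inheritParams generate_grating
#' @return A `size x size` matrix of class `gray_image`.
#' @export
generate_checker <- function(size, period, noise_sd = 0, seed = NULL) {
  if (period < 2 || size < period) {
    stop("need size >= period >= 2", call. = FALSE)
  }
  blk <- ((seq_len(size) - 1L) %/% period)
  base <- 0.1 + 0.8 * ((outer(blk, blk, `+`)) %% 2L)
  img <- add_noise(base, noise_sd, seed)
  structure(img, class = "gray_image")
}

add_noise <- function(base, noise_sd, seed) {
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) {
      stats::rnorm(length(base), 0, noise_sd)
    } else {
      withr::with_seed(as.integer(seed),
                       stats::rnorm(length(base), 0, noise_sd))
    }
    base <- base + matrix(eps, nrow(base), ncol(base))
  }
  pmin(pmax(base, 0), 1)
}

#' Synthetic Gaussian random field image
#'
#' Frequency-domain synthesis: complex white noise is filtered with an
#' isotropic amplitude `|k|^(-exponent/2)` and transformed back; the real
#' part is rescaled to `[0, 1]`. Exponent 0 gives white noise (flat
#' spectrum, maximal spectral entropy); larger exponents concentrate power
#' at low spatial frequencies and give smoother textures.
#'
#' @param size Image side length (>= 8).
#' @param spectral_exponent Power-law exponent of the power spectrum
#'   (>= 0; amplitude falls as `|k|^(-exponent/2)`).
#' @param seed Seed for the random phases.
#' @return A `size x size` matrix of class `gray_image`.
#' @export
generate_gaussian_field <- function(size, spectral_exponent, seed = 1L) {
  if (size < 8L) stop("size must be >= 8", call. = FALSE)
  k <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  kk <- sqrt(outer(k^2, k^2, `+`))
  amp <- ifelse(kk > 0, kk^(-spectral_exponent / 2), 0)
  z <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(size^2), size, size) +
      1i * matrix(stats::rnorm(size^2), size, size)
  })
  field <- Re(stats::fft(z * amp, inverse = TRUE)) / size
  rng <- range(field)
  if (rng[2] > rng[1]) field <- (field - rng[1]) / (rng[2] - rng[1])
  structure(field, class = "gray_image")
}

#' Texture class specification
#'
#' @param kind One of `"grating"`, `"gaussian_field"`, `"checker"`.
#' @param label Class label (unique across specs).
#' @param period Dominant spatial period in pixels (grating/checker; >= 2).
#' @param spectral_exponent Spectral power-law exponent (gaussian_field).
#' @param noise_sd Additive noise standard deviation (default 0.05).
#' @return A `texture_class_spec` list.
#' @export
texture_class_spec <- function(kind = c("grating", "gaussian_field",
                                        "checker"),
                               label, period = NULL,
                               spectral_exponent = NULL, noise_sd = 0.05) {
  kind <- match.arg(kind)
  if (kind %in% c("grating", "checker")) {
    if (is.null(period) || period < 2) stop("period must be >= 2",
                                            call. = FALSE)
  } else if (is.null(spectral_exponent)) {
    stop("gaussian_field specs need a spectral_exponent", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(kind = kind, label = label, period = period,
                 spectral_exponent = spectral_exponent,
                 noise_sd = noise_sd),
            class = "texture_class_spec")
}

#' Default two-class texture specification
#'
#' Two noisy gratings with well-separated dominant periods (6 and 16 px):
#' at fs = 300 Hz their vectorized series have dominant frequencies of 50 and
#' 18.75 Hz, so the class-conditional distributions of mean instantaneous
#' frequency do not overlap.
#'
#' @param noise_sd Additive noise level (default 0.05).
#' @return List of two `texture_class_spec` objects.
#' @export
default_two_class_specs <- function(noise_sd = 0.05) {
  list(texture_class_spec("grating", label = "coarse", period = 16,
                          noise_sd = noise_sd),
       texture_class_spec("grating", label = "fine", period = 6,
                          noise_sd = noise_sd))
}

#' Generate a labeled synthetic texture dataset
#'
#' Draws `n_per_class` images per class spec (optionally imbalanced), with a
#' per-image jittered phase and an independently derived sub-seed per image,
#' so the dataset is fully deterministic given `seed` at every granularity.
#'
#' @param specs List of [texture_class_spec()] objects (>= 2, unique labels).
#' @param n_per_class Images per class, either a single count or one count
#'   per spec (to exercise class imbalance).
#' @param size Image side length in pixels (default 64).
#' @param seed Master seed.
#' @return A `synthetic_dataset`: list with `images` (list of `gray_image`),
#'   `labels` (factor), `seeds` (per-image sub-seeds), `specs`, `seed`.
#' @export
generate_dataset <- function(specs, n_per_class, size = 64L, seed = 1L) {
  if (length(specs) < 2L) stop("need at least 2 class specs", call. = FALSE)
  labels <- vapply(specs, function(s) as.character(s$label), character(1L))
  if (anyDuplicated(labels)) stop("class labels must be unique",
                                  call. = FALSE)
  n_per_class <- rep_len(as.integer(n_per_class), length(specs))
  if (any(n_per_class < 1L)) stop("n_per_class must be >= 1", call. = FALSE)
  total <- sum(n_per_class)
  draws <- withr::with_seed(as.integer(seed), {
    list(sub_seeds = sample.int(.Machine$integer.max %/% 2L, total),
         phases = stats::runif(total, 0, 2 * pi))
  })
  images <- vector("list", total)
  out_labels <- character(total)
  i <- 0L
  for (s in seq_along(specs)) {
    sp <- specs[[s]]
    for (j in seq_len(n_per_class[s])) {
      i <- i + 1L
      images[[i]] <- switch(sp$kind,
        grating = generate_grating(size, sp$period, phase = draws$phases[i],
                                   noise_sd = sp$noise_sd,
                                   seed = draws$sub_seeds[i]),
        checker = generate_checker(size, sp$period, noise_sd = sp$noise_sd,
                                   seed = draws$sub_seeds[i]),
        gaussian_field = generate_gaussian_field(
          size, sp$spectral_exponent, seed = draws$sub_seeds[i])
      )
      out_labels[i] <- labels[s]
    }
  }
  structure(list(images = images, labels = factor(out_labels,
                                                  levels = labels),
                 seeds = draws$sub_seeds, specs = specs,
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic texture dataset: ", length(x$images), " images (",
      nrow(x$images[[1L]]), "x", ncol(x$images[[1L]]), "), classes: ",
      paste(sprintf("%s (n=%d)", levels(x$labels), table(x$labels)),
            collapse = ", "),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `DIR/<class>/<idx>.png` (8-bit grayscale) plus a `manifest.csv`
#' with columns `path`, `label`, `seed`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(ds$images))
  counter <- stats::setNames(rep(0L, nlevels(ds$labels)), levels(ds$labels))
  for (i in seq_along(ds$images)) {
    cl <- as.character(ds$labels[i])
    dir.create(file.path(dir, cl), showWarnings = FALSE)
    counter[cl] <- counter[cl] + 1L
    paths[i] <- file.path(cl, sprintf("%04d.png", counter[cl]))
    png::writePNG(unclass(ds$images[[i]]), file.path(dir, paths[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(path = paths, label = as.character(ds$labels),
                              seed = ds$seeds),
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' Extract feature sequences for a whole dataset
#'
#' Applies [image_features()] to every image of a `synthetic_dataset` or to
#' every file listed in a directory's `manifest.csv` (as written by
#' [write_dataset()]).
#'
#' @param x A `synthetic_dataset` or a directory containing `manifest.csv`.
#' @param ... Passed to [image_features()] (`fs`, `window_len`, ...).
#' @return List of labeled `feature_sequence` objects with a `labels`
#'   attribute (factor).
#' @export
dataset_features <- function(x, ...) {
  if (inherits(x, "synthetic_dataset")) {
    feats <- mapply(function(img, lab) image_features(img, label = lab, ...),
                    x$images, as.character(x$labels), SIMPLIFY = FALSE)
    labels <- x$labels
  } else {
    manifest <- utils::read.csv(file.path(x, "manifest.csv"),
                                stringsAsFactors = FALSE)
    feats <- mapply(function(p, lab)
      image_features(file.path(x, p), label = lab, ...),
      manifest$path, manifest$label, SIMPLIFY = FALSE)
    labels <- factor(manifest$label)
  }
  names(feats) <- NULL
  attr(feats, "labels") <- labels
  feats
}
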