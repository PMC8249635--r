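#' Construct a feature sequence
#'
#' A `T x 4` matrix of per-frame features in the fixed channel order
#' `if_hz`, `se`, `frie`, `fre`, with an optional class label and source id.
#'
#' @param channels `T x 4` numeric matrix (columns IF, SE, FRIE, FRE).
#' @param label Class label (any scalar; `NA` for unlabeled).
#' @param source_id Free-text identifier of the source image.
#' @return A `feature_sequence` (matrix with attributes `label`,
#'   `source_id`).
#' @export
feature_sequence <- function(channels, label = NA, source_id = NA_character_) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 4L) stop("feature sequences have 4 channels",
                                 call. = FALSE)
  if (nrow(channels) < 1L || !all(is.finite(channels))) {
    stop("feature sequence must be non-empty and finite", call. = FALSE)
  }
  colnames(channels) <- c("if_hz", "se", "frie", "fre")
  structure(channels, label = label, source_id = source_id,
            class = c("feature_sequence", "matrix"))
}

#' Combine time-frequency and time-space sequences
#'
#' Binds the IF/SE and FRIE/FRE sequences of one image into the `T x 4`
#' classifier input. Both parts must have been computed with the same `T`
#' (the time-space extraction is segmented to the TF length precisely so this
#' holds).
#'
#' @param tf A `tf_sequence`.
#' @param ts A `ts_sequence`.
#' @param label,source_id Passed to [feature_sequence()].
#' @return A `feature_sequence`.
#' @export
assemble_features <- function(tf, ts, label = NA, source_id = NA_character_) {
  stopifnot(inherits(tf, "tf_sequence"), inherits(ts, "ts_sequence"))
  if (length(tf$if_hz) != length(ts$frie)) {
    stop("internal inconsistency: TF length ", length(tf$if_hz),
         " != TS length ", length(ts$frie), call. = FALSE)
  }
  feature_sequence(cbind(tf$if_hz, tf$se, ts$frie, ts$fre),
                   label = label, source_id = source_id)
}

#' Extract the full feature sequence of one image
#'
#' Runs the whole per-image pipeline: (optional read and resize) ->
#' grayscale -> column-stack vectorization -> spectrogram-based IF and SE ->
#' segmented fuzzy-recurrence FRIE and FRE -> `T x 4` feature sequence.
#'
#' @param img A file path, a `raster_image`, or a numeric matrix / array.
#' @param fs Nominal sampling frequency in Hz (default 300).
#' @param window_len,hop_len Spectrogram framing (defaults 128 and 64).
#' @param m,tau,c,L Time-space settings (defaults 1, 1, 3, 256); see
#'   [ts_sequence()].
#' @param resize Optional `c(rows, cols)` to resize to before vectorization.
#' @param label Optional class label to attach.
#' @return A `feature_sequence`.
#' @export
image_features <- function(img, fs = 300, window_len = 128,
                           hop_len = window_len %/% 2, m = 1L, tau = 1L,
                           c = 3L, L = 256L, resize = NULL, label = NA) {
  src <- NA_character_
  if (is.character(img)) {
    src <- img
    img <- load_image(img)
  } else if (!is.null(attr(img, "source_path"))) {
    src <- attr(img, "source_path")
  }
  g <- if (is.matrix(img) && !inherits(img, "raster_image")) {
    structure(unclass(img), class = "gray_image")
  } else {
    to_grayscale(img)
  }
  if (!is.null(resize)) g <- resize_image(g, resize[1L], resize[2L])
  series <- vectorize(g, fs = fs)
  tf <- tf_sequence(series, window_len = window_len, hop_len = hop_len)
  ts <- ts_sequence(series, n_segments = length(tf$if_hz), m = m, tau = tau,
                    c = c, L = L)
  assemble_features(tf, ts, label = label, source_id = src)
}

#' Fit a per-channel standardizer on training feature sequences
#'
#' Pools all time steps of all training sequences and computes a mean and a
#' (population) standard deviation per channel; applying the standardizer
#' maps `x` to `(x - mean) / sd`. Standard deviations are floored at 1e-8 so
#' constant channels standardize to zero rather than NaN. Fit on the training
#' split only; the fitted statistics are then reused for test data.
#'
#' @param train List of `feature_sequence` objects (or `T x 4` matrices).
#' @return A `feature_standardizer`: list with `mean` and `sd` (length-4).
#' @export
fit_standardizer <- function(train) {
  if (inherits(train, "feature_sequence")) train <- list(train)
  if (length(train) == 0L) stop("empty training set", call. = FALSE)
  all <- do.call(rbind, lapply(train, unclass))
  mu <- colMeans(all)
  sd <- sqrt(colMeans(sweep(all, 2L, mu)^2))
  structure(list(mean = mu, sd = pmax(sd, 1e-8)),
            class = "feature_standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std A `feature_standardizer` from [fit_standardizer()].
#' @param x A `feature_sequence` / `T x 4` matrix, or a list of them.
#' @return Standardized matrix (or list), attributes preserved.
#' @export
apply_standardizer <- function(std, x) {
  stopifnot(inherits(std, "feature_standardizer"))
  if (is.list(x) && !is.matrix(x)) return(lapply(x, apply_standardizer,
                                                 std = std))
  out <- sweep(sweep(unclass(x), 2L, std$mean), 2L, std$sd, `/`)
  attributes(out)[c("label", "source_id")] <-
    attributes(x)[c("label", "source_id")]
  class(out) <- class(x)
  out
}

#' Build a class-modeling training set
#'
#' Implements the one-class-flavoured training-set construction: the network
#' learns all training samples of a designated target class, while every
#' other class is represented by a single donor sample replicated to match
#' (by default) the target-class count. Replicating one sample per competing
#' class both balances the set and concentrates learning on the target class.
#'
#' @param features List of `feature_sequence` objects (the training split).
#' @param labels Vector/factor of class labels, parallel to `features`.
#' @param target_class The class to model (must occur in `labels`).
#' @param donor_index Optional named integer vector mapping each other class
#'   to the index (within that class's training samples) of its donor;
#'   default 1 (the first sample of the class in `features` order).
#' @param replication Copies of each donor (default: target-class count).
#' @return List with `features` (list) and `labels` (factor): all target
#'   samples followed by the replicated donors, labels preserved.
#' @export
build_class_modeling_set <- function(features, labels, target_class,
                                     donor_index = NULL, replication = NULL) {
  labels <- as.factor(labels)
  if (length(features) != length(labels)) {
    stop("features and labels differ in length", call. = FALSE)
  }
  if (!target_class %in% levels(labels)) {
    stop("target class '", target_class, "' not present", call. = FALSE)
  }
  tgt <- which(labels == target_class)
  if (length(tgt) == 0L) stop("no training samples of the target class",
                              call. = FALSE)
  others <- setdiff(levels(labels), as.character(target_class))
  if (is.null(replication)) replication <- length(tgt)
  out_feats <- features[tgt]
  out_labels <- rep(as.character(target_class), length(tgt))
  for (cl in others) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) stop("class '", cl, "' has no training samples",
                                call. = FALSE)
    di <- if (!is.null(donor_index) && cl %in% names(donor_index)) {
      donor_index[[cl]]
    } else 1L
    donor <- features[[idx[di]]]
    out_feats <- c(out_feats, rep(list(donor), replication))
    out_labels <- c(out_labels, rep(cl, replication))
  }
  list(features = out_feats,
       labels = factor(out_labels, levels = levels(labels)))
}
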