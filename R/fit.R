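#' Fit a bidirectional LSTM sequence classifier
#'
#' Trains a bidirectional long short-term memory network on a set of labeled
#' feature sequences (typically the `T x 4` IF/SE/FRIE/FRE sequences from
#' [image_features()], usually after [build_class_modeling_set()]). The
#' network has `hidden_size` units per direction, reads each sequence forward
#' and backward, concatenates the two final hidden states and classifies them
#' through a dense layer with softmax. Training minimizes cross-entropy with
#' Adam (adaptive moment estimation), an L2 penalty on the weight matrices,
#' global gradient-norm clipping, and per-epoch reshuffled minibatches. A
#' per-channel standardizer is fitted on `x` and stored with the model, so
#' prediction standardizes new data with the training statistics.
#'
#' Defaults follow the large-data study configuration: 100 hidden units,
#' learning rate 0.01, gradient threshold 1, minibatch 150 (capped at the
#' training-set size), 80 epochs for two classes and 180 for more. Training
#' stops early once the mean epoch loss falls below `loss_tol`; set
#' `loss_tol = 0` to always run the full epoch count.
#'
#' @param x List of `feature_sequence` objects (or `T x D` matrices).
#' @param labels Class labels, parallel to `x` (coerced to factor).
#' @param hidden_size Hidden units per direction (default 100).
#' @param epochs Maximum epochs; default 80 for 2 classes, 180 otherwise.
#' @param batch_size Minibatch size (default 150, capped at `length(x)`).
#' @param learning_rate Initial Adam learning rate (default 0.01).
#' @param grad_clip Global L2-norm gradient threshold (default 1).
#' @param l2 L2 regularization factor on weights (default 1e-4).
#' @param loss_tol Early-stop threshold on mean epoch loss (default 1e-3).
#' @param seed Integer seed; fixes initialization and shuffling, so equal
#'   seed + data + config reproduces the model and history exactly.
#' @param standardize Fit and apply a channel standardizer (default `TRUE`).
#' @return An object of class `frp_lstm`: the fitted parameters, class
#'   levels, standardizer, configuration, and a `history` data frame with
#'   per-iteration `epoch`, `loss` and minibatch `accuracy`.
#' @seealso [predict.frp_lstm()], [build_class_modeling_set()],
#'   [repeated_kfold_cv()]
#' @examples
#' set.seed(1)
#' toy <- lapply(1:20, function(i) {
#'   base <- matrix(rnorm(30 * 4), 30, 4)
#'   if (i > 10) base[, 1] <- base[, 1] + 5
#'   feature_sequence(base)
#' })
#' fit <- frp_lstm(toy, rep(c("a", "b"), each = 10),
#'                 hidden_size = 8, epochs = 15, seed = 1)
#' predict(fit, toy[[1]])
#' @export
frp_lstm <- function(x, labels, hidden_size = 100L, epochs = NULL,
                     batch_size = 150L, learning_rate = 0.01, grad_clip = 1,
                     l2 = 1e-4, loss_tol = 1e-3, seed = 1L,
                     standardize = TRUE) {
  if (!is.list(x) || length(x) == 0L) {
    stop("x must be a non-empty list of feature sequences", call. = FALSE)
  }
  labels <- as.factor(labels)
  if (length(x) != length(labels)) {
    stop("x and labels differ in length", call. = FALSE)
  }
  classes <- levels(droplevels(labels))
  K <- length(classes)
  if (K < 2L) stop("training set must contain at least 2 classes",
                   call. = FALSE)
  labels <- factor(as.character(labels), levels = classes)
  D <- ncol(x[[1L]])
  if (is.null(epochs)) epochs <- if (K == 2L) 80L else 180L
  std <- if (standardize) fit_standardizer(x) else
    structure(list(mean = rep(0, D), sd = rep(1, D)),
              class = "feature_standardizer")
  xs <- lapply(x, function(s) unclass(apply_standardizer(std, s)))
  n <- length(xs)
  bs <- min(as.integer(batch_size), n)
  y <- as.integer(labels)
  Y <- diag(K)[y, , drop = FALSE]

  fit_env <- withr::with_seed(as.integer(seed), {
    params <- init_bilstm(D, as.integer(hidden_size), K)
    skel <- params
    theta <- flatten_params(params)
    opt <- adam_init(length(theta))
    hist_epoch <- integer(0); hist_loss <- numeric(0); hist_acc <- numeric(0)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_losses <- numeric(0)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        st <- stack_sequences(xs[idx])
        fw <- bilstm_forward(params, st$X, st$lens)
        batch_loss <- -mean(log(pmax(fw$probs[cbind(seq_along(idx),
                                                    y[idx])], 1e-12)))
        batch_acc <- mean(max.col(fw$probs, ties.method = "first") == y[idx])
        g <- bilstm_backward(params, st$X, st$lens, fw,
                             Y[idx, , drop = FALSE], l2 = l2)
        gvec <- clip_gradient(flatten_params(g), grad_clip)
        stp <- adam_step(opt, theta, gvec, learning_rate)
        opt <- stp$state
        theta <- stp$theta
        params <- unflatten_params(theta, skel)
        hist_epoch <- c(hist_epoch, ep)
        hist_loss <- c(hist_loss, batch_loss)
        hist_acc <- c(hist_acc, batch_acc)
        ep_losses <- c(ep_losses, batch_loss)
      }
      if (mean(ep_losses) < loss_tol) break
    }
    list(params = params, hist_epoch = hist_epoch, hist_loss = hist_loss,
         hist_acc = hist_acc)
  })

  structure(list(
    params = fit_env$params,
    classes = classes,
    standardizer = std,
    config = list(hidden_size = as.integer(hidden_size), epochs = epochs,
                  batch_size = bs, learning_rate = learning_rate,
                  grad_clip = grad_clip, l2 = l2, loss_tol = loss_tol,
                  seed = as.integer(seed), n_train = n, n_channels = D),
    history = data.frame(iteration = seq_along(fit_env$hist_loss),
                         epoch = fit_env$hist_epoch,
                         loss = fit_env$hist_loss,
                         accuracy = fit_env$hist_acc)
  ), class = "frp_lstm")
}

#' Predict classes for new feature sequences
#'
#' Standardizes `newdata` with the statistics stored in the model and runs
#' the bidirectional forward pass. Softmax scores sum to 1; the predicted
#' class is the argmax, with ties broken toward the lowest class index.
#'
#' @param object A fitted [frp_lstm()] model.
#' @param newdata A single `T x 4` feature sequence or a list of them.
#' @param type `"class"` (default) for labels, `"prob"` for the score matrix.
#' @param ... Unused.
#' @return A factor of predicted classes, or an `n x K` matrix of softmax
#'   scores with classes as column names.
#' @export
predict.frp_lstm <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  if (is.matrix(newdata) || inherits(newdata, "feature_sequence")) {
    newdata <- list(newdata)
  }
  D <- object$config$n_channels
  bad <- vapply(newdata, function(s) ncol(s) != D, logical(1L))
  if (any(bad)) {
    stop("feature sequences must have ", D, " channels", call. = FALSE)
  }
  xs <- lapply(newdata, function(s)
    unclass(apply_standardizer(object$standardizer, s)))
  st <- stack_sequences(xs)
  fw <- bilstm_forward(object$params, st$X, st$lens)
  probs <- fw$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.frp_lstm <- function(x, ...) {
  cfg <- x$config
  cat("Bidirectional LSTM sequence classifier (frp_lstm)\n")
  cat("  classes:     ", paste(x$classes, collapse = ", "), "\n")
  cat("  hidden size: ", cfg$hidden_size, " per direction\n", sep = "")
  cat("  trained on ", cfg$n_train, " sequences, ",
      max(x$history$epoch), " epochs (", nrow(x$history),
      " iterations)\n", sep = "")
  cat(sprintf("  final loss %.4f, final minibatch accuracy %.1f%%\n",
              utils::tail(x$history$loss, 1L),
              100 * utils::tail(x$history$accuracy, 1L)))
  invisible(x)
}

#' @export
summary.frp_lstm <- function(object, ...) {
  structure(list(model = object), class = "summary.frp_lstm")
}

#' @export
print.summary.frp_lstm <- function(x, ...) {
  m <- x$model
  print(m)
  cfg <- m$config
  cat("\nTraining configuration:\n")
  cat(sprintf("  learning rate %.3g, batch size %d, gradient threshold %.3g, L2 %.3g, seed %d\n",
              cfg$learning_rate, cfg$batch_size, cfg$grad_clip, cfg$l2,
              cfg$seed))
  np <- length(flatten_params(m$params))
  cat("  parameters: ", format(np, big.mark = ","), "\n", sep = "")
  cat("\nChannel standardization (train statistics):\n")
  print(data.frame(mean = m$standardizer$mean, sd = m$standardizer$sd,
                   row.names = c("if_hz", "se", "frie",
                                 "fre")[seq_along(m$standardizer$mean)]))
  invisible(x)
}

#' Extract network parameters
#'
#' @param object A fitted `frp_lstm`.
#' @param ... Unused.
#' @return Named list of weight matrices and bias vectors (`Wx_f`, `Wh_f`,
#'   `b_f`, `Wx_b`, `Wh_b`, `b_b`, `Wd`, `bd`).
#' @export
coef.frp_lstm <- function(object, ...) object$params

#' Plot the training history
#'
#' Loss and minibatch accuracy against training iteration.
#'
#' @param x A fitted `frp_lstm`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.frp_lstm <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$iteration, h$loss, type = "l", xlab = "iteration",
                 ylab = "cross-entropy loss", main = "training history", ...)
  graphics::plot(h$iteration, 100 * h$accuracy, type = "l",
                 xlab = "iteration", ylab = "minibatch accuracy [%]",
                 ylim = c(0, 100), ...)
  invisible(x)
}

#' Save / load a fitted model as a plain-text checkpoint
#'
#' The checkpoint is a single JSON file holding parameters, class labels,
#' standardization statistics, configuration and a format version.
#'
#' @param model A fitted `frp_lstm`.
#' @param path Output path.
#' @return `path` (write) or the restored `frp_lstm` (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "frp_lstm"))
  payload <- list(
    format = "frplstm-checkpoint-1",
    classes = model$classes,
    config = model$config,
    standardizer = list(mean = unname(model$standardizer$mean),
                        sd = unname(model$standardizer$sd)),
    params = lapply(model$params, function(p)
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           data = as.numeric(p)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "frplstm-checkpoint-1")) {
    stop("not a recognized model checkpoint: ", path, call. = FALSE)
  }
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L]) else
      as.numeric(p$data)
  })
  structure(list(
    params = params,
    classes = payload$classes,
    standardizer = structure(list(mean = payload$standardizer$mean,
                                  sd = payload$standardizer$sd),
                             class = "feature_standardizer"),
    config = payload$config,
    history = data.frame(iteration = integer(0), epoch = integer(0),
                         loss = numeric(0), accuracy = numeric(0))
  ), class = "frp_lstm")
}
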