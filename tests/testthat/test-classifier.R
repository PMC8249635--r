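test_that("feature assembly fixes channel order and checks lengths", {
  s <- withr::with_seed(2, signal_series(stats::rnorm(4096), fs = 300))
  tf <- tf_sequence(s)
  ts <- ts_sequence(s, n_segments = length(tf$if_hz))
  fs <- assemble_features(tf, ts, label = "x")
  expect_equal(dim(fs), c(63L, 4L))
  expect_identical(colnames(fs), c("if_hz", "se", "frie", "fre"))
  expect_equal(fs[, 1], tf$if_hz, ignore_attr = TRUE)
  expect_equal(fs[, 4], ts$fre, ignore_attr = TRUE)
  expect_equal(attr(fs, "label"), "x")

  short <- ts_sequence(s, n_segments = 62)
  expect_error(assemble_features(tf, short), "inconsistency")
  expect_error(feature_sequence(matrix(1, 5, 3)), "4 channels")
})

test_that("standardizer pools train statistics with population sd", {
  a <- feature_sequence(matrix(0, 3, 4))
  b <- feature_sequence(matrix(2, 3, 4))
  std <- fit_standardizer(list(a, b))
  expect_equal(unname(std$mean), rep(1, 4))
  expect_equal(unname(std$sd), rep(1, 4))
  expect_equal(unclass(apply_standardizer(std, a)),
               matrix(-1, 3, 4), ignore_attr = TRUE)

  # constant training channel: sd floored, standardizes to zero
  cst <- fit_standardizer(list(a))
  expect_equal(unname(cst$sd), rep(1e-8, 4))
  expect_equal(unclass(apply_standardizer(cst, a)),
               matrix(0, 3, 4), ignore_attr = TRUE)

  # test data is standardized with the *train* statistics
  test_seq <- feature_sequence(matrix(5, 2, 4))
  expect_equal(unclass(apply_standardizer(std, test_seq)),
               matrix(4, 2, 4), ignore_attr = TRUE)
  expect_error(fit_standardizer(list()), "empty")
})

test_that("class modeling replicates one donor per competing class", {
  toy <- make_toy_features(n_per_class = 20)
  cm <- build_class_modeling_set(toy$features, toy$labels, "a")
  expect_length(cm$features, 40L)
  expect_equal(as.vector(table(cm$labels)), c(20L, 20L))
  donors <- cm$features[cm$labels == "b"]
  expect_true(all(vapply(donors, identical, logical(1), donors[[1]])))

  # eight classes at 625 each: 625 + 7 * 625 = 5000
  one <- feature_sequence(matrix(1, 1, 4))
  feats8 <- rep(list(one), 8 * 625)
  labs8 <- rep(letters[1:8], each = 625)
  cm8 <- build_class_modeling_set(feats8, labs8, "a")
  expect_length(cm8$features, 5000L)
  expect_true(all(table(cm8$labels) == 625L))

  # degenerate replication: plain one-per-class contrast set
  cm1 <- build_class_modeling_set(toy$features, toy$labels, "a",
                                  replication = 1)
  expect_length(cm1$features, 21L)
  expect_error(build_class_modeling_set(toy$features, toy$labels, "zz"),
               "not present")
})

test_that("the net separates offset classes and trains deterministically", {
  toy <- make_toy_features(n_per_class = 8, len = 20)
  fit <- frp_lstm(toy$features, toy$labels, hidden_size = 16, epochs = 20,
                  batch_size = 8, seed = 3, loss_tol = 0)
  expect_s3_class(fit, "frp_lstm")
  expect_equal(max(fit$history$epoch), 20L)
  pred <- predict(fit, toy$features)
  expect_equal(mean(pred == toy$labels), 1)

  refit <- frp_lstm(toy$features, toy$labels, hidden_size = 16, epochs = 20,
                    batch_size = 8, seed = 3, loss_tol = 0)
  expect_identical(fit$history, refit$history)
  expect_identical(fit$params, refit$params)

  expect_error(frp_lstm(toy$features, rep("a", 16)), "2 classes")
})

test_that("epoch defaults depend on the number of classes", {
  toy <- make_toy_features(n_per_class = 3, len = 10)
  fit2 <- frp_lstm(toy$features, toy$labels, hidden_size = 2, seed = 1,
                   loss_tol = Inf)   # stops after the first epoch
  expect_equal(fit2$config$epochs, 80L)

  labs3 <- factor(rep(c("a", "b", "c"), each = 2))
  fit3 <- frp_lstm(toy$features, labs3, hidden_size = 2, seed = 1,
                   loss_tol = Inf)
  expect_equal(fit3$config$epochs, 180L)
  expect_equal(fit2$config$batch_size, 6L)   # capped at the dataset size
})

test_that("epoch losses are non-increasing up to minibatch noise", {
  toy <- make_toy_features(n_per_class = 8, len = 20)
  fit <- frp_lstm(toy$features, toy$labels, hidden_size = 16, epochs = 15,
                  batch_size = 4, seed = 11, loss_tol = 0)
  ep_loss <- tapply(fit$history$loss, fit$history$epoch, mean)
  upticks <- sum(diff(ep_loss) > 0)
  expect_lte(upticks / length(ep_loss), 0.05)
})

test_that("prediction is normalized, order-invariant and type-checked", {
  toy <- make_toy_features(n_per_class = 6, len = 15)
  fit <- frp_lstm(toy$features, toy$labels, hidden_size = 8, epochs = 10,
                  batch_size = 6, seed = 5)
  probs <- predict(fit, toy$features, type = "prob")
  expect_equal(rowSums(probs), rep(1, 12), tolerance = 1e-6)
  expect_identical(colnames(probs), c("a", "b"))

  perm <- c(4, 1, 12, 7)
  expect_identical(predict(fit, toy$features[perm]),
                   predict(fit, toy$features)[perm])
  expect_error(predict(fit, matrix(1, 5, 3)), "4 channels")
})

test_that("model checkpoints round-trip through JSON", {
  toy <- make_toy_features(n_per_class = 4, len = 12)
  fit <- frp_lstm(toy$features, toy$labels, hidden_size = 4, epochs = 5,
                  batch_size = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$params, fit$params)
  expect_identical(back$classes, fit$classes)
  expect_equal(predict(back, toy$features, type = "prob"),
               predict(fit, toy$features, type = "prob"))
  expect_error(read_model(withr::local_tempfile(fileext = ".json",
                                                lines = "{}")),
               "not a recognized")
})
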