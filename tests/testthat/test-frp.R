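test_that("phase-space embedding matches the delay-coordinate definition", {
  expect_equal(embed_phase_space(c(5, 6, 7)), matrix(c(5, 6, 7), 3, 1))
  expect_equal(embed_phase_space(c(1, 2, 3, 4), m = 2, tau = 1),
               rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(nrow(embed_phase_space(stats::rnorm(100), m = 3, tau = 2)),
               96L)
  expect_error(embed_phase_space(1:3, m = 4, tau = 2), "too short")
})

test_that("fuzzy c-means resolves well-separated clusters crisply", {
  part <- fuzzy_c_means(c(0, 0, 0, 10, 10, 10), c = 2)
  expect_equal(sort(as.numeric(part$centroids)), c(0, 10), tolerance = 1e-6)
  low <- which.min(part$centroids)
  expect_true(all(part$U[1:3, low] >= 0.99))
  expect_true(all(part$U[4:6, 3 - low] >= 0.99))
  # zero-distance convention: points sitting on a centroid are crisp
  expect_equal(part$U[1, low], 1)
  expect_equal(part$U[1, 3 - low], 0)
})

test_that("membership rows always sum to one", {
  withr::with_seed(3, {
    for (i in 1:10) {
      x <- stats::rnorm(40)
      part <- fuzzy_c_means(x, c = 3)
      expect_equal(rowSums(part$U), rep(1, 40), tolerance = 1e-9)
      expect_true(all(part$U >= 0 & part$U <= 1))
    }
  })
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  x <- withr::with_seed(21, c(stats::rnorm(30, 0, .3),
                              stats::rnorm(30, 4, .3),
                              stats::rnorm(30, 9, .3)))
  mine <- fuzzy_c_means(x, c = 3)
  ref <- e1071::cmeans(matrix(x, ncol = 1), centers = 3, m = 2,
                       iter.max = 200)
  expect_equal(sort(as.numeric(mine$centroids)),
               sort(as.numeric(ref$centers)), tolerance = 1e-2)
  # same objective value at the optimum
  obj <- function(U, V) {
    d2 <- outer(x, as.numeric(V), function(a, b) (a - b)^2)
    sum(U^2 * d2)
  }
  expect_equal(obj(mine$U, mine$centroids),
               obj(ref$membership, ref$centers), tolerance = 1e-3)
})

test_that("degenerate inputs are rejected", {
  expect_error(fuzzy_c_means(rep(1, 10), c = 3), "degenerate")
  expect_error(fuzzy_c_means(c(0, 1), c = 1), "c must be >= 2")
})

test_that("the crisp two-cluster series yields a block recurrence plot", {
  part <- fuzzy_c_means(embed_phase_space(c(0, 0, 1, 1)), c = 2)
  R <- build_frp(part)
  expected <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                    c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unclass(R), expected, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("max-min composition equals the brute-force triple loop", {
  for (seed in 1:10) {
    N <- 10 + 4 * seed   # up to N = 50
    part <- random_partition(N, c = 3, seed = seed)
    R <- build_frp(part)
    expected <- oracle_maxmin(part$U)
    diag(expected) <- 1
    expect_equal(unclass(R), expected, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("recurrence plots satisfy the three fuzzy-relation axioms", {
  withr::with_seed(17, {
    for (i in 1:20) {
      x <- stats::rnorm(60)
      R <- build_frp(fuzzy_c_means(embed_phase_space(x), c = 3))
      expect_identical(diag(unclass(R)), rep(1, 60))
      expect_lt(max(abs(R - t(R))), 1e-12)
      expect_true(all(R >= 0 & R <= 1))
    }
  })
})

test_that("composition is invariant to cluster relabeling", {
  part <- random_partition(25, c = 3, seed = 5)
  permuted <- part
  permuted$U <- part$U[, c(3, 1, 2)]
  expect_equal(unclass(build_frp(part)), unclass(build_frp(permuted)))
})

test_that("iterated composition reaches a max-min transitive closure", {
  part <- random_partition(20, c = 3, seed = 9)
  single <- build_frp(part)
  closed <- build_frp(part, iterate = TRUE)
  expect_true(all(closed >= single - 1e-12))
  again <- frplstm:::maxmin_compose(unclass(closed), unclass(closed))
  diag(again) <- 1
  expect_equal(unclass(closed), again, tolerance = 1e-12)
})

test_that("FRIE matches closed forms and the counting oracle", {
  expect_equal(frie(matrix(1, 6, 6)), 0)
  half <- matrix(c(0, 1), 4, 4)
  expect_equal(frie(half), 1)
  withr::with_seed(23, {
    for (i in 1:5) {
      R <- matrix(stats::runif(30 * 30), 30, 30)
      expect_equal(frie(R, 256), oracle_frie(R, 256), tolerance = 1e-10)
      expect_lte(frie(R, 16), log2(16))
    }
  })
  expect_error(frie(matrix(1, 2, 2), L = 1), "L must be >= 2")
})

test_that("FRE matches closed forms and the elementwise oracle", {
  crisp <- matrix(sample(c(0, 1), 25, replace = TRUE), 5, 5)
  expect_equal(fre(crisp), 0)
  expect_equal(fre(matrix(0.5, 4, 4)), 16)
  withr::with_seed(29, {
    for (i in 1:5) {
      R <- matrix(stats::runif(20 * 20), 20, 20)
      expect_equal(fre(R), oracle_fre(R), tolerance = 1e-10)
      expect_lte(fre(R), 400)
      expect_gte(fre(R), 0)
    }
  })
})

test_that("segmented time-space sequences align and handle degeneracy", {
  s <- withr::with_seed(31, signal_series(stats::rnorm(4096), fs = 300))
  ts <- ts_sequence(s, n_segments = 63)
  expect_length(ts$frie, 63L)
  expect_length(ts$fre, 63L)
  b <- ts$segment_bounds
  expect_equal(unname(b[1, "start"]), 1L)
  expect_equal(unname(b[63, "end"]), 4096L)
  expect_true(all(b[-1, "start"] == b[-63, "end"] + 1L))
  sizes <- b[, "end"] - b[, "start"] + 1L
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_true(all(diff(sizes) <= 0))   # longer segments come first

  # constant series: every segment degenerate, full recurrence, zero entropy
  const <- ts_sequence(signal_series(rep(2, 800), fs = 300), n_segments = 10)
  expect_equal(const$frie, rep(0, 10))
  expect_equal(const$fre, rep(0, 10))

  expect_error(ts_sequence(signal_series(rep(1, 100)), n_segments = 50),
               "at least")
})

test_that("FRE separates low- and high-variance regimes", {
  s <- withr::with_seed(37, signal_series(
    c(stats::rnorm(2048, sd = 0.05), stats::rnorm(2048, sd = 1)), fs = 300))
  ts <- ts_sequence(s, n_segments = 32)
  low <- mean(ts$fre[1:16])
  high <- mean(ts$fre[17:32])
  # direction recorded from the oracle run: near-constant segments cluster
  # more crisply, so the quieter half carries lower fuzzy entropy
  expect_lt(low, high)
})

test_that("FRP PNG export and TS CSV writer round-trip", {
  part <- fuzzy_c_means(embed_phase_space(c(0, 0, 1, 1, 0.5, 0.4)), c = 2)
  R <- build_frp(part)
  png_path <- withr::local_tempfile(fileext = ".png")
  write_frp_png(R, png_path)
  back <- png::readPNG(png_path)
  expect_equal(back, round(unclass(R) * 255) / 255, tolerance = 1e-6)

  ts <- ts_sequence(signal_series(stats::rnorm(200), fs = 300),
                    n_segments = 8)
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_ts_csv(ts, csv_path)
  back2 <- utils::read.csv(csv_path)
  expect_named(back2, c("segment", "start", "end", "frie_bits", "fre_bits"))
  expect_equal(back2$fre_bits, ts$fre)
})
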