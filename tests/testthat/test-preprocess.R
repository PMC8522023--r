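test_that("epsilon selection follows the mean + sd/2 rule", {
  x <- with_seed(1, rnorm(500, mean = 1, sd = 0.4))
  expect_equal(select_epsilon(x), mean(x) + sd(x) / 2)
  expect_equal(select_epsilon(rep(3.5, 10)), 3.5)  # sd = 0 allowed
  # standard normal: rule gives ~0.5
  z <- with_seed(2, rnorm(1e5))
  expect_equal(select_epsilon(z), 0.5, tolerance = 0.01)
  expect_error(select_epsilon(1), "at least 2")
})

test_that("ternary quantizer maps the three branches literally", {
  expect_identical(quantize(c(2, 1), 0.5), 1L)
  expect_identical(quantize(c(1, 1.3), 0.5), 0L)
  expect_identical(quantize(c(1, 2), 0.5), -1L)
  # boundary: |diff| == epsilon is "no change"
  expect_identical(quantize(c(0, 0.5), 0.5), 0L)
  # monotone ramp with steps exceeding epsilon: all falls (-1 by the
  # literal orientation)
  eps <- 0.3
  ramp <- seq(0, 10, by = 2 * eps + 0.01)
  expect_true(all(quantize(ramp, eps) == -1L))
  # output length n - 1, matrices row-wise
  x <- matrix(rnorm(20), 2, 10)
  q <- quantize(x, c(0.1, 0.2))
  expect_equal(dim(q), c(2L, 9L))
})

test_that("zero-threshold quantization is invariant under strictly
           monotone transforms", {
  x <- with_seed(3, cumsum(rnorm(60)))
  expect_identical(quantize(x, 0), quantize(exp(x / 4), 0))
  expect_identical(quantize(x, 0), quantize(3 * x + 7, 0))
})

test_that("window slicing counts and annotation fractions", {
  x <- matrix(rnorm(300), 3, 100)
  ann <- rep(0L, 100); ann[41:70] <- 2L
  ds <- make_windows(x, ann, l = 20, stride = 20)
  expect_equal(n_windows(ds), 5L)
  expect_identical(dim(ds$windows), c(3L, 20L, 5L))
  # stride 1 gives T - l + 1 windows
  expect_equal(n_windows(make_windows(x, ann, l = 20, stride = 1)), 81L)
  # window fully inside the annotated segment has fraction 1
  expect_equal(ds$meta$activity[3], 2L)
  expect_equal(ds$meta$fraction[3], 1.0)
  expect_equal(ds$meta$fraction[1], 0)
  # coverage at stride = l: floor(T/l) * l samples
  expect_equal(n_windows(ds) * 20L, (100L %/% 20L) * 20L)
  expect_error(make_windows(x, ann, l = 200), "l")
})

test_that("window labeling threshold is inclusive and monotone", {
  expect_identical(label_window(16 / 20, 0.75), 1L)
  expect_identical(label_window(10 / 20, 0.75), 0L)
  expect_identical(label_window(15 / 20, 0.75), 1L)  # boundary case
  expect_error(label_window(1.2), "\\[0, 1\\]")
  # raising the threshold never converts a 0 into a 1
  fr <- seq(0, 1, by = 0.05)
  l1 <- label_window(fr, 0.5)
  l2 <- label_window(fr, 0.75)
  expect_true(all(l2 <= l1))
})

test_that("dataset labeling targets one activity against the null class", {
  x <- matrix(0, 1, 60)
  ann <- rep(c(0L, 1L, 2L), each = 20L)
  ds <- make_windows(x, ann, l = 20, stride = 10)
  d1 <- label_dataset(ds, 1L, 0.75)
  expect_equal(sum(d1$labels), sum(ds$meta$activity == 1L &
                                     ds$meta$fraction >= 0.75))
  d2 <- label_dataset(ds, 2L, 0.75)
  expect_true(all(d1$labels + d2$labels <= 1L))
  expect_error(label_dataset(ds, 1L, 0.3), "0.5")
})

test_that("quantizer fitting centers channels so gravity offsets do not
           swamp the threshold", {
  with_seed(4, {
    x <- rbind(9.8 + rnorm(600, sd = 0.2), rnorm(600, sd = 0.2))
    ds <- make_windows(x, rep(0L, 600), l = 30, stride = 30)
    qc <- fit_quantizer(ds)
    # both channels have identical spread; thresholds are sd/2-like and
    # unaffected by the offset
    expect_equal(qc$epsilon[1], qc$epsilon[2], tolerance = 0.05)
    expect_lt(qc$epsilon[1], 0.3)
    qd <- quantize_dataset(ds, qc)
    expect_true(qd$quantized)
    expect_identical(dim(qd$windows)[2], 29L)
    expect_true(all(qd$windows %in% c(-1, 0, 1)))
  })
})

test_that("standardization uses the supplied (training) statistics", {
  x <- with_seed(5, matrix(rnorm(400, 3, 2), 2, 200))
  ds <- make_windows(x, rep(0L, 200), l = 50, stride = 50)
  st <- fit_standardizer(ds)
  sd_ <- standardize_dataset(ds, st)
  expect_equal(mean(sd_$windows[1, , ]), 0, tolerance = 1e-10)
  expect_equal(sd(as.numeric(sd_$windows[2, , ])), 1, tolerance = 1e-10)
})
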