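test_that("single mutations differ at exactly one position within the
           allowed extent", {
  w <- with_seed(1, matrix(sample(c(-1L, 0L, 1L), 3 * 12, TRUE), 3, 12))
  with_seed(2, {
    muts <- mutate_window(w, augment_config(K = 25, M = 1))
    expect_length(muts, 25L)
    for (m in muts) {
      diffpos <- which(m != w)
      expect_length(diffpos, 1L)  # Hamming distance exactly 1
      expect_true(m[diffpos] %in% c(-1L, 0L, 1L))
      expect_lte(abs(m[diffpos] - w[diffpos]), 1)  # M = 1 adjacency
    }
  })
  expect_length(with_seed(3, mutate_window(w, augment_config(K = 0))), 0L)
})

test_that("per-position mode mutates K positions of a single copy", {
  w <- matrix(0L, 2, 50)
  with_seed(4, {
    m <- mutate_window(w, augment_config(K = 5, mode = "per_position"))
    expect_length(m, 1L)
    expect_lte(sum(m[[1]] != w), 5L)
    expect_gt(sum(m[[1]] != w), 0L)
  })
})

test_that("continuous windows mutate on the level grid", {
  w <- with_seed(5, matrix(rnorm(40), 2, 20))
  with_seed(6, {
    m <- mutate_window(w, augment_config(K = 10, M = 2,
                                         level_spacing = 0.25),
                       ternary = FALSE)
    for (mm in m) {
      dpos <- which(mm != w)
      expect_length(dpos, 1L)
      steps <- (mm[dpos] - w[dpos]) / 0.25
      expect_equal(steps, round(steps))
      expect_lte(abs(steps), 2)
      expect_true(steps != 0)
    }
  })
})

test_that("dataset augmentation appends K positives per positive and
           nothing else", {
  ds <- toy_ternary_dataset(n_pos = 10, n_neg = 90)
  aug <- augment_dataset(ds, augment_config(K = 5, seed = 3))
  expect_equal(n_windows(aug), 150L)
  expect_equal(sum(aug$labels == 1L), 60L)
  # originals untouched, in place
  expect_equal(aug$windows[, , 1:100], ds$windows, ignore_attr = TRUE)
  expect_identical(aug$labels[1:100], ds$labels)
  expect_true(all(aug$meta$origin[101:150] == "mutated"))
  expect_true(all(aug$labels[101:150] == 1L))
  # every mutated window is at Hamming distance 1 from some positive parent
  for (j in 101:150) {
    dists <- vapply(1:10, function(k)
      sum(aug$windows[, , j] != ds$windows[, , k]), integer(1))
    expect_equal(min(dists), 1L)
  }
})

test_that("K = 0 and label conservation", {
  ds <- toy_ternary_dataset()
  expect_identical(augment_dataset(ds, augment_config(K = 0)), ds)
  aug <- augment_dataset(ds, augment_config(K = 2, seed = 1))
  neg <- which(ds$labels == 0L)
  expect_equal(aug$windows[, , neg], ds$windows[, , neg],
               ignore_attr = TRUE)
  expect_identical(aug$labels[neg], ds$labels[neg])
})

test_that("augmentation is reproducible under a seed and monotone in K", {
  ds <- toy_ternary_dataset()
  a1 <- augment_dataset(ds, augment_config(K = 4, seed = 11))
  a2 <- augment_dataset(ds, augment_config(K = 4, seed = 11))
  expect_identical(a1, a2)
  fracs <- vapply(c(0L, 2L, 5L, 9L), function(K)
    mean(augment_dataset(ds, augment_config(K = K, seed = 1))$labels == 1L),
    numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("auto-selected K balances the positive class to about one half", {
  ds <- toy_ternary_dataset(n_pos = 10, n_neg = 90)
  aug <- augment_dataset(ds, augment_config(seed = 2))
  expect_equal(mean(aug$labels == 1L), 0.5, tolerance = 0.06)
})

test_that("augmenting a test split is rejected as a pipeline violation", {
  ds <- toy_ternary_dataset()
  parts <- split_dataset(ds, seed = 1)
  expect_error(augment_dataset(parts$test, augment_config(K = 1)),
               "test split")
  expect_silent(augment_dataset(parts$train, augment_config(K = 1, seed = 1)))
})
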