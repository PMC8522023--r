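test_that("random splits are disjoint, exhaustive, sized and seeded", {
  ds <- toy_ternary_dataset(n_pos = 20, n_neg = 80)
  parts <- split_dataset(ds, train_frac = 0.7, seed = 3)
  expect_equal(n_windows(parts$train), 70L)
  expect_equal(n_windows(parts$test), 30L)
  expect_identical(parts$train$role, "train")
  expect_identical(parts$test$role, "test")
  # union equals the input (as multisets of windows, via content totals)
  expect_equal(sum(parts$train$windows) + sum(parts$test$windows),
               sum(ds$windows))
  p2 <- split_dataset(ds, train_frac = 0.7, seed = 3)
  expect_identical(p2$train$windows, parts$train$windows)
  p3 <- split_dataset(ds, train_frac = 0.7, seed = 4)
  expect_false(identical(p3$train$windows, parts$train$windows))
})

test_that("by-subject splits keep whole subjects on one side", {
  x <- matrix(rnorm(300), 1, 300)
  parts <- lapply(1:4, function(s)
    make_windows(x, rep(0L, 300), l = 30, stride = 30, subject = s))
  ds <- bind_datasets(parts)
  ds$labels <- rep(0L, n_windows(ds))
  sp <- split_dataset(ds, train_frac = 0.5, seed = 2, by = "subject")
  expect_length(intersect(unique(sp$train$meta$subject),
                          unique(sp$test$meta$subject)), 0L)
})

test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracy(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_equal(accuracy(c(1, 1), c(0, 0)), 0.0)
  expect_equal(accuracy(c(1, 0, 1, 0), c(1, 0, 0, 1)), 0.5)
  expect_equal(accuracy(c(1, 0, 1, 1), c(1, 0, 0, 1)), 0.75)
  expect_error(accuracy(1:3, 1:4), "equal length")
})

test_that("cross-activity averaging reproduces the two-decimal reporting
           convention", {
  tab <- hapt_reference_accuracy()$threshold_16n_nonquantized
  expect_equal(average_accuracy(tab$mems_ctrnn_75), 77.94)
  expect_equal(average_accuracy(tab$ctrnn_75), 78.48)
  expect_equal(average_accuracy(rep(81.3, 4)), 81.3)
  expect_error(average_accuracy(numeric(0)), "nonempty")
})

test_that("grid constructor validates the multiplier set and expands
           cells", {
  g <- experiment_grid(n_hidden = c(3, 6), threshold = c(0.5, 0.75),
                      seeds = 1:2)
  expect_equal(nrow(g), 8L)
  expect_error(experiment_grid(P = 0.7), "p_multipliers")
  g2 <- experiment_grid(P = c(1 / 4, 2))
  expect_equal(sort(unique(g2$P)), c(0.25, 2))
})

test_that("a one-cell grid reduces to a single train-and-evaluate run and
           failures are caught per cell", {
  cfg <- synth_config(duration = 80, seed = 7)
  bench <- generate_benchmark(cfg, subjects = 2)
  ctl <- train_config(epochs = 2, seed = 1)
  g <- experiment_grid(n_hidden = 3, seeds = 1)
  res <- run_grid(g, bench, control = ctl)
  expect_equal(nrow(res), 1L)
  expect_true(is.na(res$error[1]))
  expect_true(res$test_accuracy[1] >= 0 && res$test_accuracy[1] <= 1)
  expect_true(is.finite(res$final_loss[1]))
  # a cell targeting an activity with no positive windows fails alone
  g2 <- experiment_grid(n_hidden = 3, activity = c("walk", "sit_to_stand"),
                        seeds = 1)
  res2 <- run_grid(g2, bench, control = ctl)
  expect_equal(nrow(res2), 2L)
  expect_true(any(is.na(res2$error)))   # the walk cell ran
  expect_true(any(!is.na(res2$error)))  # the empty-class cell was caught
})

test_that("tau-sweep cells rescale the natural frequency and stay
           Euler-stable", {
  p <- mems_params()
  expect_equal(stable_substeps(p, 50), as.integer(ceiling(2.5 / (2 * 0.0017 * 50))))
  p10 <- scale_omega_n(p, 10)
  s10 <- stable_substeps(p10, 50)
  expect_gte(s10, 2.5 / (2 * 0.00017 * 50) - 1)
  # dt below the stability limit after adjustment
  expect_lt(1 / (50 * s10), 2 * 0.00017)
})

test_that("quantizer thresholds and scaling statistics never see the test
           split", {
  cfg <- synth_config(duration = 60, seed = 9)
  bench <- generate_benchmark(cfg, subjects = 2)
  parts <- split_dataset(bench, seed = 1)
  qc <- fit_quantizer(parts$train)
  # manipulating the test windows must not change the fitted thresholds
  test2 <- parts$test
  test2$windows <- test2$windows * 100
  expect_identical(fit_quantizer(parts$train)$epsilon, qc$epsilon)
  # the pipeline applies train-fitted thresholds to both splits
  q_train <- quantize_dataset(parts$train, qc)
  q_test <- quantize_dataset(parts$test, qc)
  expect_identical(q_train$epsilon, q_test$epsilon)
})

test_that("grid summaries aggregate repeated seeds per cell", {
  res <- data.frame(engine = "mems", n_hidden = 3, quantize = TRUE,
                    channel_set = 1, threshold = 0.75, P = 1,
                    activity = "walk", seed = 1:3,
                    test_accuracy = c(0.8, 0.9, 1.0))
  s <- summarize_grid(res)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mean_accuracy, 0.9)
  expect_equal(s$sd_accuracy, 0.1)
  expect_equal(s$n_seeds, 3L)
})
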