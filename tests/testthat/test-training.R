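test_that("weight initialization: shapes, seed determinism, layering", {
  w <- init_network(6, 3, seed = 1)
  expect_identical(dim(w$w_rec), c(9L, 9L))
  expect_identical(dim(w$w_out), c(2L, 9L))
  expect_identical(dim(w$w_in), c(9L, 3L))
  # input weights only on the input-layer rows
  expect_true(all(w$w_in[4:9, ] == 0))
  expect_true(all(w$w_in[1:3, ] != 0))
  expect_identical(init_network(6, 3, seed = 1), w)
  expect_false(identical(init_network(6, 3, seed = 2), w))
  expect_error(init_network(0, 3), "positive")
})

test_that("weights round-trip through the CSV/JSON serialization", {
  w <- init_network(4, 2, seed = 8)
  d <- tempfile()
  write_network_weights(w, d)
  w2 <- read_network_weights(d)
  expect_equal(w2$w_rec, w$w_rec)
  expect_equal(w2$theta, w$theta)
  expect_equal(w2$n_input, w$n_input)
  unlink(d, recursive = TRUE)
})

test_that("smooth forward with zero weights returns the readout biases", {
  p <- mems_params()
  w <- network_weights(matrix(0, 3, 3), matrix(0, 3, 2), rep(0, 3),
                       matrix(0, 2, 3), c(1.1, -0.3), n_input = 2L)
  sc <- forward_smooth(matrix(0, 2, 10), w, p)
  expect_equal(drop(sc), c(1.1, -0.3))
})

test_that("smooth forward converges to the hard-step simulator as the
           surrogate sharpens", {
  p <- mems_params()
  w <- small_net(2, 1, seed = 5)
  w$theta <- abs(w$theta) + 0.4
  x <- with_seed(12, matrix(sample(c(-1, 0, 1), 15, TRUE), 1, 15))
  hard <- simulate_network(x, p, w, record = FALSE)$scores
  sharp <- forward_smooth(x, w, p, train_config(surrogate_beta = 5e8,
                                                beta_growth = 1))
  expect_equal(drop(sharp), hard, tolerance = 1e-6)
})

test_that("backpropagated gradients match central finite differences on a
           two-neuron network", {
  # fire threshold placed inside the sub-pull-in operating range so the
  # surrogate is active along the trajectory
  p <- mems_params(fire_frac = 0.25)
  ph <- memsctrnn:::mems_derived(p)
  w <- init_network(1, 1, seed = 3, engine = "mems", params = p)
  w$w_in[1, 1] <- 0.3 * memsctrnn:::input_weight_scale(p)
  X <- with_seed(7, array(runif(5, 0.2, 1), c(1, 5, 1)))
  y <- 1L
  beta <- 1.2e5
  dt <- 1 / (50 * 16)
  lossfun <- function(wts)
    memsctrnn:::cpp_mems_train_batch(X, y, wts$w_rec, wts$w_in, wts$theta,
                                     wts$w_out, wts$b_out, ph$tau, ph$c1,
                                     ph$d, ph$zc, ph$zf, ph$invw2, dt, 16L,
                                     beta, p$d / 2, FALSE)$loss
  g <- memsctrnn:::cpp_mems_train_batch(X, y, w$w_rec, w$w_in, w$theta,
                                        w$w_out, w$b_out, ph$tau, ph$c1,
                                        ph$d, ph$zc, ph$zf, ph$invw2, dt,
                                        16L, beta, p$d / 2, TRUE)
  bp <- list(w_rec = g$gW, w_in = g$gWin, theta = g$gtheta,
             w_out = g$gWout, b_out = g$gbout)
  hs <- c(w_rec = 1e-6, w_in = 1e-6 * memsctrnn:::input_weight_scale(p),
          theta = 1e-6, w_out = 1e-6, b_out = 1e-6)
  for (grp in names(bp)) {
    fd <- as.matrix(bp[[grp]]) * 0
    for (i in seq_along(fd)) {
      wp <- w; wm <- w
      wp[[grp]][i] <- wp[[grp]][i] + hs[[grp]]
      wm[[grp]][i] <- wm[[grp]][i] - hs[[grp]]
      fd[i] <- (lossfun(wp) - lossfun(wm)) / (2 * hs[[grp]])
    }
    bpv <- as.numeric(bp[[grp]]); fdv <- as.numeric(fd)
    rel <- abs(bpv - fdv) /
      pmax(abs(bpv), abs(fdv), 1e-3 * max(abs(fdv), 1e-12))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("CTRNN backpropagation matches finite differences", {
  p <- mems_params()
  w <- init_network(1, 1, seed = 9, engine = "ctrnn", params = p)
  tau <- rep(0.01, 2)
  X <- with_seed(15, array(runif(5, -1, 1), c(1, 5, 1)))
  y <- 0L
  dt <- 1 / (50 * 16)
  lossfun <- function(wts)
    memsctrnn:::cpp_ctrnn_train_batch(X, y, wts$w_rec, wts$w_in, wts$theta,
                                      wts$w_out, wts$b_out, tau, dt, 16L,
                                      FALSE)$loss
  g <- memsctrnn:::cpp_ctrnn_train_batch(X, y, w$w_rec, w$w_in, w$theta,
                                         w$w_out, w$b_out, tau, dt, 16L,
                                         TRUE)
  bp <- list(w_rec = g$gW, w_in = g$gWin, theta = g$gh, w_out = g$gWout,
             b_out = g$gbout)
  for (grp in names(bp)) {
    fd <- as.matrix(bp[[grp]]) * 0
    for (i in seq_along(fd)) {
      wp <- w; wm <- w
      wp[[grp]][i] <- wp[[grp]][i] + 1e-6
      wm[[grp]][i] <- wm[[grp]][i] - 1e-6
      fd[i] <- (lossfun(wp) - lossfun(wm)) / 2e-6
    }
    bpv <- as.numeric(bp[[grp]]); fdv <- as.numeric(fd)
    rel <- abs(bpv - fdv) /
      pmax(abs(bpv), abs(fdv), 1e-3 * max(abs(fdv), 1e-12))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("zero-epoch training returns the seeded initial weights
           unchanged", {
  ds <- toy_ternary_dataset()
  res <- train_network(ds, train_config(epochs = 0, seed = 4), n_hidden = 2)
  expect_identical(res$weights,
                   init_network(2, 3, seed = 4, init_scale = 0.5))
  expect_equal(nrow(res$history), 0L)
})

test_that("training rejects single-class datasets and is seed
           deterministic", {
  ds <- toy_ternary_dataset(n_pos = 0, n_neg = 20)
  expect_error(train_network(ds, train_config(epochs = 1)), "both classes")
  ds2 <- toy_ternary_dataset(n_pos = 8, n_neg = 24)
  cfg <- train_config(epochs = 2, seed = 6, batch_size = 8)
  r1 <- train_network(ds2, cfg, n_hidden = 2)
  r2 <- train_network(ds2, cfg, n_hidden = 2)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$history, r2$history)
})

test_that("training reduces the loss on a small separable task", {
  ds <- toy_ternary_dataset(n_pos = 16, n_neg = 16)
  res <- train_network(ds, train_config(epochs = 6, seed = 2,
                                        batch_size = 16), n_hidden = 2)
  h <- res$history
  expect_lt(mean(tail(h$loss, 2)), mean(head(h$loss, 2)))
})

test_that("the model front end fits, predicts, and exposes the usual
           methods", {
  ds <- toy_ternary_dataset(n_pos = 16, n_neg = 32)
  fit <- mems_ctrnn(ds, n_hidden = 2,
                    control = train_config(epochs = 4, seed = 3,
                                           batch_size = 16))
  expect_s3_class(fit, "mems_ctrnn")
  pr <- predict(fit, ds)
  expect_true(all(pr %in% c(0L, 1L)))
  pp <- predict(fit, ds, type = "prob")
  expect_true(all(pp >= 0 & pp <= 1))
  expect_identical(as.integer(pp > 0.5), pr)
  expect_named(coef(fit), c("w_rec", "w_in", "theta", "w_out", "b_out"))
  expect_output(print(fit), "MEMS-CTRNN")
  expect_output(print(summary(fit)), "pull-in")
  r <- residuals(fit, ds)
  expect_equal(r, ds$labels - pp)
  sim <- simulate(fit, nsim = 2, seed = 1, newdata = ds)
  expect_identical(dim(sim), c(n_windows(ds), 2L))
  # ctrnn engine end to end
  fitc <- mems_ctrnn(ds, engine = "ctrnn", n_hidden = 2,
                     control = train_config(epochs = 2, seed = 3,
                                            batch_size = 16))
  expect_true(all(predict(fitc, ds) %in% c(0L, 1L)))
})
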