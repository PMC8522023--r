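ctrnn_one <- function(w_self = 0, h = 0, w_in = 0, tau = 1) {
  ctrnn_params(network_weights(matrix(w_self, 1, 1), matrix(w_in, 1, 1), h,
                               matrix(0, 2, 1), c(0, 0), n_input = 1L),
               tau = tau)
}

test_that("free CTRNN decay matches the linear closed form", {
  cp <- ctrnn_one(tau = 1)
  # w = 0 with sigma(0) = 0.5 contributes w*0.5 = 0, so pure decay
  st <- ctrnn_state(1)
  dt <- 0.01
  ys <- numeric(100)
  for (i in 1:100) {
    st <- ctrnn_step(st, cp, 0, dt)
    ys[i] <- st$y
  }
  expected <- exp(-dt * (1:100))
  expect_lt(max(abs(ys - expected)), 0.01)
})

test_that("constant-input fixed point is bias plus input", {
  cp <- ctrnn_one(h = 0.4, w_in = 1, tau = 0.05)
  st <- ctrnn_state(0)
  for (i in 1:2000) st <- ctrnn_step(st, cp, 0.3, 0.05 * 0.05)
  expect_equal(st$y, 0.4 + 0.3, tolerance = 1e-6)
})

test_that("self-excited neuron settles at the root of the fixed-point
           equation", {
  w_self <- 1.5; h <- 0.2; inp <- 0.1
  cp <- ctrnn_one(w_self = w_self, h = h, w_in = 1, tau = 0.02)
  st <- ctrnn_state(0)
  for (i in 1:4000) st <- ctrnn_step(st, cp, inp, 0.02 * 0.05)
  # bisection oracle for y = w*sigma(y) + h + I
  f <- function(y) w_self / (1 + exp(-y)) + h + inp - y
  root <- uniroot(f, c(-10, 10))$root
  expect_equal(st$y, root, tolerance = 1e-4)
})

test_that("zero network is silent and scores equal the readout biases", {
  w <- network_weights(matrix(0, 2, 2), matrix(0, 2, 1), c(0, 0),
                       matrix(0, 2, 2), c(0.2, -0.1), n_input = 1L)
  tr <- simulate_ctrnn(matrix(0, 1, 10), ctrnn_params(w, 0.01))
  expect_equal(max(abs(tr$y)), 0)
  expect_equal(tr$scores, c(0.2, -0.1))
})

test_that("activations stay within the a-priori bound with logistic
           sigma", {
  w <- small_net(3, 2, seed = 7)
  cp <- ctrnn_params(w, tau = 0.005)
  x <- with_seed(1, matrix(runif(2 * 40, -1, 1), 2, 40))
  tr <- simulate_ctrnn(x, cp, substeps = 16)
  bound <- abs(w$theta) + rowSums(abs(w$w_rec)) +
    rowSums(abs(w$w_in)) * 1 + 1e-9
  expect_true(all(abs(tr$y) <= bound))
})

test_that("larger time constants respond more slowly (time to 90% of the
           step response grows)", {
  t90 <- vapply(c(0.002, 0.005, 0.02), function(tau) {
    cp <- ctrnn_one(h = 0, w_in = 1, tau = tau)
    st <- ctrnn_state(0)
    dt <- tau / 100
    target <- 0.9 * 1  # step input of 1, fixed point y* = 1
    for (i in 1:2000) {
      st <- ctrnn_step(st, cp, 1, dt)
      if (st$y >= target) return(st$t)
    }
    st$t
  }, numeric(1))
  expect_true(all(diff(t90) > 0))
})

test_that("compiled CTRNN converges first-order to a fine-step reference
           solution", {
  w <- init_network(2, 1, seed = 13, engine = "ctrnn")
  cp <- ctrnn_params(w, tau = 0.01)
  x <- with_seed(6, matrix(runif(6, -1, 1), 1, 6))
  ref <- simulate_ctrnn(x, cp, substeps = 1024)
  yref <- ref$y[, ncol(ref$y)]
  err <- vapply(c(16, 64), function(s) {
    tr <- simulate_ctrnn(x, cp, substeps = s)
    max(abs(tr$y[, ncol(tr$y)] - yref))
  }, numeric(1))
  # Euler is first order: quartering the step shrinks the error ~4x
  expect_lt(err[2], err[1] / 2.5)
  expect_lt(err[2], 5e-3)
})

test_that("CTRNN simulation is bit-stable across repeated runs", {
  w <- small_net(2, 1, seed = 17)
  cp <- ctrnn_params(w)
  x <- with_seed(9, matrix(runif(10, -1, 1), 1, 10))
  t1 <- simulate_ctrnn(x, cp)
  t2 <- simulate_ctrnn(x, cp)
  expect_identical(t1$scores, t2$scores)
  expect_identical(t1$y, t2$y)
})
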