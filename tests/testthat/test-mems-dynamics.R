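test_that("node voltages equal the gated linear-system fixed point", {
  w <- small_net(2, 1, seed = 1)
  N <- 3L
  # no firing: voltages are the biases exactly
  expect_equal(node_voltages(w, rep(0, N)), w$theta)
  # single-substitution example
  w2 <- network_weights(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE),
                        matrix(0, 2, 1), c(0, 2), matrix(0, 2, 2), c(0, 0),
                        n_input = 1L)
  expect_equal(node_voltages(w2, c(0, 1)), c(2, 2))
  # random small networks: match a dense linear solve restricted to the
  # fired neurons
  for (seed in 1:5) {
    ws <- small_net(3, 2, seed = seed)
    n <- nrow(ws$w_rec)
    fired <- with_seed(seed, rbinom(n, 1, 0.5))
    V <- node_voltages(ws, fired)
    A <- diag(n) - ws$w_rec %*% diag(as.numeric(fired), n)
    expect_equal(drop(A %*% V), ws$theta)
  }
})

test_that("diverging voltage recursion is reported with the neuron", {
  w <- network_weights(matrix(1, 1, 1), matrix(0, 1, 1), 1,
                       matrix(0, 2, 1), c(0, 0), n_input = 1L)
  expect_error(node_voltages(w, 1), "neuron 1")
})

test_that("force-free relaxation follows the closed-form decay", {
  p <- mems_params()
  tau <- time_constant(p$zeta, p$omega_n)
  w <- one_neuron_weights(0)
  dt <- tau / 50
  z0 <- 0.3 * p$d
  st <- network_state(z0, p, w)
  nstep <- 150L  # 3 tau
  zs <- numeric(nstep)
  for (i in seq_len(nstep)) {
    st <- mems_step(st, p, w, 0, dt)
    zs[i] <- st$z
  }
  expected <- z0 * exp(-dt * seq_len(nstep) / tau)
  expect_lt(max(abs(zs - expected) / expected), 2 * dt / tau)
})

test_that("constant sub-pull-in voltage converges to the smallest
           equilibrium root, below d/3", {
  p <- mems_params()
  for (frac in c(0.5, 0.9)) {
    V <- frac * static_pullin_voltage(p)
    w <- one_neuron_weights(V)
    st <- network_state(0, p, w)
    dt <- time_constant(p$zeta, p$omega_n) / 20
    for (i in 1:400) st <- mems_step(st, p, w, 0, dt)
    roots <- equilibrium_roots(p, V)
    expect_lt(min(roots), p$d / 3)
    expect_equal(st$z, min(roots), tolerance = 1e-3)
  }
})

test_that("mems_step flags unstable steps and overlarge displacements", {
  p <- mems_params()
  w <- one_neuron_weights(0)
  st <- network_state(0, p, w)
  expect_error(mems_step(st, p, w, 0, dt = 2.1 * 0.0017), "stability")
  # near-contact start + strong voltage: raw Euler overshoots past 2d
  w2 <- one_neuron_weights(2 * static_pullin_voltage(p))
  st2 <- network_state(0.94 * p$d, p, w2)
  dt <- time_constant(p$zeta, p$omega_n) / 2
  expect_error(mems_step(st2, p, w2, 0, dt), "overshoot")
  # the capped integrator resolves the same situation by clamping
  st3 <- mems_step(st2, p, w2, 0, dt, max_step = p$d / 2)
  expect_lte(st3$z, p$contact_frac * p$d)
})

test_that("quasi-static sweep shows pull-in/release hysteresis matching the
           equilibrium-tracking oracle", {
  p <- mems_params()
  sweep <- hysteresis_sweep(p)
  expect_gt(sweep$pullin_v, sweep$release_v)
  # oracle: pull-in = loss of the low stable equilibrium (closed form);
  # release = voltage where the contact force balance at the stop fails
  ph <- memsctrnn:::mems_derived(p)
  v_pi_oracle <- static_pullin_voltage(p)
  v_rel_oracle <- sqrt(ph$zc * (p$d - ph$zc)^2 / ph$c1)
  expect_lt(abs(sweep$pullin_v - v_pi_oracle) / v_pi_oracle, 0.01)
  expect_lt(abs(sweep$release_v - v_rel_oracle) / v_rel_oracle, 0.01)
})

test_that("simulated trajectories respect the displacement bound", {
  p <- mems_params()
  w <- small_net(3, 2, seed = 9)
  w$theta <- w$theta + 0.6  # bias the network toward activity
  x <- with_seed(4, matrix(sample(c(-1, 0, 1), 2 * 30, TRUE), 2, 30))
  tr <- simulate_network(x, p, w, substeps = 16)
  expect_true(all(tr$z >= 0))
  expect_true(all(tr$z <= p$contact_frac * p$d + 1e-18))
})

test_that("all-zero weights and input give a silent network; scores are
           the readout biases", {
  p <- mems_params()
  w <- network_weights(matrix(0, 3, 3), matrix(0, 3, 2), rep(0, 3),
                       matrix(0.7, 2, 3), c(0.3, -0.4), n_input = 2L)
  tr <- simulate_network(matrix(0, 2, 10), p, w)
  expect_equal(sum(tr$activity), 0)
  expect_equal(tr$scores, c(0.3, -0.4))
})

test_that("sub-pull-in bias never fires; slightly above pull-in fires
           within ten time constants", {
  p <- mems_params()
  tau <- time_constant(p$zeta, p$omega_n)
  L <- ceiling(10 * tau * 50) + 2L
  vpi <- static_pullin_voltage(p)
  tr_lo <- simulate_network(matrix(0, 1, L), p,
                            one_neuron_weights(0.95 * vpi), substeps = 32)
  expect_equal(sum(tr_lo$activity), 0)
  tr_hi <- simulate_network(matrix(0, 1, L), p,
                            one_neuron_weights(1.05 * vpi), substeps = 32)
  fire_idx <- which(tr_hi$activity[1, ] > 0)
  expect_gt(length(fire_idx), 0)
  expect_lt(tr_hi$time[min(fire_idx)], 10 * tau)
})

test_that("the compiled simulator matches the composition of mems_step", {
  p <- mems_params()
  w <- small_net(2, 1, seed = 11)
  w$theta <- abs(w$theta) + 0.3
  x <- with_seed(2, matrix(runif(8, -1, 1), 1, 8))
  substeps <- 16L
  dt <- 1 / (50 * substeps)
  st <- network_state(rep(0, 3), p, w)
  for (l in seq_len(ncol(x)))
    for (s in seq_len(substeps))
      st <- mems_step(st, p, w, x[, l], dt, max_step = p$d / 2)
  tr <- simulate_network(x, p, w, substeps = substeps)
  expect_equal(tr$z[, ncol(tr$z)], st$z, tolerance = 1e-12)
})

test_that("halving the Euler step changes terminal displacements only
           slightly (self-convergence)", {
  p <- mems_params()
  w <- small_net(2, 1, seed = 3)
  x <- with_seed(8, matrix(runif(10, -0.5, 0.5), 1, 10))
  t1 <- simulate_network(x, p, w, substeps = 32)
  t2 <- simulate_network(x, p, w, substeps = 64)
  expect_lt(max(abs(t1$z[, ncol(t1$z)] - t2$z[, ncol(t2$z)])), 0.02 * p$d)
})

test_that("simulation is deterministic given identical arguments", {
  p <- mems_params()
  w <- small_net(2, 1, seed = 21)
  x <- with_seed(3, matrix(sample(c(-1, 0, 1), 20, TRUE), 1, 20))
  t1 <- simulate_network(x, p, w)
  t2 <- simulate_network(x, p, w)
  expect_identical(t1$scores, t2$scores)
  expect_identical(t1$z, t2$z)
})

test_that("trajectory CSV dump round-trips through read.csv", {
  p <- mems_params()
  w <- small_net(2, 1, seed = 2)
  tr <- simulate_network(matrix(0.5, 1, 5), p, w)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- read.csv(f)
  expect_equal(nrow(df), ncol(tr$z))
  expect_equal(df$z_1, tr$z[1, ])
  expect_equal(names(df)[1], "time_s")
})
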