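#' Node voltages given the previous firing pattern
#'
#' Each neuron's voltage is its bias plus the weighted voltages of the
#' neurons currently firing into it. Holding the firing pattern of the
#' previous time step fixed breaks the cyclic recursion, and the voltages are
#' the fixed point of the resulting linear system:
#' `(I - w_rec diag(fired)) V = theta`.
#'
#' @param weights a [network_weights()] object.
#' @param fired_prev binary (0/1) vector of length N: which neurons fired at
#'   the previous step.
#' @return Numeric vector of node voltages.
#' @examples
#' w <- init_network(2, 1, seed = 1)
#' node_voltages(w, rep(0, 3))  # no firing: voltages equal the biases
#' @export
node_voltages <- function(weights, fired_prev) {
  stopifnot(inherits(weights, "network_weights"))
  N <- nrow(weights$w_rec)
  fired_prev <- as.numeric(fired_prev)
  if (length(fired_prev) != N)
    stopf("'fired_prev' must have length %d", N)
  if (!all(fired_prev %in% c(0, 1)))
    stopf("'fired_prev' must be a binary vector")
  A <- diag(N) - weights$w_rec %*% diag(fired_prev, N)
  V <- tryCatch(solve(A, weights$theta), error = function(e) rep(NA_real_, N))
  if (!all(is.finite(V))) {
    bad <- which(!is.finite(V))[1L]
    if (all(is.na(V))) bad <- which.max(abs(fired_prev))
    stopf("voltage recursion diverged at neuron %d: gated linear system is singular", bad)
  }
  drop(V)
}

#' Instantaneous network state
#'
#' Displacements, firing indicators, voltages and elapsed time of a MEMS
#' network. `fired` is recomputed from `z` against the firing threshold
#' `fire_frac * d`; displacements must lie within `[0, contact_frac * d]`.
#'
#' @param z length-N displacement vector (m).
#' @param params a [mems_params()] object.
#' @param weights a [network_weights()] object (defines N and the voltages).
#' @param t elapsed time (s).
#' @return An object of class `network_state` with fields `z`, `fired`, `V`,
#'   `t`.
#' @export
network_state <- function(z, params, weights, t = 0) {
  stopifnot(inherits(params, "mems_params"), inherits(weights, "network_weights"))
  z <- as.numeric(z)
  ph <- mems_derived(params)
  if (any(z < 0) || any(z > ph$zc + 1e-15 * ph$d))
    stopf("displacements must lie in [0, contact_frac * d]")
  fired <- as.numeric(z >= ph$zf)
  V <- node_voltages(weights, fired)
  structure(list(z = z, fired = fired, V = V, t = t),
            class = "network_state")
}

#' One explicit-Euler step of the MEMS network
#'
#' Advances each displacement by one Euler step of
#' `tau * dz/dt = -z + eps*A*V^2 / (2*k*(d - z)^2) + (1/omega_n^2) * w_in %*% u`,
#' with `tau = 2*zeta/omega_n` and voltages from [node_voltages()] using the
#' previous step's firing pattern. After the step, displacements are clamped
#' to `[0, contact_frac * d]` and the firing indicators recomputed.
#'
#' With `max_step = Inf` (the default here), a pre-clamp overshoot beyond
#' `2 d` raises an error suggesting sub-stepping; the production simulator
#' [simulate_network()] instead caps the per-substep increment so that
#' pull-in snap-through is resolved over a few substeps.
#'
#' @param state a [network_state()] object.
#' @param params a [mems_params()] object.
#' @param weights a [network_weights()] object.
#' @param input_t length-O input vector held constant over the step.
#' @param dt step size in seconds (> 0; must be below `2 * tau` for
#'   stability).
#' @param max_step cap on the per-step displacement increment (m); `Inf`
#'   disables the cap and enables the overshoot error.
#' @return The advanced `network_state`.
#' @export
mems_step <- function(state, params, weights, input_t, dt, max_step = Inf) {
  stopifnot(inherits(state, "network_state"),
            inherits(params, "mems_params"),
            inherits(weights, "network_weights"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stopf("'dt' must be a single positive number")
  ph <- mems_derived(params)
  if (dt >= 2 * ph$tau)
    stopf("dt = %g exceeds the explicit-Euler stability limit 2*tau = %g; use more substeps",
          dt, 2 * ph$tau)
  input_t <- as.numeric(input_t)
  if (length(input_t) != ncol(weights$w_in))
    stopf("'input_t' must have length %d", ncol(weights$w_in))
  z <- state$z
  V <- node_voltages(weights, state$fired)
  Fdrive <- ph$c1 * V^2 / (ph$d - z)^2 +
    ph$invw2 * drop(weights$w_in %*% input_t)
  dz <- (dt / ph$tau) * (Fdrive - z)
  if (is.finite(max_step)) {
    dz <- pmin(pmax(dz, -max_step), max_step)
  } else if (any(z + dz > 2 * ph$d)) {
    stopf("displacement overshoot beyond 2*d at neuron %d: dt too large for stability, increase substeps",
          which.max(z + dz))
  }
  znew <- pmin(pmax(z + dz, 0), ph$zc)
  structure(list(z = znew, fired = as.numeric(znew >= ph$zf), V = V,
                 t = state$t + dt),
            class = "network_state")
}

#' Simulate a MEMS network over an input window
#'
#' Holds each input sample constant for its sampling interval, integrates the
#' network with `substeps` explicit-Euler substeps per sample, and applies
#' the dense readout to the window-averaged firing activity to produce two
#' class scores. Deterministic given its arguments.
#'
#' @param input_window O x L numeric matrix: one row per channel, one column
#'   per sample.
#' @param params a [mems_params()] object.
#' @param weights a [network_weights()] object.
#' @param sample_rate input sampling rate in Hz.
#' @param substeps Euler substeps per input sample (>= 1).
#' @param mode `"hard"` uses the unit-step firing (the physical model);
#'   `"smooth"` replaces it with the logistic surrogate of steepness `beta`.
#' @param beta surrogate steepness (1/m), used when `mode = "smooth"`.
#' @param max_step per-substep displacement cap in meters; the default `d/2`
#'   resolves pull-in snap-through over a few substeps. `Inf` restores the
#'   strict overshoot error of [mems_step()].
#' @param z0 initial displacements (default: all at rest).
#' @param record if `TRUE`, keep the full state trajectory.
#' @return An object of class `mems_trajectory`: a list with `scores`
#'   (length 2), `summary` (per-neuron mean activity), and, when recorded,
#'   `time`, `z`, `V`, `activity` matrices (N x T).
#' @examples
#' w <- init_network(3, 1, seed = 2)
#' x <- matrix(sin(seq(0, 4 * pi, length.out = 20)), nrow = 1)
#' tr <- simulate_network(x, mems_params(), w)
#' tr$scores
#' @export
simulate_network <- function(input_window, params, weights,
                             sample_rate = 50, substeps = 16,
                             mode = c("hard", "smooth"), beta = 1.5e6,
                             max_step = params$d / 2, z0 = NULL,
                             record = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "mems_params"),
            inherits(weights, "network_weights"))
  input_window <- as.matrix(input_window)
  if (ncol(weights$w_in) != nrow(input_window))
    stopf("input window must have %d channels (rows)", ncol(weights$w_in))
  if (ncol(input_window) < 1L) stopf("input window must have >= 1 samples")
  substeps <- as.integer(substeps)
  if (substeps < 1L) stopf("'substeps' must be >= 1")
  ph <- mems_derived(params)
  dt <- 1 / (sample_rate * substeps)
  if (dt >= 2 * ph$tau)
    stopf("dt = %g exceeds the explicit-Euler stability limit 2*tau = %g; use more substeps",
          dt, 2 * ph$tau)
  N <- nrow(weights$w_rec)
  if (is.null(z0)) z0 <- rep(0, N)
  res <- cpp_mems_forward(input_window, weights$w_rec, weights$w_in,
                          weights$theta, ph$tau, ph$c1, ph$d, ph$zc, ph$zf,
                          ph$invw2, dt, substeps, mode == "hard", beta,
                          max_step, as.numeric(z0), record)
  scores <- drop(weights$w_out %*% res$summary) + weights$b_out
  out <- list(scores = scores, summary = drop(res$summary),
              mode = mode, dt = dt, substeps = substeps)
  if (record) {
    out$time <- dt * seq_len(ncol(res$z))
    out$z <- res$z
    out$V <- res$V
    out$activity <- res$activity
  }
  structure(out, class = "mems_trajectory")
}

#' @export
print.mems_trajectory <- function(x, ...) {
  cat(sprintf("MEMS network trajectory (%s mode): scores = (%.4g, %.4g)\n",
              x$mode, x$scores[1], x$scores[2]))
  if (!is.null(x$z))
    cat(sprintf("  %d neurons x %d substeps recorded (dt = %g s)\n",
                nrow(x$z), ncol(x$z), x$dt))
  invisible(x)
}

#' Write a recorded trajectory as CSV
#'
#' Columns: `time_s`, `z_1..z_N` (m), `fired_1..fired_N`, `V_1..V_N` (V).
#'
#' @param trajectory a recorded [simulate_network()] result.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "mems_trajectory"))
  if (is.null(trajectory$z)) stopf("trajectory was not recorded")
  N <- nrow(trajectory$z)
  df <- data.frame(time_s = trajectory$time,
                   t(trajectory$z), t(trajectory$activity), t(trajectory$V))
  names(df) <- c("time_s", paste0("z_", 1:N), paste0("fired_", 1:N),
                 paste0("V_", 1:N))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Quasi-static pull-in/release hysteresis sweep
#'
#' Drives a single unconnected neuron with a triangular bias-voltage ramp,
#' letting the displacement settle at each voltage level, and records the
#' voltage at which contact occurs on the way up (pull-in) and the voltage at
#' which the proof mass detaches on the way down (release). Pull-in exceeds
#' release; the loop between them is the device's memory.
#'
#' @param params a [mems_params()] object.
#' @param v_max maximum ramp voltage (default: 20% above the static pull-in
#'   voltage).
#' @param n_levels voltage levels per ramp direction.
#' @param settle_tau settle time per level, in units of the neuron time
#'   constant. Generous by default: the escape from a marginally unstable
#'   equilibrium slows critically just above pull-in, and a short settle
#'   would bias the detected pull-in voltage upward.
#' @param substep_frac Euler step as a fraction of the time constant.
#' @return A list with `pullin_v`, `release_v`, and the swept `v_up`,
#'   `z_up`, `v_down`, `z_down` curves.
#' @export
hysteresis_sweep <- function(params, v_max = 1.2 * static_pullin_voltage(params),
                             n_levels = 600, settle_tau = 40,
                             substep_frac = 0.1) {
  stopifnot(inherits(params, "mems_params"))
  ph <- mems_derived(params)
  dt <- substep_frac * ph$tau
  nsettle <- ceiling(settle_tau / substep_frac)
  v_up <- seq(0, v_max, length.out = n_levels)
  v_down <- rev(v_up)
  z <- 0
  settle <- function(z, V) {
    for (i in seq_len(nsettle)) {
      Fd <- ph$c1 * V^2 / (ph$d - z)^2
      dz <- (dt / ph$tau) * (Fd - z)
      dz <- min(max(dz, -ph$d / 2), ph$d / 2)
      z <- min(max(z + dz, 0), ph$zc)
    }
    z
  }
  z_up <- numeric(n_levels)
  for (i in seq_along(v_up)) z_up[i] <- z <- settle(z, v_up[i])
  z_down <- numeric(n_levels)
  for (i in seq_along(v_down)) z_down[i] <- z <- settle(z, v_down[i])
  contact <- ph$zf
  pullin_v <- v_up[which(z_up >= contact)[1L]]
  rel_idx <- which(z_down < contact)[1L]
  release_v <- v_down[rel_idx]
  list(pullin_v = pullin_v, release_v = release_v,
       v_up = v_up, z_up = z_up, v_down = v_down, z_down = z_down)
}
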