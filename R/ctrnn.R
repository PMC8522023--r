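#' Reference CTRNN parameters
#'
#' The software baseline: a continuous-time recurrent neural network whose
#' activations obey `tau_i * dy_i/dt = -y_i + sum_j w_ij sigma(y_j) + h_i +
#' I_i` with logistic `sigma`. Weights are carried in the same
#' [network_weights()] container as the MEMS engine (`w_rec` as `w`, `theta`
#' as the bias `h`), so comparisons isolate the node model.
#'
#' @param weights a [network_weights()] object.
#' @param tau time constants in seconds: scalar (recycled) or length-N
#'   vector, strictly positive. Defaults to the MEMS design value 0.0017 s.
#' @return An object of class `ctrnn_params`.
#' @export
ctrnn_params <- function(weights, tau = 0.0017) {
  stopifnot(inherits(weights, "network_weights"))
  N <- nrow(weights$w_rec)
  tau <- as.numeric(tau)
  if (length(tau) == 1L) tau <- rep(tau, N)
  if (length(tau) != N || any(!is.finite(tau)) || any(tau <= 0))
    stopf("'tau' must be positive and of length 1 or %d", N)
  structure(list(weights = weights, tau = tau), class = "ctrnn_params")
}

#' @export
print.ctrnn_params <- function(x, ...) {
  cat(sprintf("Reference CTRNN: %d neurons, tau in [%g, %g] s\n",
              nrow(x$weights$w_rec), min(x$tau), max(x$tau)))
  invisible(x)
}

#' Instantaneous CTRNN state
#'
#' @param y length-N activation vector.
#' @param t elapsed time (s).
#' @return An object of class `ctrnn_state`.
#' @export
ctrnn_state <- function(y, t = 0) {
  y <- as.numeric(y)
  if (!all(is.finite(y))) stopf("activations must be finite")
  structure(list(y = y, t = t), class = "ctrnn_state")
}

#' One explicit-Euler step of the reference CTRNN
#'
#' @param state a [ctrnn_state()] object.
#' @param params a [ctrnn_params()] object.
#' @param input_t length-O input vector held constant over the step.
#' @param dt step size in seconds (> 0).
#' @return The advanced `ctrnn_state`.
#' @export
ctrnn_step <- function(state, params, input_t, dt) {
  stopifnot(inherits(state, "ctrnn_state"), inherits(params, "ctrnn_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stopf("'dt' must be a single positive number")
  w <- params$weights
  input_t <- as.numeric(input_t)
  if (length(input_t) != ncol(w$w_in))
    stopf("'input_t' must have length %d", ncol(w$w_in))
  y <- state$y
  sig <- 1 / (1 + exp(-pmin(pmax(y, -40), 40)))
  dy <- (dt / params$tau) *
    (-y + drop(w$w_rec %*% sig) + w$theta + drop(w$w_in %*% input_t))
  ctrnn_state(y + dy, state$t + dt)
}

#' Simulate the reference CTRNN over an input window
#'
#' Same contract as [simulate_network()]: each input sample is held constant
#' for its sampling interval, the network is integrated with `substeps`
#' Euler substeps per sample, and the readout is applied to the
#' window-averaged `sigma(y)` activity.
#'
#' @param input_window O x L numeric matrix.
#' @param params a [ctrnn_params()] object.
#' @param sample_rate input sampling rate in Hz.
#' @param substeps Euler substeps per sample (>= 1).
#' @param y0 initial activations (default 0).
#' @param record if `TRUE`, keep the activation trajectory.
#' @return An object of class `ctrnn_trajectory` with `scores`, `summary`
#'   and, when recorded, `time` and `y`.
#' @export
simulate_ctrnn <- function(input_window, params, sample_rate = 50,
                           substeps = 16, y0 = NULL, record = TRUE) {
  stopifnot(inherits(params, "ctrnn_params"))
  w <- params$weights
  input_window <- as.matrix(input_window)
  if (ncol(w$w_in) != nrow(input_window))
    stopf("input window must have %d channels (rows)", ncol(w$w_in))
  substeps <- as.integer(substeps)
  if (substeps < 1L) stopf("'substeps' must be >= 1")
  dt <- 1 / (sample_rate * substeps)
  if (dt >= 2 * min(params$tau))
    stopf("dt = %g exceeds the explicit-Euler stability limit 2*min(tau) = %g; use more substeps",
          dt, 2 * min(params$tau))
  N <- nrow(w$w_rec)
  if (is.null(y0)) y0 <- rep(0, N)
  res <- cpp_ctrnn_forward(input_window, w$w_rec, w$w_in, w$theta,
                           params$tau, dt, substeps, as.numeric(y0), record)
  scores <- drop(w$w_out %*% res$summary) + w$b_out
  out <- list(scores = scores, summary = drop(res$summary), dt = dt,
              substeps = substeps)
  if (record) {
    out$time <- dt * seq_len(ncol(res$y))
    out$y <- res$y
  }
  structure(out, class = "ctrnn_trajectory")
}

#' @export
print.ctrnn_trajectory <- function(x, ...) {
  cat(sprintf("CTRNN trajectory: scores = (%.4g, %.4g)\n",
              x$scores[1], x$scores[2]))
  invisible(x)
}
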