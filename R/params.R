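#' Physical parameters of an electrostatic MEMS neuron
#'
#' Bundles the lumped single-degree-of-freedom description of one
#' electrostatically actuated MEMS device used as a network neuron: a heavily
#' damped spring--mass system driven by the parallel-plate electrostatic
#' force, with a mechanical stop just short of the electrode and a firing
#' threshold expressed as a fraction of the gap. The neuron time constant is
#' `tau = 2 * zeta / omega_n`.
#'
#' The defaults place the device in the regime the network model assumes:
#' `tau = 0.0017` s, and electrode area / stiffness chosen so that the static
#' pull-in voltage is approximately 1 V, which keeps trained voltage weights
#' at order one.
#'
#' @param zeta damping ratio (dimensionless, > 0); the model assumes damping
#'   dominates inertia, so values well above 1 are typical.
#' @param omega_n natural angular frequency (rad/s, > 0).
#' @param A overlap area of the electrostatic electrodes (m^2).
#' @param k linear suspension stiffness (N/m).
#' @param eps_air permittivity of air (F/m).
#' @param d electrostatic gap between proof mass and electrode (m).
#' @param contact_frac fraction of `d` at which the mechanical stop halts the
#'   proof mass, in (0, 1).
#' @param fire_frac fraction of `d` at which the neuron counts as firing;
#'   must satisfy `0 < fire_frac <= contact_frac`.
#' @return An object of class `mems_params`.
#' @examples
#' p <- mems_params()
#' time_constant(p$zeta, p$omega_n)  # 0.0017 s
#' static_pullin_voltage(p)          # ~1 V
#' @export
mems_params <- function(zeta = 8.5, omega_n = 1e4, A = 1e-7, k = 4e-5,
                        eps_air = 8.854e-12, d = 42e-6,
                        contact_frac = 0.95, fire_frac = 0.9) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stopf("'%s' must be a single finite number", nm)
    x
  }
  for (nm in c("zeta", "omega_n", "A", "k", "eps_air", "d")) {
    v <- num1(get(nm), nm)
    if (v < 0 || (nm != "zeta" && v <= 0))
      stopf("'%s' must be positive", nm)
  }
  num1(contact_frac, "contact_frac"); num1(fire_frac, "fire_frac")
  if (!(contact_frac > 0 && contact_frac < 1))
    stopf("'contact_frac' must be in (0, 1)")
  if (!(fire_frac > 0 && fire_frac <= contact_frac))
    stopf("'fire_frac' must satisfy 0 < fire_frac <= contact_frac")
  tau <- 2 * zeta / omega_n
  if (!is.finite(tau) || tau < 0) stopf("derived time constant is not finite")
  structure(list(zeta = zeta, omega_n = omega_n, A = A, k = k,
                 eps_air = eps_air, d = d, contact_frac = contact_frac,
                 fire_frac = fire_frac),
            class = "mems_params")
}

#' @export
print.mems_params <- function(x, ...) {
  cat("MEMS neuron parameters\n")
  cat(sprintf("  zeta = %g, omega_n = %g rad/s  (tau = %g s)\n",
              x$zeta, x$omega_n, time_constant(x$zeta, x$omega_n)))
  cat(sprintf("  gap d = %g m, stop at %g d, fires at %g d\n",
              x$d, x$contact_frac, x$fire_frac))
  cat(sprintf("  A = %g m^2, k = %g N/m, eps = %g F/m\n", x$A, x$k, x$eps_air))
  cat(sprintf("  static pull-in voltage = %.4g V\n", static_pullin_voltage(x)))
  invisible(x)
}

#' Neuron time constant from the mechanical design
#'
#' The first-order response time of a heavily damped MEMS neuron is
#' `tau = 2 * zeta / omega_n`: doubling the damping ratio slows the neuron,
#' raising the natural frequency (stiffer, lighter device) speeds it up.
#'
#' @param zeta damping ratio (>= 0).
#' @param omega_n natural angular frequency in rad/s (> 0).
#' @return Time constant in seconds.
#' @examples
#' time_constant(1, 1000)        # 0.002 s
#' time_constant(8.5, 1e4)       # 0.0017 s, the package default
#' @export
time_constant <- function(zeta, omega_n) {
  if (!is.numeric(omega_n) || any(omega_n <= 0))
    stopf("'omega_n' must be positive")
  if (!is.numeric(zeta) || any(zeta < 0))
    stopf("'zeta' must be nonnegative")
  2 * zeta / omega_n
}

#' Time constant under a natural-frequency multiplier
#'
#' Scaling the natural frequency by a multiplier `P` (a design sweep over
#' stiffer or softer devices) scales the time constant to `tau_base / P`.
#' Multipliers are conventionally drawn from [p_multipliers()].
#'
#' @param tau_base baseline time constant (s, > 0).
#' @param P frequency multiplier (nonzero).
#' @return Scaled time constant in seconds.
#' @examples
#' scaled_time_constant(0.0017, 1 / 4)  # 0.0068 s
#' scaled_time_constant(0.0017, 10)     # 0.00017 s
#' @export
scaled_time_constant <- function(tau_base, P) {
  if (!is.numeric(tau_base) || any(tau_base <= 0))
    stopf("'tau_base' must be positive")
  if (!is.numeric(P) || any(P == 0)) stopf("'P' must be nonzero")
  tau_base / P
}

#' @describeIn scaled_time_constant The canonical sweep set of frequency
#'   multipliers: fractions 1/5 .. 1/2 followed by the integers 1 .. 10.
#' @export
p_multipliers <- function() c(1 / 5, 1 / 4, 1 / 3, 1 / 2, 1:10)

#' Scale the natural frequency of a parameter set
#'
#' Returns a copy of `params` with `omega_n` multiplied by `P`, so the
#' neuron time constant becomes `tau / P`. Used by time-constant sweeps.
#'
#' @param params a [mems_params()] object.
#' @param P frequency multiplier (nonzero).
#' @return A new `mems_params` object.
#' @export
scale_omega_n <- function(params, P) {
  stopifnot(inherits(params, "mems_params"))
  if (!is.numeric(P) || length(P) != 1L || P == 0)
    stopf("'P' must be a single nonzero number")
  params$omega_n <- params$omega_n * P
  params
}

#' Static pull-in voltage of one MEMS neuron
#'
#' The voltage at which the parallel-plate electrostatic force overcomes the
#' linear restoring force and the static balance loses its stable
#' equilibrium: `sqrt(8 k d^3 / (27 eps A))`. Beyond it the proof mass snaps
#' toward the electrode (pull-in); below the lower release voltage it detaches
#' again, and the gap between the two thresholds is the hysteresis the
#' network uses as memory.
#'
#' @param params a [mems_params()] object.
#' @return Pull-in voltage in volts.
#' @examples
#' static_pullin_voltage(mems_params())
#' @export
static_pullin_voltage <- function(params) {
  stopifnot(inherits(params, "mems_params"))
  sqrt(8 * params$k * params$d^3 / (27 * params$eps_air * params$A))
}

#' Read and write device parameters as JSON
#'
#' @param params a [mems_params()] object.
#' @param path JSON file path.
#' @return `path` (write) or the restored `mems_params` (read).
#' @export
write_mems_params <- function(params, path) {
  stopifnot(inherits(params, "mems_params"))
  jsonlite::write_json(c(list(format = "memsctrnn-params-1"),
                         unclass(params)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mems_params
#' @export
read_mems_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "memsctrnn-params-1"))
    stopf("unrecognized parameter file format")
  do.call(mems_params, x[setdiff(names(x), "format")])
}

# natural magnitude of input weights: they act through 1/omega_n^2, so a
# weight of ~2*d*omega_n^2 moves the proof mass across the gap for a
# unit-scale input sample
input_weight_scale <- function(params) 2 * params$d * params$omega_n^2

# derived quantities used by the integrators
mems_derived <- function(params) {
  list(tau = 2 * params$zeta / params$omega_n,
       c1 = params$eps_air * params$A / (2 * params$k),
       d = params$d,
       zc = params$contact_frac * params$d,
       zf = params$fire_frac * params$d,
       invw2 = 1 / params$omega_n^2)
}
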