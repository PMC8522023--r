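#' Capacitor-switching power model
#'
#' A MEMS neuron switches by charging its device capacitance; the energy per
#' switching event is `C * V_op^2 / 2`, so a neuron switching at `f_switch`
#' events per second dissipates `f_switch * C * V_op^2 / 2` watts. The
#' defaults (0.5 pF, 5 V, 100 Hz worst case) give 0.625 nW per neuron.
#'
#' @param C switch capacitance in farads (>= 0).
#' @param V_op operating voltage in volts (>= 0).
#' @param f_switch worst-case switching frequency in hertz (>= 0).
#' @return An object of class `power_model`.
#' @seealso [network_power()]
#' @export
power_model <- function(C = 0.5e-12, V_op = 5, f_switch = 100) {
  for (nm in c("C", "V_op", "f_switch")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stopf("'%s' must be a single nonnegative number", nm)
  }
  structure(list(C = C, V_op = V_op, f_switch = f_switch),
            class = "power_model")
}

#' @export
print.power_model <- function(x, ...) {
  cat(sprintf("Switching power model: C = %g F, V_op = %g V, f = %g Hz\n",
              x$C, x$V_op, x$f_switch))
  cat(sprintf("  per neuron: %g W\n", network_power(x, 1)))
  invisible(x)
}

#' Switching power of a MEMS network
#'
#' Total power of `n_neurons` identical neurons under the capacitor-charging
#' model: `n_neurons * (C * V_op^2 / 2) * f_switch`. With the default model a
#' single neuron draws 0.625 nW and a 100-neuron network 6.25 nW.
#'
#' @param model a [power_model()] object.
#' @param n_neurons number of neurons (>= 0).
#' @return Power in watts.
#' @examples
#' network_power(power_model(), 1)    # 6.25e-10 W = 0.625 nW
#' network_power(power_model(), 100)  # 6.25e-09 W = 6.25 nW
#' @export
network_power <- function(model, n_neurons) {
  stopifnot(inherits(model, "power_model"))
  if (!is.numeric(n_neurons) || any(n_neurons < 0))
    stopf("'n_neurons' must be nonnegative")
  n_neurons * (0.5 * model$C * model$V_op^2) * model$f_switch
}
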