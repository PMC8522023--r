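#' Network weight container
#'
#' Holds all trainable quantities of a MEMS-CTRNN (or reference CTRNN):
#' the recurrent neuron-to-neuron voltage coupling matrix, the input weights
#' (nonzero rows only for the input-layer neurons), the per-neuron bias
#' voltages, and the two-way dense readout. Total network size is
#' `N = n_inputs + n_hidden` (one input neuron per channel plus the computing
#' layer); `w_out` maps the per-neuron activity summary to two class scores.
#'
#' @param w_rec N x N recurrent weight matrix.
#' @param w_in N x O input weight matrix; rows beyond `n_input` must be zero.
#' @param theta length-N bias vector (volts for the MEMS engine).
#' @param w_out 2 x N readout weight matrix.
#' @param b_out length-2 readout bias.
#' @param n_input number of input-layer neurons (leading rows of `w_in`).
#' @return An object of class `network_weights`.
#' @seealso [init_network()]
#' @export
network_weights <- function(w_rec, w_in, theta, w_out, b_out,
                            n_input = nrow(w_in) - 0L) {
  w_rec <- as.matrix(w_rec); w_in <- as.matrix(w_in)
  theta <- as.numeric(theta); b_out <- as.numeric(b_out)
  w_out <- as.matrix(w_out)
  N <- nrow(w_rec)
  if (ncol(w_rec) != N) stopf("'w_rec' must be square")
  if (nrow(w_in) != N) stopf("'w_in' must have %d rows", N)
  if (length(theta) != N) stopf("'theta' must have length %d", N)
  if (!identical(dim(w_out), c(2L, N))) stopf("'w_out' must be 2 x %d", N)
  if (length(b_out) != 2L) stopf("'b_out' must have length 2")
  n_input <- as.integer(n_input)
  if (n_input < 0L || n_input > N) stopf("invalid 'n_input'")
  vals <- c(w_rec, w_in, theta, w_out, b_out)
  if (!all(is.finite(vals))) stopf("all weight entries must be finite")
  if (n_input < N && any(w_in[seq.int(n_input + 1L, N), , drop = FALSE] != 0))
    stopf("'w_in' rows beyond the input layer must be zero")
  structure(list(w_rec = w_rec, w_in = w_in, theta = theta,
                 w_out = w_out, b_out = b_out, n_input = n_input),
            class = "network_weights")
}

#' @export
print.network_weights <- function(x, ...) {
  N <- nrow(x$w_rec)
  cat(sprintf("Network weights: %d neurons (%d input + %d hidden), %d channels\n",
              N, x$n_input, N - x$n_input, ncol(x$w_in)))
  invisible(x)
}

#' Random initial weights
#'
#' Draws uniform small-random weights in `[-init_scale, init_scale]` for a
#' network of `n_inputs` input-layer neurons (one per channel, fully
#' connected to the channels) plus `n_hidden` computing neurons, with a dense
#' two-way readout. For the MEMS engine the input weights are drawn on the
#' larger scale `init_scale * 2 * d * omega_n^2` because they act through
#' the `1/omega_n^2` input normalization of the displacement equation; at
#' this scale unit-amplitude input samples can drive an input neuron across
#' the gap and into pull-in, which is the operating regime of the network.
#'
#' @param n_hidden number of computing neurons (>= 1).
#' @param n_inputs number of input channels / input-layer neurons (>= 1).
#' @param seed integer RNG seed; identical seeds give identical weights.
#' @param init_scale half-width of the uniform initialization.
#' @param engine `"mems"` or `"ctrnn"` (controls the input-weight scale).
#' @param params [mems_params()] supplying `d` and `omega_n` for the MEMS
#'   input-weight scale.
#' @return A [network_weights()] object.
#' @examples
#' w <- init_network(6, 3, seed = 1)
#' dim(w$w_rec)  # 9 x 9
#' @export
init_network <- function(n_hidden, n_inputs, seed = 1L, init_scale = 0.5,
                         engine = c("mems", "ctrnn"),
                         params = mems_params()) {
  engine <- match.arg(engine)
  n_hidden <- as.integer(n_hidden); n_inputs <- as.integer(n_inputs)
  if (n_hidden < 1L || n_inputs < 1L)
    stopf("'n_hidden' and 'n_inputs' must be positive")
  N <- n_inputs + n_hidden
  # input weights need to span the node nonlinearity: across the gap for
  # MEMS, across the sigmoid's dynamic range for the reference CTRNN
  s_in <- if (engine == "mems") init_scale * input_weight_scale(params)
          else 4 * init_scale
  with_seed(seed, {
    w_rec <- matrix(runif(N * N, -init_scale, init_scale), N, N)
    w_in <- matrix(0, N, n_inputs)
    w_in[seq_len(n_inputs), ] <- runif(n_inputs * n_inputs, -s_in, s_in)
    theta <- runif(N, -init_scale, init_scale)
    w_out <- matrix(runif(2 * N, -init_scale, init_scale), 2, N)
    b_out <- runif(2, -init_scale, init_scale)
    network_weights(w_rec, w_in, theta, w_out, b_out, n_input = n_inputs)
  })
}

#' Write network weights to a directory
#'
#' Serializes a [network_weights()] object as CSV matrices plus a JSON
#' manifest (`weights.json`) recording shapes and the input-layer size.
#'
#' @param weights a [network_weights()] object.
#' @param dir directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_network_weights <- function(weights, dir) {
  stopifnot(inherits(weights, "network_weights"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f)
    write.table(m, file.path(dir, f), sep = ",", row.names = FALSE,
                col.names = FALSE)
  wm(weights$w_rec, "w_rec.csv"); wm(weights$w_in, "w_in.csv")
  wm(matrix(weights$theta, ncol = 1), "theta.csv")
  wm(weights$w_out, "w_out.csv")
  wm(matrix(weights$b_out, ncol = 1), "b_out.csv")
  jsonlite::write_json(list(n_neurons = nrow(weights$w_rec),
                            n_input = weights$n_input,
                            n_channels = ncol(weights$w_in),
                            format = "memsctrnn-weights-1"),
                       file.path(dir, "weights.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_network_weights
#' @export
read_network_weights <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "weights.json"))
  if (!identical(man$format, "memsctrnn-weights-1"))
    stopf("unrecognized weights manifest format")
  rm_ <- function(f) {
    m <- as.matrix(read.csv(file.path(dir, f), header = FALSE))
    dimnames(m) <- NULL
    m
  }
  network_weights(rm_("w_rec.csv"), rm_("w_in.csv"),
                  drop(rm_("theta.csv")), rm_("w_out.csv"),
                  drop(rm_("b_out.csv")), n_input = man$n_input)
}
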