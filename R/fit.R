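#' Fit a MEMS-CTRNN (or reference CTRNN) activity detector
#'
#' The main fitting front end. Takes a labeled training dataset of windowed
#' multi-channel signals, optionally standardizes non-quantized channels
#' (training statistics are stored in the model and reused at prediction
#' time), trains the network by backpropagation through time
#' ([train_network()]), and returns a classed model object with the usual
#' methods: `print`, `summary`, `coef`, `predict`, `plot`, `fitted`,
#' `residuals`, `simulate`.
#'
#' @param x a labeled training [windowed_dataset()] (quantized or raw).
#' @param engine `"mems"` for the physical MEMS network, `"ctrnn"` for the
#'   software reference.
#' @param n_hidden number of computing (hidden-layer) neurons.
#' @param params a [mems_params()] object.
#' @param control a [train_config()].
#' @param standardize standardize raw channels with training statistics
#'   (default: yes unless the data are ternary-quantized).
#' @param tau CTRNN time constant(s) (engine `"ctrnn"`); defaults to the
#'   MEMS design value `2 zeta / omega_n`.
#' @return An object of class `mems_ctrnn`.
#' @examples
#' \donttest{
#' bench <- generate_benchmark(synth_config(duration = 60, seed = 1),
#'                             subjects = 2)
#' parts <- split_dataset(bench, seed = 1)
#' train <- quantize_dataset(parts$train)
#' fit <- mems_ctrnn(train, n_hidden = 3,
#'                   control = train_config(epochs = 3))
#' print(fit)
#' }
#' @export
mems_ctrnn <- function(x, engine = c("mems", "ctrnn"), n_hidden = 6L,
                       params = mems_params(), control = train_config(),
                       standardize = !isTRUE(x$quantized), tau = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(x, "windowed_dataset"))
  if (any(is.na(x$labels))) stopf("training dataset must be labeled")
  scaling <- NULL
  if (standardize && !isTRUE(x$quantized)) {
    scaling <- fit_standardizer(x)
    x <- standardize_dataset(x, scaling)
  }
  res <- train_network(x, config = control, engine = engine, params = params,
                       n_hidden = n_hidden, tau = tau)
  structure(list(weights = res$weights, history = res$history,
                 engine = engine, params = params, control = control,
                 tau = tau, n_hidden = as.integer(n_hidden),
                 channels = x$channels, quantized = isTRUE(x$quantized),
                 epsilon = x$epsilon, scaling = scaling,
                 sample_rate = x$sample_rate,
                 train_labels = x$labels, call = match.call()),
            class = "mems_ctrnn")
}

# apply the model's stored preprocessing to new data
prepare_newdata <- function(object, newdata) {
  if (!inherits(newdata, "windowed_dataset")) {
    X <- as_window_array(newdata)
    newdata <- windowed_dataset(X, sample_rate = object$sample_rate,
                                quantized = object$quantized)
  }
  if (object$quantized && !isTRUE(newdata$quantized)) {
    if (is.null(object$epsilon))
      stopf("model was trained on quantized data but carries no thresholds; quantize 'newdata' first")
    newdata <- quantize_dataset(newdata,
                                quantizer_config(object$epsilon))
  }
  if (!object$quantized && isTRUE(newdata$quantized))
    stopf("model was trained on raw data; 'newdata' is quantized")
  if (!is.null(object$scaling))
    newdata <- standardize_dataset(newdata, object$scaling)
  if (dim(newdata$windows)[1L] != length(object$channels))
    stopf("'newdata' must have %d channels", length(object$channels))
  newdata
}

#' Predict method for MEMS-CTRNN models
#'
#' Applies the model's stored preprocessing (quantization thresholds or
#' standardization statistics fitted on the training split) and the
#' hard-step simulator, so predictions reflect the physical network.
#'
#' @param object a fitted [mems_ctrnn()] model.
#' @param newdata a [windowed_dataset()], matrix (one window) or O x l x B
#'   array.
#' @param type `"class"` (0/1), `"prob"` (positive-class probability) or
#'   `"score"` (both raw class scores).
#' @param ... unused.
#' @return A vector (class or probability) or 2 x B score matrix.
#' @export
predict.mems_ctrnn <- function(object, newdata,
                               type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  newdata <- prepare_newdata(object, newdata)
  sc <- hard_scores(newdata, object$weights, object$params, object$engine,
                    object$control, newdata$sample_rate, object$tau)
  if (type == "score") return(sc)
  p <- 1 / (1 + exp(sc[1L, ] - sc[2L, ]))
  if (type == "prob") p else as.integer(sc[2L, ] > sc[1L, ])
}

#' @export
print.mems_ctrnn <- function(x, ...) {
  N <- nrow(x$weights$w_rec)
  cat(sprintf("%s activity detector: %d neurons (%d input + %d hidden)\n",
              if (x$engine == "mems") "MEMS-CTRNN" else "CTRNN",
              N, x$weights$n_input, x$n_hidden))
  cat(sprintf("  inputs: %s (%s)\n", paste(x$channels, collapse = ", "),
              if (x$quantized) "ternary-quantized" else "standardized raw"))
  if (nrow(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs; final loss %.4f, training accuracy %.3f\n",
                nrow(x$history), h$loss, h$accuracy))
  }
  invisible(x)
}

#' @export
summary.mems_ctrnn <- function(object, ...) {
  out <- list(engine = object$engine, n_hidden = object$n_hidden,
              n_neurons = nrow(object$weights$w_rec),
              channels = object$channels, quantized = object$quantized,
              history = object$history,
              tau = if (object$engine == "mems")
                time_constant(object$params$zeta, object$params$omega_n)
              else object$tau %||% time_constant(object$params$zeta,
                                                 object$params$omega_n),
              pullin_v = static_pullin_voltage(object$params),
              power_nw = network_power(power_model(),
                                       nrow(object$weights$w_rec)) * 1e9,
              train_positive = mean(object$train_labels == 1L))
  class(out) <- "summary.mems_ctrnn"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.summary.mems_ctrnn <- function(x, ...) {
  cat(sprintf("%s activity detector\n",
              if (x$engine == "mems") "MEMS-CTRNN" else "Reference CTRNN"))
  cat(sprintf("  neurons: %d (%d hidden); channels: %s; inputs: %s\n",
              x$n_neurons, x$n_hidden, paste(x$channels, collapse = ","),
              if (x$quantized) "ternary" else "raw"))
  cat(sprintf("  neuron time constant: %g s\n", x$tau[1L]))
  if (x$engine == "mems")
    cat(sprintf("  static pull-in voltage: %.4g V; switching power at 0.5 pF/5 V/100 Hz: %.4g nW\n",
                x$pullin_v, x$power_nw))
  cat(sprintf("  training positives: %.1f%%\n", 100 * x$train_positive))
  if (nrow(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  training: %d epochs, final loss %.4f, accuracy %.3f\n",
                nrow(x$history), h$loss, h$accuracy))
  }
  invisible(x)
}

#' @export
coef.mems_ctrnn <- function(object, ...) {
  w <- object$weights
  list(w_rec = w$w_rec, w_in = w$w_in, theta = w$theta, w_out = w$w_out,
       b_out = w$b_out)
}

#' @export
fitted.mems_ctrnn <- function(object, ...) {
  stopf("fitted values require the training data; call predict(object, traindata, type = 'prob')")
}

#' Residuals of a MEMS-CTRNN model
#'
#' Response residuals `y - p_hat` on a labeled dataset (hard-step
#' predictions).
#'
#' @param object a fitted model.
#' @param newdata a labeled [windowed_dataset()].
#' @param ... unused.
#' @return Numeric residual vector.
#' @export
residuals.mems_ctrnn <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "windowed_dataset"))
  if (any(is.na(newdata$labels))) stopf("'newdata' must be labeled")
  newdata$labels - predict(object, newdata, type = "prob")
}

#' Plot training history
#'
#' Loss and training accuracy per epoch.
#'
#' @param x a fitted [mems_ctrnn()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mems_ctrnn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stopf("no training history (epochs = 0)")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", ...)
  graphics::plot(h$epoch, h$accuracy, type = "l", xlab = "epoch",
                 ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' Simulate labels from a fitted detector
#'
#' Draws Bernoulli class labels from the model's predicted positive-class
#' probabilities for the given windows.
#'
#' @param object a fitted [mems_ctrnn()] model.
#' @param nsim number of simulated label sets.
#' @param seed optional RNG seed.
#' @param newdata windows to predict on.
#' @param ... unused.
#' @return A data frame with `nsim` columns of 0/1 labels.
#' @export
simulate.mems_ctrnn <- function(object, nsim = 1, seed = NULL, newdata,
                                ...) {
  p <- predict(object, newdata, type = "prob")
  draw <- function() rbinom(length(p), 1L, p)
  out <- if (is.null(seed)) replicate(nsim, draw())
         else with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(matrix(out, ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
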