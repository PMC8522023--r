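#' Training configuration
#'
#' Settings for backpropagation-through-time training of the discretized
#' network. Training uses the smooth forward pass (logistic surrogate of
#' steepness `surrogate_beta` in place of the unit-step firing) and
#' mini-batch gradient descent with momentum and gradient-norm clipping on
#' the mean cross-entropy of the softmaxed class scores. Evaluation always
#' uses the hard-step simulator so reported accuracy reflects the physical
#' model.
#'
#' Because the input weights act through the `1/omega_n^2` normalization of
#' the displacement equation, the optimizer rescales each weight group to a
#' dimensionless magnitude before clipping and stepping; this is plain
#' clipped SGD on normalized parameters.
#'
#' @param substeps Euler substeps per input sample (dt = 1 / (rate *
#'   substeps); must keep dt below twice the neuron time constant).
#' @param surrogate_beta initial steepness of the logistic firing surrogate
#'   (1/m for the MEMS engine). The default spreads the transition over
#'   roughly the full gap so that sub-pull-in displacements (which sit below
#'   a third of the gap) still receive gradient; large values recover the
#'   hard step.
#' @param beta_growth factor by which the surrogate steepness grows
#'   (geometrically per epoch) over the course of training, annealing the
#'   smooth forward pass toward the hard-step simulator so that the trained
#'   solution transfers to hard-mode evaluation. 1 disables annealing.
#' @param lr learning rate.
#' @param momentum heavy-ball momentum coefficient.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param grad_clip maximum (rescaled) gradient norm.
#' @param seed RNG seed for initialization and batch shuffling.
#' @param init_scale half-width of the uniform weight initialization.
#' @param max_step_frac per-substep displacement cap as a fraction of the
#'   gap `d` (MEMS engine).
#' @return An object of class `train_config`.
#' @export
train_config <- function(substeps = 16L, surrogate_beta = 1.2e5,
                         beta_growth = 30, lr = 0.1, momentum = 0.9,
                         epochs = 25L, batch_size = 32L, grad_clip = 5,
                         seed = 1L, init_scale = 0.5, max_step_frac = 0.5) {
  for (nm in c("substeps", "surrogate_beta", "beta_growth", "lr", "epochs",
               "batch_size", "grad_clip", "init_scale", "max_step_frac")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stopf("'%s' must be a single nonnegative finite number", nm)
  }
  if (substeps < 1L) stopf("'substeps' must be >= 1")
  if (momentum < 0 || momentum >= 1) stopf("'momentum' must be in [0, 1)")
  if (beta_growth < 1) stopf("'beta_growth' must be >= 1")
  structure(list(substeps = as.integer(substeps),
                 surrogate_beta = surrogate_beta, beta_growth = beta_growth,
                 lr = lr,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), grad_clip = grad_clip,
                 seed = as.integer(seed), init_scale = init_scale,
                 max_step_frac = max_step_frac),
            class = "train_config")
}

#' Read and write a training configuration as JSON
#'
#' @param config a [train_config()].
#' @param path JSON file path.
#' @return `path` (write) or the restored `train_config` (read).
#' @export
write_train_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  jsonlite::write_json(c(list(format = "memsctrnn-train-config-1"),
                         unclass(config)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "memsctrnn-train-config-1"))
    stopf("unrecognized training-config file format")
  do.call(train_config, x[setdiff(names(x), "format")])
}

# dataset/array -> O x l x B cube
as_window_array <- function(x) {
  if (inherits(x, "windowed_dataset")) return(x$windows)
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stopf("expected a windowed_dataset, a matrix, or a 3-d array")
}

# shared plumbing: physical constants + dt for an engine
engine_setup <- function(engine, params, config, sample_rate, tau = NULL,
                         n_neurons = NULL) {
  dt <- 1 / (sample_rate * config$substeps)
  if (engine == "mems") {
    ph <- mems_derived(params)
    if (dt >= 2 * ph$tau)
      stopf("dt = %g exceeds the stability limit 2*tau = %g; increase substeps",
            dt, 2 * ph$tau)
    ph$dt <- dt
    ph$max_step <- config$max_step_frac * params$d
    ph
  } else {
    if (is.null(tau)) tau <- time_constant(params$zeta, params$omega_n)
    tau <- rep_len(as.numeric(tau), n_neurons)
    if (dt >= 2 * min(tau))
      stopf("dt = %g exceeds the stability limit 2*min(tau) = %g; increase substeps",
            dt, 2 * min(tau))
    list(tau = tau, dt = dt)
  }
}

#' Differentiable (surrogate) forward pass
#'
#' Identical to [simulate_network()] except that the unit-step firing is
#' replaced everywhere by a logistic of steepness `surrogate_beta`, making
#' the window-to-scores map differentiable; as the steepness grows the
#' scores converge to the hard-step simulator's. Used internally by training
#' and exposed for gradient checking.
#'
#' @param x a [windowed_dataset()], O x l matrix, or O x l x B array.
#' @param weights a [network_weights()] object.
#' @param params a [mems_params()] object.
#' @param config a [train_config()].
#' @param sample_rate sampling rate (Hz); taken from the dataset when
#'   available.
#' @return 2 x B matrix of class scores.
#' @export
forward_smooth <- function(x, weights, params = mems_params(),
                           config = train_config(), sample_rate = NULL) {
  stopifnot(inherits(weights, "network_weights"),
            inherits(params, "mems_params"))
  if (is.null(sample_rate))
    sample_rate <- if (inherits(x, "windowed_dataset")) x$sample_rate else 50
  X <- as_window_array(x)
  ph <- engine_setup("mems", params, config, sample_rate)
  res <- cpp_mems_train_batch(X, rep(0L, dim(X)[3L]), weights$w_rec,
                              weights$w_in, weights$theta, weights$w_out,
                              weights$b_out, ph$tau, ph$c1, ph$d, ph$zc,
                              ph$zf, ph$invw2, ph$dt, config$substeps,
                              config$surrogate_beta, ph$max_step, FALSE)
  res$scores
}

# hard-mode class scores for a batch
hard_scores <- function(x, weights, params, engine, config, sample_rate,
                        tau = NULL) {
  X <- as_window_array(x)
  if (engine == "mems") {
    ph <- engine_setup("mems", params, config, sample_rate)
    summ <- cpp_mems_forward_batch(X, weights$w_rec, weights$w_in,
                                   weights$theta, ph$tau, ph$c1, ph$d, ph$zc,
                                   ph$zf, ph$invw2, ph$dt, config$substeps,
                                   TRUE, config$surrogate_beta, ph$max_step)
  } else {
    es <- engine_setup("ctrnn", params, config, sample_rate, tau,
                       nrow(weights$w_rec))
    summ <- cpp_ctrnn_forward_batch(X, weights$w_rec, weights$w_in,
                                    weights$theta, es$tau, es$dt,
                                    config$substeps)
  }
  weights$w_out %*% summ + weights$b_out
}

#' Train a network by backpropagation through time
#'
#' Minimizes the mean cross-entropy of the softmaxed class scores over a
#' labeled window dataset by mini-batch gradient descent with momentum and
#' gradient-norm clipping, backpropagating through the discretized dynamics
#' (smooth surrogate forward pass). Fully seeded: identical data, config and
#' seed give identical trained weights. With `epochs = 0` the initial
#' weights are returned unchanged.
#'
#' @param dataset a labeled [windowed_dataset()] containing both classes.
#' @param config a [train_config()].
#' @param engine `"mems"` (physical model) or `"ctrnn"` (software
#'   reference).
#' @param params a [mems_params()] object (also supplies the default CTRNN
#'   time constant through `tau = 2 zeta / omega_n`).
#' @param n_hidden hidden-layer size used when `weights` is `NULL`.
#' @param weights optional initial [network_weights()]; default: seeded
#'   [init_network()].
#' @param tau CTRNN time constant(s); default: the MEMS design value.
#' @return A list with the trained `weights` and a `history` data frame
#'   (epoch, loss, accuracy).
#' @seealso [mems_ctrnn()] for the model-object front end.
#' @export
train_network <- function(dataset, config = train_config(),
                          engine = c("mems", "ctrnn"),
                          params = mems_params(), n_hidden = 6L,
                          weights = NULL, tau = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(dataset, "windowed_dataset"),
            inherits(config, "train_config"),
            inherits(params, "mems_params"))
  y <- dataset$labels
  if (any(is.na(y))) stopf("dataset must be labeled")
  X <- dataset$windows
  O <- dim(X)[1L]; B <- dim(X)[3L]
  if (is.null(weights))
    weights <- init_network(n_hidden, O, seed = config$seed,
                            init_scale = config$init_scale, engine = engine,
                            params = params)
  if (config$epochs == 0L)
    return(list(weights = weights,
                history = data.frame(epoch = integer(), loss = numeric(),
                                     accuracy = numeric())))
  if (length(unique(y)) < 2L)
    stopf("training requires both classes to be present")

  sr <- dataset$sample_rate
  if (engine == "mems") {
    ph <- engine_setup("mems", params, config, sr)
  } else {
    es <- engine_setup("ctrnn", params, config, sr, tau, nrow(weights$w_rec))
  }
  # group scales: dimensionless magnitude of each weight group
  s_in <- if (engine == "mems") input_weight_scale(params) else 4
  groups <- c("w_rec", "w_in", "theta", "w_out", "b_out")
  scale_of <- c(w_rec = 1, w_in = s_in, theta = 1, w_out = 1, b_out = 1)
  in_mask <- matrix(0, nrow(weights$w_in), O)
  in_mask[seq_len(weights$n_input), ] <- 1
  vel <- list(w_rec = weights$w_rec * 0, w_in = weights$w_in * 0,
              theta = weights$theta * 0, w_out = weights$w_out * 0,
              b_out = weights$b_out * 0)

  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      beta_ep <- config$surrogate_beta *
        config$beta_growth^(if (config$epochs > 1L)
          (ep - 1) / (config$epochs - 1) else 1)
      ord <- sample.int(B)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_hits <- 0
      for (bi in batches) {
        Xb <- X[, , bi, drop = FALSE]
        yb <- as.integer(y[bi])
        if (engine == "mems") {
          g <- cpp_mems_train_batch(Xb, yb, weights$w_rec, weights$w_in,
                                    weights$theta, weights$w_out,
                                    weights$b_out, ph$tau, ph$c1, ph$d,
                                    ph$zc, ph$zf, ph$invw2, ph$dt,
                                    config$substeps, beta_ep,
                                    ph$max_step, TRUE)
          grads <- list(w_rec = g$gW, w_in = g$gWin * in_mask,
                        theta = drop(g$gtheta), w_out = g$gWout,
                        b_out = drop(g$gbout))
        } else {
          g <- cpp_ctrnn_train_batch(Xb, yb, weights$w_rec, weights$w_in,
                                     weights$theta, weights$w_out,
                                     weights$b_out, es$tau, es$dt,
                                     config$substeps, TRUE)
          grads <- list(w_rec = g$gW, w_in = g$gWin * in_mask,
                        theta = drop(g$gh), w_out = g$gWout,
                        b_out = drop(g$gbout))
        }
        if (!is.finite(g$loss))
          stopf("training diverged (loss = %s) at epoch %d; reduce lr or increase substeps",
                format(g$loss), ep)
        # rescale to dimensionless units, clip the global norm, step
        gs <- lapply(groups, function(nm) grads[[nm]] * scale_of[[nm]])
        names(gs) <- groups
        nrm <- sqrt(sum(vapply(gs, function(m) sum(m^2), numeric(1))))
        if (is.finite(nrm) && nrm > config$grad_clip)
          gs <- lapply(gs, function(m) m * (config$grad_clip / nrm))
        for (nm in groups) {
          vel[[nm]] <- config$momentum * vel[[nm]] + gs[[nm]]
          weights[[nm]] <- weights[[nm]] -
            config$lr * scale_of[[nm]] * vel[[nm]]
        }
        ep_loss <- ep_loss + g$loss * length(bi)
        ep_hits <- ep_hits + sum(g$pred == yb)
      }
      history$loss[ep] <- ep_loss / B
      history$accuracy[ep] <- ep_hits / B
    }
  })
  list(weights = weights, history = history)
}
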