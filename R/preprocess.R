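#' Quantization threshold from a signal
#'
#' The ternary quantizer's threshold for a channel is `mean(x) + sd(x) / 2`,
#' the rule of thumb for separating genuine rises and falls from noise in
#' normalized accelerometer streams. For a standard normal signal the rule
#' gives approximately 0.5. Constant signals (sd = 0) are allowed and return
#' the constant.
#'
#' @param channel numeric vector of at least 2 samples.
#' @return The threshold (signal units).
#' @examples
#' select_epsilon(c(0.6, 1.4))  # mean 1, sd ~0.57
#' @export
select_epsilon <- function(channel) {
  channel <- as.numeric(channel)
  if (length(channel) < 2L) stopf("'channel' must have at least 2 samples")
  s <- sd(channel)
  if (!is.finite(s)) s <- 0
  mean(channel) + s / 2
}

#' Ternary quantization of a signal
#'
#' Maps each consecutive pair of samples to one of three symbols using
#' threshold `epsilon`: `+1` when `a[t] > a[t+1] + epsilon`, `-1` when
#' `a[t] < a[t+1] - epsilon`, and `0` when `|a[t+1] - a[t]| <= epsilon`. The
#' output has length `n - 1`. Note the convention: `+1` flags a step *down*
#' to the next sample and `-1` a step up; only the three-symbol trend
#' pattern matters to the downstream network, and the mapping is kept
#' in this fixed orientation for reproducibility.
#'
#' @param channel numeric vector of length n >= 2 (or an O x n matrix,
#'   quantized row-wise with per-row `epsilon`).
#' @param epsilon nonnegative threshold; for a matrix, scalar or one value
#'   per row.
#' @return Integer vector of length n - 1 (or O x (n-1) matrix) with values
#'   in `{-1, 0, 1}`.
#' @examples
#' quantize(c(2, 1), 0.5)    # +1
#' quantize(c(1, 1.3), 0.5)  # 0
#' @export
quantize <- function(channel, epsilon) {
  if (any(epsilon < 0)) stopf("'epsilon' must be nonnegative")
  if (is.matrix(channel)) {
    if (ncol(channel) < 2L) stopf("need at least 2 samples")
    eps <- rep_len(epsilon, nrow(channel))
    out <- t(vapply(seq_len(nrow(channel)),
                    function(i) quantize(channel[i, ], eps[i]),
                    integer(ncol(channel) - 1L)))
    rownames(out) <- rownames(channel)
    return(out)
  }
  channel <- as.numeric(channel)
  n <- length(channel)
  if (n < 2L) stopf("need at least 2 samples")
  a <- channel[-n]
  b <- channel[-1L]
  out <- integer(n - 1L)
  out[a > b + epsilon] <- 1L
  out[a < b - epsilon] <- -1L
  out
}

#' Slice a recording into fixed-length windows
#'
#' Slides a window of `l` samples with the given stride over a multi-channel
#' series and records, for each window, the majority non-null activity and
#' the fraction of window samples it occupies. Yields
#' `floor((T - l) / stride) + 1` windows.
#'
#' @param series O x T numeric matrix (or a recording object from
#'   [generate_recording()] / [read_raw_recordings()], from which
#'   annotations and sample rate are taken).
#' @param annotations length-T integer vector of per-sample activity ids
#'   (0 = null class). Ignored when `series` is a recording.
#' @param l window length in samples (1 <= l <= T). When the windows will be
#'   ternary-quantized afterwards, pass the post-quantization length plus
#'   one.
#' @param stride hop between window starts in samples (>= 1).
#' @param subject subject id stored in the metadata.
#' @param sample_rate sampling rate (Hz).
#' @return An unlabeled [windowed_dataset()].
#' @examples
#' x <- matrix(rnorm(300), nrow = 3)
#' ds <- make_windows(x, rep(0L, 100), l = 20, stride = 20)
#' n_windows(ds)  # 5
#' @export
make_windows <- function(series, annotations = NULL, l = 128, stride = 64,
                         subject = NA_integer_, sample_rate = 50) {
  if (inherits(series, "har_recording")) {
    annotations <- annotation_vector(series)
    sample_rate <- series$sample_rate
    if (is.na(subject)) subject <- series$subject
    series <- series$signals
  }
  series <- as.matrix(series)
  O <- nrow(series); Tn <- ncol(series)
  l <- as.integer(l); stride <- as.integer(stride)
  if (l < 1L || l > Tn) stopf("'l' must satisfy 1 <= l <= %d", Tn)
  if (stride < 1L) stopf("'stride' must be >= 1")
  if (is.null(annotations)) annotations <- rep(0L, Tn)
  annotations <- as.integer(annotations)
  if (length(annotations) != Tn)
    stopf("'annotations' must have length %d", Tn)
  starts <- seq.int(1L, Tn - l + 1L, by = stride)
  n <- length(starts)
  windows <- array(0, dim = c(O, l, n))
  act <- integer(n); frac <- numeric(n)
  for (j in seq_len(n)) {
    idx <- starts[j]:(starts[j] + l - 1L)
    windows[, , j] <- series[, idx, drop = FALSE]
    ann <- annotations[idx]
    ann <- ann[ann != 0L]
    if (length(ann)) {
      tab <- tabulate(ann)
      act[j] <- which.max(tab)
      frac[j] <- max(tab) / l
    }
  }
  meta <- data.frame(subject = rep(as.integer(subject), n), activity = act,
                     fraction = frac, origin = rep("original", n))
  windowed_dataset(windows, meta = meta, sample_rate = sample_rate,
                   channels = rownames(series))
}

#' Binary window label from the activity fraction
#'
#' A window belongs to the activity of interest when the fraction of its
#' samples annotated with that activity reaches the labeling threshold
#' (inclusive: a window at exactly the threshold is positive).
#'
#' @param fraction fraction of in-window samples belonging to the activity,
#'   in `[0, 1]`.
#' @param threshold labeling threshold in `[0, 1]` (default 0.75).
#' @return Integer 0/1 label(s).
#' @examples
#' label_window(16 / 20)         # 1
#' label_window(10 / 20)         # 0
#' label_window(0.75, 0.75)      # 1 (inclusive boundary)
#' @export
label_window <- function(fraction, threshold = 0.75) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stopf("'fraction' must lie in [0, 1]")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stopf("'threshold' must be a single number in [0, 1]")
  as.integer(fraction >= threshold)
}

#' Label a dataset for one-vs-null detection of a target activity
#'
#' Marks a window positive when its majority non-null activity equals the
#' target and occupies at least `threshold` of the window. Thresholds below
#' 0.5 are rejected because the majority-activity summary kept in the window
#' metadata only identifies fractions at or above one half.
#'
#' @param ds a [windowed_dataset()].
#' @param activity target activity id (integer) or name when the dataset
#'   carries an activity palette attribute.
#' @param threshold labeling threshold in `[0.5, 1]`.
#' @return The dataset with 0/1 labels.
#' @export
label_dataset <- function(ds, activity, threshold = 0.75) {
  stopifnot(inherits(ds, "windowed_dataset"))
  if (threshold < 0.5 || threshold > 1)
    stopf("'threshold' must lie in [0.5, 1]")
  if (is.character(activity)) {
    pal <- ds$activities
    if (is.null(pal)) stopf("dataset has no activity palette; pass an id")
    activity <- match(activity, pal)
    if (is.na(activity)) stopf("unknown activity name")
  }
  lab <- ifelse(ds$meta$activity == activity,
                label_window(ds$meta$fraction, threshold), 0L)
  ds_replace(ds, labels = as.integer(lab))
}

#' Quantizer configuration
#'
#' Per-channel thresholds for the ternary quantizer, normally fitted on the
#' training split only (see [fit_quantizer()]).
#'
#' @param epsilon nonnegative numeric vector, one threshold per channel.
#' @return An object of class `quantizer_config`.
#' @export
quantizer_config <- function(epsilon) {
  epsilon <- as.numeric(epsilon)
  if (any(!is.finite(epsilon)) || any(epsilon < 0))
    stopf("'epsilon' must be nonnegative and finite")
  structure(list(epsilon = epsilon, alphabet = c(-1L, 0L, 1L)),
            class = "quantizer_config")
}

#' @describeIn quantizer_config Fit per-channel thresholds on a training
#'   dataset with [select_epsilon()] applied to the mean-centered samples of
#'   each channel. Centering matters because the quantizer compares
#'   consecutive-sample differences, which are blind to the channel mean; on
#'   a gravity-offset axis the uncentered mean would swamp the threshold and
#'   silence the channel.
#' @param train a raw (non-quantized) training [windowed_dataset()].
#' @export
fit_quantizer <- function(train) {
  stopifnot(inherits(train, "windowed_dataset"))
  if (isTRUE(train$quantized)) stopf("dataset is already quantized")
  O <- dim(train$windows)[1L]
  eps <- vapply(seq_len(O), function(i) {
    x <- as.numeric(train$windows[i, , ])
    select_epsilon(x - mean(x))
  }, numeric(1))
  quantizer_config(eps)
}

#' Apply ternary quantization to every window of a dataset
#'
#' Each window row of length `l` becomes a ternary row of length `l - 1`.
#' Thresholds come from `config`; to prevent information leaking from a test
#' split, fit the config on the training split only and reuse it.
#'
#' @param ds a raw [windowed_dataset()].
#' @param config a [quantizer_config()]; defaults to thresholds fitted on
#'   `ds` itself (appropriate only for a training split).
#' @return The quantized dataset (window length reduced by one).
#' @export
quantize_dataset <- function(ds, config = fit_quantizer(ds)) {
  stopifnot(inherits(ds, "windowed_dataset"),
            inherits(config, "quantizer_config"))
  if (isTRUE(ds$quantized)) stopf("dataset is already quantized")
  d <- dim(ds$windows)
  eps <- rep_len(config$epsilon, d[1L])
  out <- array(0, dim = c(d[1L], d[2L] - 1L, d[3L]))
  for (j in seq_len(d[3L]))
    out[, , j] <- quantize(ds$windows[, , j], eps)
  ds_replace(ds, windows = out, quantized = TRUE, epsilon = eps)
}

#' Per-channel standardization statistics
#'
#' Mean and standard deviation per channel over all windows of a (training)
#' dataset, for standardizing non-quantized inputs before they enter the
#' network.
#'
#' @param train a raw training [windowed_dataset()].
#' @return A list with `mean` and `sd` vectors (one entry per channel).
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "windowed_dataset"))
  O <- dim(train$windows)[1L]
  m <- vapply(seq_len(O), function(i) mean(train$windows[i, , ]), numeric(1))
  s <- vapply(seq_len(O), function(i) sd(as.numeric(train$windows[i, , ])),
              numeric(1))
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

#' @describeIn fit_standardizer Apply standardization statistics to a
#'   dataset.
#' @param ds a raw [windowed_dataset()].
#' @param stats statistics from `fit_standardizer()`.
#' @export
standardize_dataset <- function(ds, stats) {
  stopifnot(inherits(ds, "windowed_dataset"))
  w <- ds$windows
  for (i in seq_len(dim(w)[1L]))
    w[i, , ] <- (w[i, , ] - stats$mean[i]) / stats$sd[i]
  ds_replace(ds, windows = w)
}
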