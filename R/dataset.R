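#' Windowed dataset container
#'
#' Fixed-length multi-channel windows with binary labels and per-window
#' provenance. `windows` is a `channels x length x n` array; `meta` records
#' for each window the subject, the majority non-null activity id, the
#' fraction of window samples belonging to it, and whether the window is an
#' original or a mutated copy.
#'
#' @param windows O x l x n numeric array (or a list of equally sized O x l
#'   matrices).
#' @param labels integer 0/1 vector of length n, or `NA` for unlabeled.
#' @param meta data frame with columns `subject`, `activity`, `fraction`,
#'   `origin` (one row per window).
#' @param sample_rate sampling rate of the underlying signals (Hz).
#' @param channels channel names.
#' @param quantized logical: are the windows ternary-quantized?
#' @param epsilon per-channel quantization thresholds (or `NULL`).
#' @param role `"all"`, `"train"` or `"test"`; set by [split_dataset()].
#' @param augmented logical: has mutation augmentation been applied?
#' @return An object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(windows, labels = NULL, meta = NULL,
                             sample_rate = 50, channels = NULL,
                             quantized = FALSE, epsilon = NULL,
                             role = "all", augmented = FALSE) {
  if (is.list(windows) && !is.array(windows)) {
    if (length(windows) == 0L) {
      windows <- array(numeric(0), dim = c(0, 0, 0))
    } else {
      d <- dim(windows[[1L]])
      if (!all(vapply(windows, function(w) identical(dim(w), d), logical(1))))
        stopf("all windows must have the same shape")
      windows <- array(unlist(windows), dim = c(d, length(windows)))
    }
  }
  if (length(dim(windows)) != 3L)
    stopf("'windows' must be a channels x length x n array")
  n <- dim(windows)[3L]
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- as.integer(labels)
  if (length(labels) != n) stopf("'labels' must have length %d", n)
  if (!all(is.na(labels) | labels %in% c(0L, 1L)))
    stopf("labels must be 0/1 or NA")
  if (is.null(meta))
    meta <- data.frame(subject = rep(NA_integer_, n),
                       activity = rep(0L, n),
                       fraction = rep(NA_real_, n),
                       origin = rep("original", n))
  if (nrow(meta) != n) stopf("'meta' must have %d rows", n)
  ok <- is.na(meta$fraction) | (meta$fraction >= 0 & meta$fraction <= 1)
  if (!all(ok)) stopf("window activity fractions must lie in [0, 1]")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(windows)[1L]))
  structure(list(windows = windows, labels = labels, meta = meta,
                 sample_rate = sample_rate, channels = channels,
                 quantized = quantized, epsilon = epsilon, role = role,
                 augmented = augmented),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("Windowed dataset: %d windows of %d channels x %d samples (%s)\n",
              d[3], d[1], d[2],
              if (x$quantized) "ternary" else "raw"))
  if (!all(is.na(x$labels)))
    cat(sprintf("  labels: %d positive / %d total; role: %s%s\n",
                sum(x$labels == 1L, na.rm = TRUE), d[3], x$role,
                if (x$augmented) " (augmented)" else ""))
  invisible(x)
}

#' @describeIn windowed_dataset Number of windows.
#' @param x,ds a `windowed_dataset`.
#' @export
n_windows <- function(ds) {
  stopifnot(inherits(ds, "windowed_dataset"))
  dim(ds$windows)[3L]
}

#' @describeIn windowed_dataset Subset windows by index.
#' @param i window indices.
#' @param ... unused.
#' @export
`[.windowed_dataset` <- function(x, i, ...) {
  ds_replace(x, windows = x$windows[, , i, drop = FALSE],
             labels = x$labels[i], meta = x$meta[i, , drop = FALSE])
}

# rebuild a dataset keeping unspecified fields (incl. the activity palette)
ds_replace <- function(ds, windows = ds$windows, labels = ds$labels,
                       meta = ds$meta, quantized = ds$quantized,
                       epsilon = ds$epsilon, role = ds$role,
                       augmented = ds$augmented, channels = ds$channels) {
  rownames(meta) <- NULL
  out <- windowed_dataset(windows, labels, meta, sample_rate = ds$sample_rate,
                          channels = channels, quantized = quantized,
                          epsilon = epsilon, role = role,
                          augmented = augmented)
  out$activities <- ds$activities
  out
}

#' Combine windowed datasets
#'
#' Concatenates windows, labels and metadata of datasets with identical
#' window shape and preprocessing state.
#'
#' @param ... `windowed_dataset` objects.
#' @return A single `windowed_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "windowed_dataset"))
    parts <- parts[[1L]]
  stopifnot(length(parts) >= 1L)
  for (p in parts) stopifnot(inherits(p, "windowed_dataset"))
  d1 <- dim(parts[[1L]]$windows)[1:2]
  q1 <- parts[[1L]]$quantized
  for (p in parts)
    if (!identical(dim(p$windows)[1:2], d1) || !identical(p$quantized, q1))
      stopf("datasets must have identical window shape and quantization state")
  windows <- array(unlist(lapply(parts, function(p) p$windows)),
                   dim = c(d1, sum(vapply(parts, n_windows, integer(1)))))
  ds_replace(parts[[1L]], windows = windows,
             labels = unlist(lapply(parts, function(p) p$labels)),
             meta = do.call(rbind, lapply(parts, function(p) p$meta)))
}

#' Subset the channels of a dataset
#'
#' @param ds a `windowed_dataset`.
#' @param channels channel names or indices to keep.
#' @return A `windowed_dataset` with the selected channels.
#' @export
select_channels <- function(ds, channels) {
  stopifnot(inherits(ds, "windowed_dataset"))
  if (is.character(channels)) channels <- match(channels, ds$channels)
  if (any(is.na(channels))) stopf("unknown channel")
  ds_replace(ds, windows = ds$windows[channels, , , drop = FALSE],
             channels = ds$channels[channels],
             epsilon = if (!is.null(ds$epsilon)) ds$epsilon[channels])
}
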