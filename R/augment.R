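#' Mutation-augmentation configuration
#'
#' Settings for the genetic-mutation training-set augmentation: each
#' positive window spawns `K` mutated copies, each copy differing from its
#' parent at exactly one randomly chosen (sample, channel) position, moved to
#' a different quantization level within `M` levels of the original. An
#' alternative reading -- one copy with `K` mutated positions -- is available
#' via `mode = "per_position"`.
#'
#' For ternary windows the levels are the quantizer alphabet `{-1, 0, +1}`
#' (clipped). For continuous windows mutation moves on a grid of spacing
#' `level_spacing` (default: per-channel standard deviation / 4, computed
#' from the dataset at augmentation time), preserving the "extent M"
#' semantics without quantization.
#'
#' @param K mutated windows per positive window; `NULL` selects K at
#'   augmentation time so the positive class reaches about half the training
#'   set.
#' @param M maximum mutation extent in quantization levels (>= 1).
#' @param mode `"per_window"` (K copies, one mutation each; default) or
#'   `"per_position"` (one copy with K mutated positions).
#' @param level_spacing grid spacing for continuous windows (signal units),
#'   scalar or per channel; `NULL` = channel sd / 4.
#' @param seed RNG seed; identical seeds give identical augmented sets.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(K = NULL, M = 1L, mode = c("per_window",
                                                      "per_position"),
                           level_spacing = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.null(K) && (!is.numeric(K) || K < 0))
    stopf("'K' must be a nonnegative count or NULL")
  if (!is.numeric(M) || M < 1) stopf("'M' must be >= 1")
  if (!is.null(level_spacing) && any(level_spacing <= 0))
    stopf("'level_spacing' must be positive")
  structure(list(K = if (!is.null(K)) as.integer(K), M = as.integer(M),
                 mode = mode, level_spacing = level_spacing,
                 seed = as.integer(seed)),
            class = "augment_config")
}

# mutate one (index, channel) position of a window in place
mutate_one <- function(w, M, ternary, spacing) {
  O <- nrow(w); l <- ncol(w)
  i <- sample.int(O, 1L)
  j <- sample.int(l, 1L)
  old <- w[i, j]
  if (ternary) {
    cand <- setdiff(pmin(pmax(old + seq.int(-M, M), -1L), 1L), old)
    if (!length(cand)) stopf("degenerate alphabet: no alternative level")
    w[i, j] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  } else {
    offs <- setdiff(seq.int(-M, M), 0L)
    k <- if (length(offs) == 1L) offs else sample(offs, 1L)
    w[i, j] <- old + k * spacing[i]
  }
  w
}

#' Mutated copies of one window
#'
#' Produces `K` copies of a window (per the config's mode), each obtained by
#' moving randomly chosen positions to neighboring quantization levels. The
#' original window is never modified; in `"per_window"` mode every copy is
#' at Hamming distance exactly 1 from its parent.
#'
#' Uses the current R RNG state; seed it (or use [augment_dataset()], which
#' seeds from the config) for reproducibility.
#'
#' @param window O x l numeric matrix (ternary or continuous).
#' @param config an [augment_config()]; `K` must be set.
#' @param ternary treat values as the ternary alphabet? Defaults to a guess
#'   from the window contents.
#' @return A list of `K` mutated windows.
#' @export
mutate_window <- function(window, config = augment_config(K = 1L),
                          ternary = all(window %in% c(-1, 0, 1))) {
  stopifnot(inherits(config, "augment_config"))
  window <- as.matrix(window)
  if (!length(window)) stopf("'window' must be nonempty")
  K <- config$K
  if (is.null(K)) stopf("'K' must be set in the config for mutate_window")
  if (K == 0L) return(list())
  spacing <- config$level_spacing
  if (!ternary && is.null(spacing)) {
    spacing <- apply(window, 1L, sd) / 4
    spacing[!is.finite(spacing) | spacing == 0] <- 1
  }
  spacing <- rep_len(if (is.null(spacing)) 1 else spacing, nrow(window))
  if (config$mode == "per_window") {
    lapply(seq_len(K), function(k) mutate_one(window, config$M, ternary,
                                              spacing))
  } else {
    out <- window
    for (k in seq_len(K)) out <- mutate_one(out, config$M, ternary, spacing)
    list(out)
  }
}

#' Mutation-based augmentation of a labeled training set
#'
#' For every positive window, appends its mutated copies (labeled positive,
#' origin `"mutated"`); negative windows are never touched. With `K` copies
#' per positive and `P` positives the output has `K * P` additional
#' windows. Augmentation is a training-only device: applying it to a test
#' split is a pipeline contract violation and raises an error.
#'
#' @param ds a labeled [windowed_dataset()] (role `"all"` or `"train"`).
#' @param config an [augment_config()]; a `NULL` `K` is resolved so the
#'   positive class reaches about half of the augmented set.
#' @return The augmented dataset (`augmented = TRUE`), deterministic given
#'   the config seed.
#' @examples
#' ds <- windowed_dataset(array(sample(c(-1, 0, 1), 3 * 8 * 20, TRUE),
#'                              c(3, 8, 20)),
#'                        labels = rep(c(1, 0), c(4, 16)), quantized = TRUE)
#' n_windows(augment_dataset(ds, augment_config(K = 5)))  # 20 + 5*4
#' @export
augment_dataset <- function(ds, config = augment_config()) {
  stopifnot(inherits(ds, "windowed_dataset"),
            inherits(config, "augment_config"))
  if (identical(ds$role, "test"))
    stopf("augmentation must not be applied to a test split (training-only device)")
  if (any(is.na(ds$labels))) stopf("dataset must be labeled")
  pos <- which(ds$labels == 1L)
  K <- config$K
  if (is.null(K)) {
    if (!length(pos)) stopf("cannot auto-select K: no positive windows")
    K <- max(0L, as.integer(round((n_windows(ds) - 2L * length(pos)) /
                                    length(pos))))
  }
  if (K == 0L || !length(pos)) return(ds)
  cfgK <- config; cfgK$K <- as.integer(K)
  ternary <- isTRUE(ds$quantized)
  if (!ternary && is.null(cfgK$level_spacing)) {
    sp <- vapply(seq_len(dim(ds$windows)[1L]),
                 function(i) sd(as.numeric(ds$windows[i, , ])), numeric(1))
    sp[!is.finite(sp) | sp == 0] <- 1
    cfgK$level_spacing <- sp / 4
  }
  with_seed(config$seed, {
    muts <- lapply(pos, function(j)
      mutate_window(ds$windows[, , j, drop = TRUE], cfgK, ternary = ternary))
  })
  n_new <- K * length(pos)
  d <- dim(ds$windows)
  windows <- array(0, dim = c(d[1L], d[2L], d[3L] + n_new))
  windows[, , seq_len(d[3L])] <- ds$windows
  meta_new <- ds$meta[rep(pos, each = K), , drop = FALSE]
  meta_new$origin <- "mutated"
  j <- d[3L]
  for (m in muts) for (w in m) windows[, , (j <- j + 1L)] <- w
  ds_replace(ds, windows = windows,
             labels = c(ds$labels, rep(1L, n_new)),
             meta = rbind(ds$meta, meta_new), augmented = TRUE)
}
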