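#' Random train/test split of a window dataset
#'
#' Seeded random partition at the window level (default 70/30): disjoint,
#' exhaustive, reproducible. Augmentation and preprocessing statistics must
#' be applied to the training part only, afterwards. A by-subject mode
#' assigns whole subjects to one side, for pipelines where subject leakage
#' matters.
#'
#' @param ds a [windowed_dataset()].
#' @param train_frac fraction of windows (or subjects) in the training part.
#' @param seed RNG seed.
#' @param by `"window"` (default) or `"subject"`.
#' @return A list with `train` and `test` datasets (roles set accordingly).
#' @export
split_dataset <- function(ds, train_frac = 0.7, seed = 1L,
                          by = c("window", "subject")) {
  by <- match.arg(by)
  stopifnot(inherits(ds, "windowed_dataset"))
  n <- n_windows(ds)
  if (n < 2L) stopf("dataset too small to split")
  if (train_frac <= 0 || train_frac >= 1)
    stopf("'train_frac' must be in (0, 1)")
  idx <- with_seed(seed, {
    if (by == "window") {
      sample.int(n, round(train_frac * n))
    } else {
      subj <- unique(ds$meta$subject)
      ins <- sample(subj, max(1L, round(train_frac * length(subj))))
      which(ds$meta$subject %in% ins)
    }
  })
  train <- ds[sort(idx)]
  test <- ds[setdiff(seq_len(n), idx)]
  train$role <- "train"
  test$role <- "test"
  list(train = train, test = test)
}

#' Classification accuracy
#'
#' Fraction of exact matches between predictions and labels.
#'
#' @param predictions,labels equal-length vectors.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stopf("'predictions' and 'labels' must have equal length")
  if (!length(labels)) stopf("empty inputs")
  mean(predictions == labels)
}

#' @describeIn accuracy Mean of the two class-conditional accuracies
#'   (sensitivity and specificity). Unlike plain accuracy it is immune to
#'   class imbalance: any uninformed classifier -- constant or random --
#'   scores 1/2 in expectation, which makes it the right yardstick for
#'   null-model comparisons on imbalanced test splits.
#' @export
balanced_accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stopf("'predictions' and 'labels' must have equal length")
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stopf("'labels' must contain both classes")
  mean(vapply(cls, function(k) mean(predictions[labels == k] == k),
              numeric(1)))
}

#' Average of per-activity accuracies
#'
#' Arithmetic mean of a set of per-activity accuracy percentages, reported
#' to two decimals -- the convention for summarizing one-vs-null detectors
#' across activities.
#'
#' @param per_activity nonempty numeric vector of percentages.
#' @return The mean, rounded to two decimals.
#' @examples
#' average_accuracy(c(76.5, 77.6, 78.9, 78.7, 78.0))  # 77.94
#' @export
average_accuracy <- function(per_activity) {
  if (!length(per_activity)) stopf("'per_activity' must be nonempty")
  round(mean(as.numeric(per_activity)), 2)
}

#' Substeps needed for Euler stability
#'
#' Smallest substep count per input sample keeping the Euler step below
#' `2 tau / margin`; used by sweeps that rescale the natural frequency.
#'
#' @param params a [mems_params()] object (or a numeric tau).
#' @param sample_rate input sampling rate (Hz).
#' @param margin safety factor (> 1).
#' @return Integer substep count.
#' @export
stable_substeps <- function(params, sample_rate = 50, margin = 2.5) {
  tau <- if (inherits(params, "mems_params"))
    time_constant(params$zeta, params$omega_n) else as.numeric(params)
  as.integer(ceiling(margin / (2 * tau * sample_rate)))
}

#' Full activity-detection pipeline on a benchmark
#'
#' Runs the complete leak-free protocol on a labeled raw window dataset:
#' optional channel subset, random 70/30 split, quantization (thresholds
#' fitted on the training split) or per-channel standardization (training
#' statistics), mutation augmentation of the training split, surrogate
#' BPTT training, and hard-step evaluation on both splits.
#'
#' @param bench a labeled raw [windowed_dataset()] (e.g. from
#'   [generate_benchmark()]); relabel with [label_dataset()] to change the
#'   target activity or threshold.
#' @param engine `"mems"` or `"ctrnn"`.
#' @param quantize ternary-quantize inputs (otherwise standardize).
#' @param channels optional channel subset (names or indices).
#' @param augment apply mutation augmentation to the training split.
#' @param aug_config an [augment_config()].
#' @param params a [mems_params()] object.
#' @param control a [train_config()].
#' @param n_hidden hidden-layer size.
#' @param train_frac training fraction of the split.
#' @param split_seed seed of the random split.
#' @param shuffle_labels permute the training labels after augmentation (a
#'   null-model control; test labels are untouched).
#' @param tau CTRNN time constant(s).
#' @return A list with the fitted model (`fit`), `train_accuracy`,
#'   `test_accuracy`, `confusion` (test confusion counts), and split sizes.
#' @export
evaluate_activity_detection <- function(bench, engine = c("mems", "ctrnn"),
                                        quantize = TRUE, channels = NULL,
                                        augment = TRUE,
                                        aug_config = augment_config(),
                                        params = mems_params(),
                                        control = train_config(),
                                        n_hidden = 6L, train_frac = 0.7,
                                        split_seed = control$seed,
                                        shuffle_labels = FALSE, tau = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(bench, "windowed_dataset"))
  if (any(is.na(bench$labels))) stopf("benchmark must be labeled")
  if (!is.null(channels)) bench <- select_channels(bench, channels)
  parts <- split_dataset(bench, train_frac = train_frac, seed = split_seed)
  train <- parts$train; test <- parts$test
  if (quantize) {
    qc <- fit_quantizer(train)
    train <- quantize_dataset(train, qc)
    test <- quantize_dataset(test, qc)
    standardize <- FALSE
  } else {
    standardize <- TRUE
  }
  if (augment) train <- augment_dataset(train, aug_config)
  if (shuffle_labels)
    train$labels <- with_seed(child_seed(control$seed, 991L),
                              sample(train$labels))
  fit <- mems_ctrnn(train, engine = engine, n_hidden = n_hidden,
                    params = params, control = control,
                    standardize = standardize, tau = tau)
  pr_train <- predict(fit, train)
  pr_test <- predict(fit, test)
  conf <- table(factor(pr_test, levels = 0:1),
                factor(test$labels, levels = 0:1),
                dnn = c("predicted", "actual"))
  list(fit = fit,
       train_accuracy = accuracy(pr_train, train$labels),
       test_accuracy = accuracy(pr_test, test$labels),
       test_balanced_accuracy =
         if (length(unique(test$labels)) > 1L)
           balanced_accuracy(pr_test, test$labels) else NA_real_,
       confusion = conf,
       n_train = n_windows(train), n_test = n_windows(test))
}

#' Experiment grid definition
#'
#' Cross-product of protocol axes: model engine, hidden size, quantization,
#' channel subsets, labeling thresholds, natural-frequency multipliers
#' (from [p_multipliers()]), target activities, and seeds. Each row of the
#' returned frame is one (cell, seed) run for [run_grid()].
#'
#' @param engine model kinds.
#' @param n_hidden hidden sizes (the canonical sweep is 3, 6, 9, 16).
#' @param quantize logical axis.
#' @param channels list of channel subsets (names or indices); `NULL` = all.
#' @param threshold labeling thresholds.
#' @param P natural-frequency multipliers; must belong to the canonical set.
#' @param activity target activities.
#' @param seeds RNG seeds (each cell runs once per seed).
#' @return A data frame of class `experiment_grid`.
#' @export
experiment_grid <- function(engine = "mems", n_hidden = 6L, quantize = TRUE,
                            channels = list(NULL), threshold = 0.75, P = 1,
                            activity = "walk", seeds = 1L) {
  if (!all(vapply(P, function(p) any(abs(p - p_multipliers()) < 1e-9),
                  logical(1))))
    stopf("'P' values must come from p_multipliers()")
  if (!length(engine) || !length(n_hidden) || !length(threshold) ||
      !length(activity) || !length(seeds))
    stopf("grid axes must be nonempty")
  g <- expand.grid(engine = engine, n_hidden = n_hidden,
                   quantize = quantize,
                   channel_set = seq_along(channels),
                   threshold = threshold, P = P, activity = activity,
                   seed = seeds, stringsAsFactors = FALSE)
  attr(g, "channel_sets") <- channels
  class(g) <- c("experiment_grid", class(g))
  g
}

#' Run an experiment grid
#'
#' Trains and evaluates one model per grid row via
#' [evaluate_activity_detection()], relabeling the benchmark per row
#' (activity, threshold) and rescaling the natural frequency by the row's
#' multiplier `P` (time constant `tau / P`), with the substep count raised
#' as needed for Euler stability. Failures in one cell are caught and
#' logged without aborting the rest.
#'
#' @param grid an [experiment_grid()].
#' @param bench a labeled raw benchmark dataset ([generate_benchmark()]).
#' @param params baseline [mems_params()].
#' @param control baseline [train_config()] (seed and substeps are adjusted
#'   per row).
#' @param augment,aug_config augmentation settings.
#' @return The grid with result columns: `train_accuracy`, `test_accuracy`,
#'   `final_loss`, `config_hash`, `error`.
#' @export
run_grid <- function(grid, bench, params = mems_params(),
                     control = train_config(), augment = TRUE,
                     aug_config = augment_config()) {
  stopifnot(inherits(grid, "experiment_grid"),
            inherits(bench, "windowed_dataset"))
  csets <- attr(grid, "channel_sets")
  out <- as.data.frame(grid)
  out$train_accuracy <- NA_real_
  out$test_accuracy <- NA_real_
  out$final_loss <- NA_real_
  out$config_hash <- NA_character_
  out$error <- NA_character_
  for (r in seq_len(nrow(out))) {
    row <- out[r, ]
    res <- tryCatch({
      pr <- scale_omega_n(params, row$P)
      ctl <- control
      ctl$seed <- as.integer(row$seed)
      ctl$substeps <- max(control$substeps,
                          stable_substeps(pr, bench$sample_rate))
      b <- label_dataset(bench, row$activity, row$threshold)
      evaluate_activity_detection(
        b, engine = row$engine, quantize = row$quantize,
        channels = csets[[row$channel_set]], augment = augment,
        aug_config = aug_config, params = pr, control = ctl,
        n_hidden = row$n_hidden, split_seed = as.integer(row$seed))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[r] <- conditionMessage(res)
    } else {
      out$train_accuracy[r] <- res$train_accuracy
      out$test_accuracy[r] <- res$test_accuracy
      out$final_loss[r] <- utils::tail(res$fit$history$loss, 1L)
      out$config_hash[r] <- paste0(format(row$engine), "-h", row$n_hidden,
                                   "-q", row$quantize, "-c", row$channel_set,
                                   "-t", row$threshold, "-P",
                                   format(row$P, digits = 4), "-",
                                   row$activity, "-s", row$seed)
    }
  }
  out
}

#' Aggregate repeated-seed grid results
#'
#' Mean and standard deviation of test accuracy per grid cell (all axes
#' except the seed).
#'
#' @param results output of [run_grid()].
#' @return A data frame with `mean_accuracy`, `sd_accuracy`, `n_seeds` per
#'   cell.
#' @export
summarize_grid <- function(results) {
  keys <- c("engine", "n_hidden", "quantize", "channel_set", "threshold",
            "P", "activity")
  key <- interaction(results[keys], drop = TRUE)
  agg <- lapply(split(results, key), function(d)
    cbind(d[1L, keys, drop = FALSE],
          mean_accuracy = mean(d$test_accuracy, na.rm = TRUE),
          sd_accuracy = sd(d$test_accuracy, na.rm = TRUE),
          n_seeds = sum(!is.na(d$test_accuracy))))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
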