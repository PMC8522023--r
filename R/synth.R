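#' Synthetic recording configuration
#'
#' Describes a generator of 50 Hz tri-axial (optionally six-channel)
#' recordings emulating waist-worn smartphone inertial data: a gravity-like
#' constant baseline with band-limited (AR(1)) noise, into which annotated
#' activity segments are inserted at random non-overlapping positions. One
#' oscillatory activity ("walk", a sinusoid spread over all three axes) and
#' four step-like postural transitions (smooth bumps on one axis) are
#' provided; default class proportions mirror a strongly imbalanced
#' real-world activity mix (15.8% walk; 0.6, 0.3, 1.0 and 0.8% for the
#' transitions).
#'
#' The templates are deliberately simple -- the goal is controlled
#' testability, not biomechanical realism. `separability` scales every
#' template amplitude relative to the noise; 0 turns the templates off
#' entirely (a null benchmark).
#'
#' @param sample_rate sampling rate (Hz).
#' @param duration recording length per subject (s).
#' @param channels 3 (accelerometer) or 6 (adds synthetic gyroscope
#'   channels: phase-delayed, differentiated copies with independent noise).
#' @param proportions named fractions of samples per activity class; the
#'   remainder is the null class.
#' @param noise_sd standard deviation of the AR(1) sensor noise (m/s^2).
#' @param noise_ar AR(1) coefficient of the noise (0 = white).
#' @param baseline per-axis constant level (m/s^2), gravity mostly on Z.
#' @param walk_amp per-axis walk oscillation amplitude (m/s^2).
#' @param walk_freq walk cadence (Hz).
#' @param walk_dur min/max walk bout duration (s). Bouts a few windows long
#'   leave plenty of clean bout-core windows while every bout also
#'   contributes boundary windows with intermediate activity fractions --
#'   the ambiguity that makes the labeling threshold matter.
#' @param walk_ramp seconds of raised-cosine amplitude ramp at each end of
#'   a walk bout (gait spin-up/down). Bout-edge windows therefore carry
#'   genuinely weaker signal than bout-core windows.
#' @param trans_delta transition bump heights (m/s^2), one per transition
#'   class.
#' @param trans_axis axis carrying each transition bump.
#' @param trans_dur min/max transition duration (s).
#' @param subject_gain range of per-subject multiplicative gain.
#' @param subject_offset_sd sd of per-subject per-axis offsets (m/s^2).
#' @param separability scalar scaling template amplitude vs noise.
#' @param seed base RNG seed; recordings are deterministic per
#'   (seed, subject).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sample_rate = 50, duration = 110, channels = 3,
                         proportions = c(walk = 0.158, stand_to_sit = 0.006,
                                         sit_to_stand = 0.003,
                                         sit_to_lie = 0.010,
                                         lie_to_sit = 0.008),
                         noise_sd = 0.3, noise_ar = 0.9,
                         baseline = c(0.2, -0.1, 9.8),
                         walk_amp = c(2.0, 1.6, 1.8), walk_freq = 2,
                         walk_dur = c(4, 8), walk_ramp = 0.6,
                         trans_delta = c(-4, 4, 4.5, -4.5),
                         trans_axis = c(3, 3, 2, 2),
                         trans_dur = c(2, 3),
                         subject_gain = c(0.9, 1.1), subject_offset_sd = 0.1,
                         separability = 1, seed = 1L) {
  if (sample_rate <= 0) stopf("'sample_rate' must be positive")
  if (!channels %in% c(3, 6)) stopf("'channels' must be 3 or 6")
  if (any(proportions < 0) || sum(proportions) > 0.9)
    stopf("class proportions must be nonnegative and sum to at most 0.9")
  if (separability < 0) stopf("'separability' must be nonnegative")
  structure(list(sample_rate = sample_rate, duration = duration,
                 channels = as.integer(channels), proportions = proportions,
                 noise_sd = noise_sd, noise_ar = noise_ar,
                 baseline = baseline, walk_amp = walk_amp,
                 walk_freq = walk_freq, walk_dur = walk_dur,
                 walk_ramp = walk_ramp,
                 trans_delta = trans_delta, trans_axis = trans_axis,
                 trans_dur = trans_dur, subject_gain = subject_gain,
                 subject_offset_sd = subject_offset_sd,
                 separability = separability, seed = as.integer(seed)),
            class = "synth_config")
}

# AR(1) noise with stationary sd `s`
ar1_noise <- function(n, s, rho) {
  if (s == 0 || n == 0L) return(numeric(n))
  e <- rnorm(n, 0, s * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive", init = rnorm(1, 0, s)))
}

# plan segment lengths (samples) for one class given a sample budget
plan_segments <- function(target, dur_range, rate) {
  min_n <- round(dur_range[1] * rate)
  max_n <- round(dur_range[2] * rate)
  if (target < 0.5 * min_n) return(integer(0))
  k <- max(1L, round(target / mean(c(min_n, max_n))))
  lens <- round(runif(k, min_n, max_n))
  # rescale to hit the budget, then clip to the allowed range
  lens <- round(lens * target / sum(lens))
  pmin(pmax(lens, min_n %/% 2L), max_n)
}

#' Generate one synthetic annotated recording
#'
#' Builds a `channels x T` signal matrix for one subject: baseline plus
#' AR(1) noise, with activity segments (per the config's palette and
#' proportions) placed at random non-overlapping positions. Annotations are
#' exact and the output is deterministic per (config seed, subject id).
#'
#' Activity ids: 1 = walk, 2 = stand_to_sit, 3 = sit_to_stand,
#' 4 = sit_to_lie, 5 = lie_to_sit; 0 is the null class.
#'
#' @param config a [synth_config()].
#' @param subject_id integer subject identifier.
#' @return A `har_recording` object (see [recording()]).
#' @export
generate_recording <- function(config, subject_id = 1L) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(child_seed(config$seed, subject_id), {
    rate <- config$sample_rate
    Tn <- round(config$duration * rate)
    classes <- names(config$proportions)
    sep <- config$separability

    # segment plan: list of (class id, length)
    seg_class <- integer(0); seg_len <- integer(0)
    for (ci in seq_along(classes)) {
      target <- round(config$proportions[ci] * Tn)
      dr <- if (classes[ci] == "walk") config$walk_dur else config$trans_dur
      lens <- plan_segments(target, dr, rate)
      seg_class <- c(seg_class, rep(ci, length(lens)))
      seg_len <- c(seg_len, lens)
    }
    if (sum(seg_len) > 0.9 * Tn)
      stopf("class proportions infeasible for this duration")
    if (length(seg_len)) {
      ord <- sample.int(length(seg_len))
      seg_class <- seg_class[ord]; seg_len <- seg_len[ord]
    }
    gaps <- as.integer(stats::rmultinom(1, Tn - sum(seg_len),
                                        rep(1, length(seg_len) + 1L)))

    # background
    gain <- runif(1, config$subject_gain[1], config$subject_gain[2])
    offs <- rnorm(3, 0, config$subject_offset_sd)
    sig <- matrix(0, 3, Tn)
    for (a in 1:3)
      sig[a, ] <- gain * (config$baseline[a] + offs[a]) +
        ar1_noise(Tn, config$noise_sd, config$noise_ar)

    ann <- integer(Tn)
    pos <- gaps[1L]
    phases <- c(0, pi / 3, 2 * pi / 3)
    for (s in seq_along(seg_len)) {
      n <- seg_len[s]; ci <- seg_class[s]
      idx <- (pos + 1L):(pos + n)
      tt <- seq_len(n) / rate
      if (classes[ci] == "walk") {
        ph0 <- runif(1, 0, 2 * pi)
        nr <- min(round(config$walk_ramp * rate), n %/% 2L)
        env <- rep(1, n)
        if (nr > 0) {
          ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
          env[seq_len(nr)] <- ramp
          env[n + 1L - seq_len(nr)] <- ramp
        }
        for (a in 1:3)
          sig[a, idx] <- sig[a, idx] + sep * gain * config$walk_amp[a] *
            env * sin(2 * pi * config$walk_freq * tt + ph0 + phases[a])
      } else {
        k <- ci - 1L  # transition index within the palette
        bump <- sin(pi * seq_len(n) / (n + 1L))^2
        a <- config$trans_axis[k]
        sig[a, idx] <- sig[a, idx] + sep * gain * config$trans_delta[k] * bump
      }
      ann[idx] <- ci
      pos <- pos + n + gaps[s + 1L]
    }

    chn <- c("acc_x", "acc_y", "acc_z")
    if (config$channels == 6L) {
      gyro <- matrix(0, 3, Tn)
      lag <- 5L
      for (a in 1:3) {
        centered <- sig[a, ] - mean(sig[a, ])
        shifted <- c(rep(0, lag), centered[seq_len(Tn - lag)])
        gyro[a, ] <- 0.5 * c(0, diff(shifted)) * rate / (2 * pi * config$walk_freq) +
          ar1_noise(Tn, config$noise_sd / 2, config$noise_ar)
      }
      sig <- rbind(sig, gyro)
      chn <- c(chn, "gyr_x", "gyr_y", "gyr_z")
    }
    rownames(sig) <- chn
    recording(sig, sample_rate = rate,
              annotations = segments_from_vector(ann),
              subject = as.integer(subject_id), experiment = config$seed,
              activities = classes)
  })
}

#' Generate a train-ready windowed benchmark
#'
#' Composes [generate_recording()] over several subjects, slices the
#' recordings into windows with [make_windows()], and labels them for
#' one-vs-null detection of the target activity. The windows are raw
#' (non-quantized); quantize or standardize after splitting so that no test
#' information leaks into the preprocessing statistics
#' (see [evaluate_activity_detection()], which automates this).
#'
#' With the default imbalanced proportions, positives are well under 20% of
#' windows for every single-activity task -- the situation mutation
#' augmentation exists to repair.
#'
#' @param config a [synth_config()].
#' @param subjects number of subjects (recordings) to generate.
#' @param target target activity name or id.
#' @param threshold labeling threshold (fraction of in-window samples).
#' @param l window length in samples. The default 65 gives 64-sample ternary
#'   windows after quantization (1.28 s at 50 Hz).
#' @param stride window hop in samples (default: near-disjoint windows,
#'   about 85 windows per subject at the default duration).
#' @return A labeled raw [windowed_dataset()] carrying the activity palette.
#' @export
generate_benchmark <- function(config = synth_config(), subjects = 5L,
                               target = "walk", threshold = 0.75, l = 65L,
                               stride = 64L) {
  stopifnot(inherits(config, "synth_config"))
  parts <- lapply(seq_len(subjects), function(sid) {
    rec <- generate_recording(config, sid)
    make_windows(rec, l = l, stride = stride)
  })
  ds <- bind_datasets(parts)
  ds$activities <- names(config$proportions)
  label_dataset(ds, target, threshold)
}
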