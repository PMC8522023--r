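#' Raw recording container
#'
#' A multi-channel inertial recording with interval annotations. Sample
#' indexing is 0-based and annotation intervals are half-open `[start, end)`
#' in samples -- the convention used by all readers and writers in this
#' package.
#'
#' @param signals O x T numeric matrix (rows = channels).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param annotations data frame with columns `activity`, `start`, `end`
#'   (0-based, half-open, within `[0, T)`); or `NULL` for none.
#' @param subject subject id.
#' @param experiment experiment id.
#' @param activities optional activity-name palette (index = id).
#' @return An object of class `har_recording`.
#' @export
recording <- function(signals, sample_rate = 50, annotations = NULL,
                      subject = NA_integer_, experiment = NA_integer_,
                      activities = NULL) {
  signals <- as.matrix(signals)
  if (sample_rate <= 0) stopf("'sample_rate' must be positive")
  Tn <- ncol(signals)
  if (is.null(annotations))
    annotations <- data.frame(activity = integer(), start = integer(),
                              end = integer())
  if (nrow(annotations)) {
    if (any(annotations$start < 0) || any(annotations$end > Tn) ||
        any(annotations$start > annotations$end))
      stopf("annotations must satisfy 0 <= start <= end <= T")
  }
  structure(list(signals = signals, sample_rate = sample_rate,
                 annotations = annotations, subject = subject,
                 experiment = experiment, activities = activities),
            class = "har_recording")
}

#' @export
print.har_recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples at %g Hz (subject %s, experiment %s)\n",
              nrow(x$signals), ncol(x$signals), x$sample_rate,
              format(x$subject), format(x$experiment)))
  cat(sprintf("  %d annotated segments\n", nrow(x$annotations)))
  invisible(x)
}

#' @describeIn recording Per-sample activity ids (length T, 0 = null) from
#'   the interval annotations.
#' @param rec a `har_recording`.
#' @export
annotation_vector <- function(rec) {
  stopifnot(inherits(rec, "har_recording"))
  ann <- integer(ncol(rec$signals))
  a <- rec$annotations
  for (i in seq_len(nrow(a)))
    if (a$end[i] > a$start[i])
      ann[(a$start[i] + 1L):a$end[i]] <- a$activity[i]
  ann
}

# inverse: contiguous runs of a per-sample id vector -> interval table
segments_from_vector <- function(ann) {
  r <- rle(ann)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0L
  data.frame(activity = r$values[keep], start = starts[keep],
             end = ends[keep])
}

#' Read raw recordings in the public smartphone-dataset layout
#'
#' Best-effort reader for the raw-data layout of the public smartphone HAR
#' archive: per-experiment whitespace-separated tri-axial text files named
#' `acc_expXX_userYY.txt` (and optionally `gyro_expXX_userYY.txt`), plus a
#' `labels.txt` index whose rows are `experiment user activity start end`
#' (sample indices). Missing gyroscope files are tolerated (3-channel
#' recordings). Label rows are interpreted as 0-based half-open intervals.
#'
#' @param dir directory containing the files.
#' @param sample_rate sampling rate to record (Hz).
#' @return A list of [recording()] objects, one per (experiment, user).
#' @export
read_raw_recordings <- function(dir, sample_rate = 50) {
  if (!dir.exists(dir)) stopf("directory '%s' does not exist", dir)
  accs <- list.files(dir, pattern = "^acc_exp[0-9]+_user[0-9]+\\.txt$")
  if (!length(accs)) stopf("no acc_expXX_userYY.txt files in '%s'", dir)
  labfile <- file.path(dir, "labels.txt")
  labels <- if (file.exists(labfile)) {
    l <- read.table(labfile, header = FALSE)
    if (ncol(l) != 5L) stopf("labels.txt must have 5 columns")
    names(l) <- c("experiment", "user", "activity", "start", "end")
    l
  } else data.frame(experiment = integer(), user = integer(),
                    activity = integer(), start = integer(),
                    end = integer())
  read_signal <- function(path) {
    m <- tryCatch(as.matrix(read.table(path, header = FALSE)),
                  error = function(e)
                    stopf("malformed numeric data in '%s': %s", path,
                          conditionMessage(e)))
    if (!is.numeric(m) || anyNA(m))
      stopf("malformed numeric data in '%s'", path)
    t(m)
  }
  lapply(accs, function(f) {
    ids <- as.integer(regmatches(f, gregexpr("[0-9]+", f))[[1L]][1:2])
    acc <- read_signal(file.path(dir, f))
    rownames(acc) <- c("acc_x", "acc_y", "acc_z")
    gf <- file.path(dir, sub("^acc_", "gyro_", f))
    sig <- acc
    if (file.exists(gf)) {
      gyr <- read_signal(gf)
      rownames(gyr) <- c("gyr_x", "gyr_y", "gyr_z")
      sig <- rbind(acc, gyr)
    }
    lab <- labels[labels$experiment == ids[1L] & labels$user == ids[2L], ,
                  drop = FALSE]
    recording(sig, sample_rate = sample_rate,
              annotations = data.frame(activity = lab$activity,
                                       start = lab$start, end = lab$end),
              subject = ids[2L], experiment = ids[1L])
  })
}

#' Write recordings in the raw text layout
#'
#' Emits the same layout [read_raw_recordings()] consumes, so synthetic
#' recordings can exercise the full reader path.
#'
#' @param recordings a list of [recording()] objects (or a single one).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_raw_recordings <- function(recordings, dir) {
  if (inherits(recordings, "har_recording")) recordings <- list(recordings)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- list()
  for (rec in recordings) {
    eid <- if (is.na(rec$experiment)) 1L else as.integer(rec$experiment)
    uid <- if (is.na(rec$subject)) 1L else as.integer(rec$subject)
    tag <- sprintf("exp%02d_user%02d.txt", eid, uid)
    acc <- rec$signals[seq_len(3L), , drop = FALSE]
    write.table(t(acc), file.path(dir, paste0("acc_", tag)),
                row.names = FALSE, col.names = FALSE)
    if (nrow(rec$signals) >= 6L)
      write.table(t(rec$signals[4:6, , drop = FALSE]),
                  file.path(dir, paste0("gyro_", tag)),
                  row.names = FALSE, col.names = FALSE)
    a <- rec$annotations
    if (nrow(a))
      labs[[length(labs) + 1L]] <-
        data.frame(experiment = eid, user = uid, activity = a$activity,
                   start = a$start, end = a$end)
  }
  if (length(labs))
    write.table(do.call(rbind, labs), file.path(dir, "labels.txt"),
                row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Lossless dataset round-trip on disk
#'
#' Writes a [windowed_dataset()] as a directory holding a flattened CSV of
#' window values plus a JSON manifest with labels, metadata, preprocessing
#' state and lineage. `read_dataset()` restores an identical object.
#'
#' @param ds a `windowed_dataset`.
#' @param dir output directory.
#' @return `dir` (write) or the restored dataset (read).
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "windowed_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ds$windows)
  flat <- matrix(aperm(ds$windows, c(2L, 1L, 3L)), nrow = d[1L] * d[3L],
                 ncol = d[2L], byrow = TRUE)
  write.table(flat, file.path(dir, "windows.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  man <- list(format = "memsctrnn-dataset-1", dim = d,
              labels = ds$labels, meta = ds$meta,
              sample_rate = ds$sample_rate, channels = ds$channels,
              quantized = ds$quantized, epsilon = ds$epsilon,
              role = ds$role, augmented = ds$augmented,
              activities = ds$activities)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "memsctrnn-dataset-1"))
    stopf("unrecognized dataset manifest version")
  d <- as.integer(man$dim)
  windows <- if (prod(d) == 0L) array(numeric(0), dim = d) else {
    flat <- as.matrix(read.csv(file.path(dir, "windows.csv"),
                               header = FALSE))
    aperm(array(t(flat), dim = c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  }
  meta <- as.data.frame(man$meta)
  if (!nrow(meta))
    meta <- data.frame(subject = integer(), activity = integer(),
                       fraction = numeric(), origin = character())
  ds <- windowed_dataset(windows,
                         labels = if (length(man$labels)) man$labels,
                         meta = meta, sample_rate = man$sample_rate,
                         channels = man$channels,
                         quantized = isTRUE(man$quantized),
                         epsilon = man$epsilon, role = man$role,
                         augmented = isTRUE(man$augmented))
  ds$activities <- man$activities
  ds
}
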