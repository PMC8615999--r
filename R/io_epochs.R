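#' Construct a continuous multichannel recording
#'
#' A `kfcs_recording` holds a channels-by-samples signal matrix (microvolts),
#' its sampling rate and unique channel labels.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_labels character vector, one unique label per channel.
#'   Defaults to `ch01, ch02, ...`.
#' @return An object of class `kfcs_recording`.
#' @export
recording <- function(signal, fs, channel_labels = NULL) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(signal)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(signal)) {
    stop("channel_labels length must equal the number of channels")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(signal) <- channel_labels
  structure(list(signal = signal, fs = fs, channel_labels = channel_labels),
            class = "kfcs_recording")
}

#' @export
print.kfcs_recording <- function(x, ...) {
  cat(sprintf("<kfcs_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  invisible(x)
}

#' Construct a set of fixed-length labelled epochs
#'
#' @param epochs list of channels-by-samples numeric matrices, all the same shape.
#' @param labels character/factor vector, one of `"braking"`/`"normal"` per epoch.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier string.
#' @param channel_labels optional channel labels (recycled onto each epoch).
#' @return An object of class `kfcs_epochs`.
#' @export
epoch_set <- function(epochs, labels, fs, subject_id = "S1", channel_labels = NULL) {
  stopifnot(is.list(epochs))
  labels <- as.character(labels)
  if (length(labels) != length(epochs)) stop("one label per epoch required")
  if (length(epochs) > 0L) {
    if (!all(labels %in% c("braking", "normal"))) {
      stop("labels must be 'braking' or 'normal'")
    }
    dims <- vapply(epochs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("all epochs must have the same shape")
    }
    if (is.null(channel_labels)) {
      channel_labels <- rownames(epochs[[1]])
      if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(dims[1, 1]))
    }
  }
  structure(list(epochs = epochs, labels = labels, fs = fs,
                 subject_id = subject_id, channel_labels = channel_labels),
            class = "kfcs_epochs")
}

#' @export
print.kfcs_epochs <- function(x, ...) {
  n <- length(x$epochs)
  cat(sprintf("<kfcs_epochs> subject %s: %d epochs (%d braking / %d normal)",
              x$subject_id, n, sum(x$labels == "braking"), sum(x$labels == "normal")))
  if (n > 0L) {
    cat(sprintf(", %d channels x %d samples @ %g Hz",
                nrow(x$epochs[[1]]), ncol(x$epochs[[1]]), x$fs))
  }
  cat("\n")
  invisible(x)
}

#' Subset an epoch set by label or index
#'
#' @param es a [epoch_set()].
#' @param which a label (`"braking"`/`"normal"`) or an integer/logical index.
#' @return A [epoch_set()] with the selected epochs.
#' @export
subset_epochs <- function(es, which) {
  stopifnot(inherits(es, "kfcs_epochs"))
  idx <- if (is.character(which)) es$labels %in% which else which
  epoch_set(es$epochs[idx], es$labels[idx], fs = es$fs,
            subject_id = es$subject_id, channel_labels = es$channel_labels)
}

#' Read a continuous recording from disk
#'
#' The delimited dialect is tab-separated: the header row holds the channel
#' labels (one per subsequent data row) and each following row holds one
#' channel's samples. The sampling rate is not stored in the file and must be
#' supplied via `fs`.
#'
#' @param path file path.
#' @param format `"delimited"` (supported) or `"edf"` (not available in this
#'   build; raises an error).
#' @param fs sampling rate in Hz; required for delimited input.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("delimited", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (format == "edf") {
    stop("EDF input is unsupported in this build (no EDF reader available); ",
         "use format = 'delimited'")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(fs)) stop("fs must be supplied for delimited recordings")
  lines <- readLines(path)
  if (length(lines) < 2L) stop("delimited recording needs a header row and data rows")
  labels <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  rows <- lapply(lines[-1], function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
  if (length(rows) != length(labels)) {
    stop("header lists ", length(labels), " channels but file has ",
         length(rows), " data rows")
  }
  len <- vapply(rows, length, integer(1))
  if (any(len != len[1])) stop("inconsistent row lengths in delimited recording")
  sig <- do.call(rbind, rows)
  if (anyNA(sig)) stop("non-numeric values in delimited recording")
  recording(sig, fs = fs, channel_labels = labels)
}

#' Write a continuous recording as delimited text
#'
#' @param rec a [recording()].
#' @param path output path.
#' @param digits significant digits retained (default 10).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "kfcs_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  for (i in seq_len(nrow(rec$signal))) {
    writeLines(paste(format(rec$signal[i, ], digits = digits, trim = TRUE,
                            scientific = FALSE), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write epoch event files
#'
#' Event files are tab-separated with two columns and no header:
#' onset in seconds, then the class label.
#'
#' @param path file path.
#' @return `read_events`: data.frame with columns `onset` (numeric seconds)
#'   and `label` (character).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, col.names = c("onset", "label"),
                   colClasses = c("numeric", "character"))
  df
}

#' @param events data.frame with columns `onset`, `label`.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  write.table(events[, c("onset", "label")], path, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cut labelled fixed-length epochs out of a continuous recording
#'
#' Sample windows are half-open and 0-based: an event at onset `t` seconds
#' covers samples `[round(t * fs), round(t * fs) + duration * fs)`, so
#' adjacent 1-s events never share samples.
#'
#' @param rec a [recording()].
#' @param events data.frame with columns `onset` (seconds) and `label`.
#' @param duration epoch length in seconds (default 1, the standard segment
#'   length for braking/normal samples).
#' @param subject_id carried into the resulting epoch set.
#' @return A [epoch_set()].
#' @export
extract_epochs <- function(rec, events, duration = 1, subject_id = "S1") {
  stopifnot(inherits(rec, "kfcs_recording"))
  n_samp <- duration * rec$fs
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop("duration * fs must be an integer number of samples")
  }
  n_samp <- as.integer(round(n_samp))
  total <- ncol(rec$signal)
  if (nrow(events) == 0L) {
    return(epoch_set(list(), character(0), fs = rec$fs, subject_id = subject_id,
                     channel_labels = rec$channel_labels))
  }
  eps <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    start0 <- as.integer(round(events$onset[i] * rec$fs))  # 0-based
    if (start0 < 0L || start0 + n_samp > total) {
      stop(sprintf("event at %g s (+%g s) extends past the recording", events$onset[i], duration))
    }
    eps[[i]] <- rec$signal[, (start0 + 1L):(start0 + n_samp), drop = FALSE]
  }
  epoch_set(eps, events$label, fs = rec$fs, subject_id = subject_id,
            channel_labels = rec$channel_labels)
}

#' Load a montage (channel label to 2-D scalp position)
#'
#' Montage files are plain text, one `label x y` triple per line
#' (whitespace-separated). A standard 64-channel 10-10 layout ships with the
#' package: `system.file("extdata", "montage_64_10_10.tsv", package = "kfcs")`.
#'
#' @param path montage file path.
#' @return A `kfcs_montage`: data.frame with columns `label`, `x`, `y`.
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad)) stop("malformed montage line ", bad[1], ": expected 'label x y'")
  label <- vapply(parts, `[[`, character(1), 1L)
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(x) || anyNA(y)) stop("malformed montage line: non-numeric coordinate")
  if (anyDuplicated(label)) {
    stop("duplicate montage label: ", label[duplicated(label)][1])
  }
  structure(data.frame(label = label, x = x, y = y, stringsAsFactors = FALSE),
            class = c("kfcs_montage", "data.frame"))
}
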