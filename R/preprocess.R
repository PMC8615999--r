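# Zero-phase FIR band-pass. No DSP package ships in the target environment,
# so the kernel is a windowed-sinc (Hamming) band-pass built as the difference
# of two unit-DC-gain low-pass kernels: DC gain is exactly zero and the
# symmetric (linear-phase) kernel, applied once with reflection padding and
# group-delay removal, is zero-phase.

fir_lowpass_kernel <- function(cutoff_hz, fs, n_taps) {
  fc <- cutoff_hz / fs                      # cycles per sample
  m <- n_taps - 1L
  k <- seq_len(n_taps) - 1L - m / 2         # symmetric around 0
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:m) / m)  # Hamming
  h <- h * w
  h / sum(h)                                # unit DC gain
}

fir_bandpass_kernel <- function(low_hz, high_hz, fs, n_taps) {
  fir_lowpass_kernel(high_hz, fs, n_taps) - fir_lowpass_kernel(low_hz, fs, n_taps)
}

apply_fir_zerophase <- function(x, h) {
  n <- length(x)
  delay <- (length(h) - 1L) %/% 2L
  pad <- length(h)                          # reflection padding at both ends
  if (n < 2L) return(x * sum(h))
  left <- x[pmin(pad, n - 1L):1L + 1L]      # mirrored, excluding endpoint
  right <- x[n - (1:pmin(pad, n - 1L))]
  xp <- c(left, x, right)
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  y <- as.numeric(y)
  start <- length(left) + length(h) - 1L - delay
  y[start + seq_len(n)]
}

#' Band-pass filter a recording (zero-phase)
#'
#' Restricts signals to the effective EEG band, 0.5–45 Hz by default, with a
#' zero-phase windowed-sinc FIR so epoch timing is preserved. The number of
#' taps defaults to a Hamming-window design whose transition bands are
#' `max(low_hz / 2, 0.25)` Hz at the low edge and `max(high_hz / 4, 2)` Hz at
#' the high edge, capped so the kernel never exceeds the signal length.
#'
#' @param rec a [recording()].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs / 2`.
#' @param n_taps odd kernel length; `NULL` (default) picks it from the
#'   transition-band rule above.
#' @return A filtered [recording()] of identical shape.
#' @export
bandpass <- function(rec, low_hz = 0.5, high_hz = 45, n_taps = NULL) {
  stopifnot(inherits(rec, "kfcs_recording"))
  fs <- rec$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2")
  }
  n <- ncol(rec$signal)
  if (is.null(n_taps)) {
    trans <- min(max(low_hz / 2, 0.25), max(high_hz / 4, 2))
    n_taps <- ceiling(3.3 * fs / trans)
    n_taps <- min(n_taps, if (n %% 2L == 0L) n - 1L else n)
  }
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  if (n_taps < 3L) stop("n_taps must be at least 3")
  h <- fir_bandpass_kernel(low_hz, high_hz, fs, n_taps)
  out <- t(apply(rec$signal, 1L, apply_fir_zerophase, h = h))
  dimnames(out) <- dimnames(rec$signal)
  recording(out, fs = fs, channel_labels = rec$channel_labels)
}

#' Artifact-cleaning hook
#'
#' Artifact rejection (e.g. ICA-based) is deliberately a pluggable hook: the
#' component-selection rule is site-specific and no automatic blink/EMG
#' classifier is bundled. The default cleaner is the identity.
#'
#' @param rec a [recording()].
#' @param cleaner a function `recording -> recording`; must preserve the
#'   channel count and labels.
#' @return `cleaner(rec)`.
#' @export
clean_artifacts <- function(rec, cleaner = identity) {
  stopifnot(inherits(rec, "kfcs_recording"), is.function(cleaner))
  out <- cleaner(rec)
  if (!inherits(out, "kfcs_recording")) stop("cleaner must return a kfcs_recording")
  if (nrow(out$signal) != nrow(rec$signal)) {
    stop("cleaner changed the channel count (", nrow(rec$signal), " -> ",
         nrow(out$signal), ")")
  }
  out
}
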