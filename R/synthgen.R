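#' Synthetic epoch-set configuration
#'
#' Describes the generator's stated world: each epoch is independent Gaussian
#' noise per channel, and the hub channels additionally receive a shared
#' band-limited (0.5–45 Hz) latent source scaled by the class's coupling
#' gain. A braking-vs-normal contrast is planted by giving the braking class
#' a nonzero gain: shared dynamics between hub channels lower their pairwise
#' CsEn, mirroring the direction seen in real recordings (braking-state
#' entropy below normal-driving entropy).
#'
#' @param n_channels number of channels (default 64, a standard cap).
#' @param fs sampling rate in Hz (default 250; the acquisition rate is a
#'   configurable default, not a fixed property of the method).
#' @param epoch_len epoch length in seconds (default 1, the standard segment).
#' @param n_epochs_per_class epochs per class (default 20).
#' @param hub_channels 1-based indices of channels receiving the shared
#'   source; default the first `max(2, n_channels %/% 8)` channels.
#' @param coupling_gain named numeric `c(braking = ..., normal = ...)`;
#'   default braking gain `2 * noise_sd`, normal 0.
#' @param noise_sd per-channel noise standard deviation (default 1).
#' @param seed integer seed; the epoch set is fully determined by it.
#' @return A `kfcs_synth_config` list.
#' @export
synth_config <- function(n_channels = 64, fs = 250, epoch_len = 1,
                         n_epochs_per_class = 20, hub_channels = NULL,
                         coupling_gain = NULL, noise_sd = 1, seed = 1) {
  n_samples <- epoch_len * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("epoch_len * fs must be an integer number of samples")
  }
  if (is.null(hub_channels)) hub_channels <- seq_len(max(2L, n_channels %/% 8L))
  hub_channels <- as.integer(hub_channels)
  if (length(hub_channels) &&
      (min(hub_channels) < 1L || max(hub_channels) > n_channels)) {
    stop("hub_channels must lie in 1..n_channels")
  }
  if (is.null(coupling_gain)) {
    coupling_gain <- c(braking = 2 * noise_sd, normal = 0)
  }
  if (!all(c("braking", "normal") %in% names(coupling_gain))) {
    stop("coupling_gain must be named for both classes")
  }
  if (any(coupling_gain < 0)) stop("coupling_gain must be nonnegative")
  if (length(hub_channels) == 0L && any(coupling_gain > 0)) {
    stop("empty hub set with nonzero coupling gain")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 epoch_len = epoch_len, n_samples = as.integer(round(n_samples)),
                 n_epochs_per_class = as.integer(n_epochs_per_class),
                 hub_channels = hub_channels,
                 coupling_gain = coupling_gain[c("braking", "normal")],
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "kfcs_synth_config")
}

# Band-limited latent source: white noise band-passed to 0.5-45 Hz (clipped
# to the Nyquist margin at low fs) so preprocessing never removes the planted
# structure, then rescaled to unit sd.
band_limited_source <- function(n, fs, rng) {
  z <- rng$rnorm(4L * n)
  rec <- recording(matrix(z, nrow = 1), fs = fs)
  hi <- min(45, 0.45 * fs)
  s <- bandpass(rec, 0.5, hi)$signal[1, ]
  s <- s[n + seq_len(n)]  # interior stretch, away from padding edges
  s / stats::sd(s)
}

#' Generate a labelled synthetic epoch set
#'
#' Epochs alternate braking/normal in blocks; each epoch is fresh noise plus
#' the class gain times a fresh shared latent source on the hub channels.
#' Identical configs (including seed) give bit-identical epoch sets.
#'
#' @param config a [synth_config()].
#' @param subject_id carried into the epoch set.
#' @return A [epoch_set()].
#' @export
generate_epoch_set <- function(config, subject_id = "synth") {
  stopifnot(inherits(config, "kfcs_synth_config"))
  rng <- make_rng(config$seed)
  labels <- rep(c("braking", "normal"), each = config$n_epochs_per_class)
  ch_labels <- sprintf("ch%02d", seq_len(config$n_channels))
  eps <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    noise <- matrix(rng$rnorm(config$n_channels * config$n_samples,
                              sd = config$noise_sd),
                    nrow = config$n_channels)
    gain <- config$coupling_gain[[labels[i]]]
    if (gain > 0 && length(config$hub_channels)) {
      src <- band_limited_source(config$n_samples, config$fs, rng)
      noise[config$hub_channels, ] <-
        noise[config$hub_channels, , drop = FALSE] +
        matrix(gain * src, nrow = length(config$hub_channels),
               ncol = config$n_samples, byrow = TRUE)
    }
    rownames(noise) <- ch_labels
    eps[[i]] <- noise
  }
  epoch_set(eps, labels, fs = config$fs, subject_id = subject_id,
            channel_labels = ch_labels)
}

#' Generate a multi-subject synthetic cohort
#'
#' Per-subject variation is simulated by redrawing `noise_sd` and the braking
#' hub gain from stated ranges with per-subject seeds derived from `seed`.
#'
#' @param n_subjects number of subjects (default 7).
#' @param base_config a [synth_config()] template.
#' @param noise_sd_range,gain_range uniform ranges for the per-subject noise
#'   sd and braking gain (as multiples of that subject's noise sd).
#' @param seed cohort seed.
#' @return Named list of [epoch_set()]s.
#' @export
generate_cohort <- function(n_subjects = 7, base_config = synth_config(),
                            noise_sd_range = c(0.8, 1.2),
                            gain_range = c(1.5, 2.5), seed = 1) {
  rng <- make_rng(seed)
  draws <- matrix(rng$with(stats::runif(2L * n_subjects)), ncol = 2L)
  out <- vector("list", n_subjects)
  names(out) <- sprintf("S%d", seq_len(n_subjects))
  for (s in seq_len(n_subjects)) {
    nsd <- noise_sd_range[1] + diff(noise_sd_range) * draws[s, 1]
    gmul <- gain_range[1] + diff(gain_range) * draws[s, 2]
    cfg <- base_config
    cfg$noise_sd <- nsd
    cfg$coupling_gain <- c(braking = gmul * nsd, normal = 0)
    cfg$seed <- seed * 1000L + s
    out[[s]] <- generate_epoch_set(cfg, subject_id = names(out)[s])
  }
  out
}

#' Write an epoch set to disk as a delimited recording plus event file
#'
#' Epochs are concatenated back-to-back into one continuous delimited
#' recording; the sidecar event file lists one `onset_seconds<TAB>label` line
#' per epoch, so [read_recording()] + [extract_epochs()] round-trips the set.
#'
#' @param es a [epoch_set()].
#' @param signal_path,events_path output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_epoch_set <- function(es, signal_path, events_path) {
  stopifnot(inherits(es, "kfcs_epochs"))
  if (length(es$epochs) == 0L) stop("cannot write an empty epoch set")
  sig <- do.call(cbind, es$epochs)
  rec <- recording(sig, fs = es$fs, channel_labels = es$channel_labels)
  write_recording(rec, signal_path)
  n_samp <- ncol(es$epochs[[1]])
  onsets <- (seq_along(es$epochs) - 1L) * n_samp / es$fs
  write_events(data.frame(onset = onsets, label = es$labels), events_path)
  invisible(list(signal = signal_path, events = events_path))
}
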