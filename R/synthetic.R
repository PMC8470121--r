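#' Per-action synthetic generation profile
#'
#' Describes one action class for the synthetic generator: per-channel
#' amplitude gains during the burst, burst timing, noise levels, and the
#' pass band of the surrogate sEMG noise.
#'
#' @param gains nonnegative per-channel amplitude multipliers (at least one
#'   positive). The default profiles use the muscle-action weight rows of
#'   [table3_fixture()] rescaled to unit mean, so the synthetic ground truth
#'   mirrors the reference muscle-action structure.
#' @param burst_onset burst start time in seconds.
#' @param burst_duration burst length in seconds.
#' @param rest_noise_sd baseline (resting) amplitude standard deviation, in
#'   signal units (volts).
#' @param burst_noise_sd burst amplitude scale: channel `i` has burst
#'   standard deviation `gains[i] * burst_noise_sd` added on top of the rest
#'   level.
#' @param band pass band of the band-limited Gaussian carrier, in Hz.
#' @param ramp duration in seconds of the raised-cosine onset/offset ramps.
#' @param gain_jitter_sd standard deviation of the per-recording log-normal
#'   jitter applied to each channel gain (trial-to-trial variability).
#' @return a list of class `action_profile`.
#' @export
action_profile <- function(gains, burst_onset = 2, burst_duration = 3,
                           rest_noise_sd = 0.01, burst_noise_sd = 0.05,
                           band = c(10, 500), ramp = 0.05,
                           gain_jitter_sd = 0.25) {
  if (any(gains < 0) || all(gains == 0)) {
    stopf("`gains` must be nonnegative with at least one positive entry")
  }
  if (burst_onset <= 0 || burst_duration <= 0) {
    stopf("burst onset and duration must be positive")
  }
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    stopf("`band` must be increasing positive (low, high) in Hz")
  }
  structure(list(gains = gains, burst_onset = burst_onset,
                 burst_duration = burst_duration,
                 rest_noise_sd = rest_noise_sd, burst_noise_sd = burst_noise_sd,
                 band = band, ramp = ramp, gain_jitter_sd = gain_jitter_sd),
            class = "action_profile")
}

#' Simulation configuration
#'
#' @param n_per_class recordings generated per action class.
#' @param fs sampling rate in Hz (default 2000).
#' @param duration trial length in seconds (default 10, i.e. 20,000 samples
#'   per channel at the default rate).
#' @param n_channels number of channels (default 8).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 1L, fs = 2000, duration = 10,
                       n_channels = 8L) {
  if (!is_count(n_per_class)) stopf("`n_per_class` must be a positive integer")
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9) stopf("fs * duration must be an integer sample count")
  structure(list(n_per_class = as.integer(n_per_class), fs = fs,
                 duration = duration, n_channels = as.integer(n_channels)),
            class = "sim_config")
}

#' Default action profiles for six lower-limb actions
#'
#' One [action_profile()] per class `y1..y6`, with channel gains taken from
#' the rows of [table3_fixture()] rescaled to unit mean (the rows already sum
#' to the channel count, so the rescaling is essentially cosmetic). Extra
#' arguments are passed through to [action_profile()] to override timing or
#' noise defaults for all classes at once.
#'
#' @param ... overrides forwarded to [action_profile()].
#' @return named list of six `action_profile` objects.
#' @export
default_action_profiles <- function(...) {
  t3 <- table3_fixture()
  out <- lapply(seq_len(nrow(t3)), function(i) {
    g <- t3[i, ]
    action_profile(gains = g / mean(g), ...)
  })
  names(out) <- paste0("y", seq_len(nrow(t3)))
  out
}

# Band-limited unit-variance Gaussian noise, one column per channel. White
# noise is shaped in the frequency domain by the squared magnitude response
# of a 4th-order Butterworth band-pass (the zero-phase forward-backward
# spectrum), which is exact on the circular FFT grid and avoids per-channel
# time-domain filtering.
bandlimited_noise <- function(n, n_channels, fs, band) {
  if (band[2] >= fs / 2) stopf("band upper edge %g Hz must be below fs/2", band[2])
  key <- paste("blnoise", n, fs, band[1], band[2], sep = "|")
  H2 <- .semgwfm_cache[[key]]
  if (is.null(H2)) {
    bp <- signal::butter(4, band / (fs / 2), type = "pass")
    w <- 2 * pi * (seq_len(n) - 1L) / n
    z1 <- exp(-1i * w)
    num <- outer(z1, seq_along(bp$b) - 1L, `^`) %*% bp$b
    den <- outer(z1, seq_along(bp$a) - 1L, `^`) %*% bp$a
    H2 <- as.vector(Mod(num / den)^2)
    .semgwfm_cache[[key]] <- H2
  }
  z <- matrix(stats::rnorm(n * n_channels), nrow = n)
  z <- Re(stats::mvfft(stats::mvfft(z) * H2, inverse = TRUE)) / n
  sweep(z, 2L, apply(z, 2L, stats::sd), "/")
}

#' Generate one synthetic sEMG recording
#'
#' Surface EMG is modelled as amplitude-modulated band-limited Gaussian
#' noise: each channel carries unit-variance 10-500 Hz noise multiplied by an
#' amplitude envelope that sits at `rest_noise_sd` during rest and rises by
#' `gains[i] * burst_noise_sd` (with raised-cosine ramps) during the burst.
#' Channel gains are jittered per recording by a log-normal factor to emulate
#' trial-to-trial variability.
#'
#' @param profile an [action_profile()].
#' @param config a [sim_config()].
#' @param seed integer seed; fixed seeds give identical recordings.
#' @param label optional class label stored on the recording.
#' @return list with `recording` (a [semg_recording]), `true_onset` (1-based
#'   sample index of the burst ramp start), and `gains_realized` (the
#'   jittered per-channel gains actually applied, the per-trial ground
#'   truth).
#' @export
generate_recording <- function(profile, config = sim_config(), seed = 1L,
                               label = NULL) {
  stopifnot(inherits(profile, "action_profile"), inherits(config, "sim_config"))
  fs <- config$fs
  N <- as.integer(round(fs * config$duration))
  nch <- config$n_channels
  gains <- rep_len(profile$gains, nch)
  if (profile$burst_onset + profile$burst_duration > config$duration) {
    stopf("burst extends past the end of the trial")
  }
  onset <- as.integer(round(profile$burst_onset * fs)) + 1L
  offset <- as.integer(round((profile$burst_onset + profile$burst_duration) * fs))
  n_ramp <- max(1L, as.integer(round(profile$ramp * fs)))
  # raised-cosine activation: 0 at rest, ramps up over n_ramp samples from the
  # true onset, plateau at 1, ramps back down at the end of the burst
  act <- numeric(N)
  act[onset:offset] <- 1
  act[seq(onset, length.out = n_ramp)] <- (1 - cos(pi * seq_len(n_ramp) / n_ramp)) / 2
  act[seq(offset - n_ramp + 1L, length.out = n_ramp)] <-
    (1 + cos(pi * seq_len(n_ramp) / n_ramp)) / 2
  gains_realized <- NULL
  dat <- with_seed(seed, {
    z <- bandlimited_noise(N, nch, fs, profile$band)
    jitter <- exp(stats::rnorm(nch, 0, profile$gain_jitter_sd))
    gains_realized <- gains * jitter
    env <- outer(act, gains_realized * profile$burst_noise_sd) + profile$rest_noise_sd
    z * env
  })
  rec <- semg_recording(dat, fs = fs, label = label)
  list(recording = rec, true_onset = onset, gains_realized = gains_realized)
}

#' Generate a labelled synthetic dataset
#'
#' `n_per_class` recordings per action class, labelled `y1..y6` (or the names
#' of `profiles`), with per-recording seeds derived deterministically from
#' the master seed. With `materialize = FALSE` the manifest stores generator
#' specs instead of signals and recordings are synthesised on demand by
#' [materialize_entry()], keeping memory flat for large runs.
#'
#' @param config a [sim_config()].
#' @param profiles named list of [action_profile()]s, one per class.
#' @param seed master integer seed.
#' @param materialize keep recordings in memory (`TRUE`) or store generator
#'   specs (`FALSE`).
#' @return a [semg_manifest] whose entries carry `label` and `true_onset`.
#' @export
generate_dataset <- function(config = sim_config(), profiles = default_action_profiles(),
                             seed = 1L, materialize = TRUE) {
  if (is.null(names(profiles))) names(profiles) <- paste0("y", seq_along(profiles))
  entries <- list()
  k <- 0L
  for (cls in names(profiles)) {
    for (r in seq_len(config$n_per_class)) {
      k <- k + 1L
      rec_seed <- derive_seed(seed, k)
      entry <- list(label = cls,
                    generator = list(profile = profiles[[cls]], config = config,
                                     seed = rec_seed))
      entry$true_onset <- as.integer(round(profiles[[cls]]$burst_onset * config$fs)) + 1L
      if (materialize) {
        gen <- generate_recording(profiles[[cls]], config, seed = rec_seed,
                                  label = cls)
        entry$recording <- gen$recording
        entry$generator <- NULL
      }
      entries[[k]] <- entry
    }
  }
  semg_manifest(entries)
}
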