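#' Sliding-frame count
#'
#' Number of full frames of length `L` advancing by `I` samples that fit in a
#' signal of `N` samples: `M = floor((N - L)/I) + 1`. Trailing samples that do
#' not fill a complete frame are dropped; for compatible lengths the relation
#' `(M - 1) * I + L = N` holds with equality.
#'
#' @param N signal length in samples.
#' @param L frame length in samples (default 64).
#' @param I frame increment in samples (default 32).
#' @return integer frame count `M`.
#' @export
frame_count <- function(N, L = 64L, I = 32L) {
  if (!is_count(L) || !is_count(I) || I > L) {
    stopf("need 1 <= I <= L, got L = %s, I = %s", L, I)
  }
  if (!is_count(N) || N < L) stopf("signal length %s is shorter than a frame (L = %d)", N, L)
  as.integer((N - L) %/% I + 1L)
}

#' Frame a single-channel signal
#'
#' Frame `i` covers samples `(i-1)*I + 1 ... (i-1)*I + L` (1-based).
#'
#' @param x numeric vector.
#' @inheritParams frame_count
#' @return an `L x M` matrix, one frame per column.
#' @export
frame_signal <- function(x, L = 64L, I = 32L) {
  M <- frame_count(length(x), L, I)
  starts <- (seq_len(M) - 1L) * I
  idx <- outer(seq_len(L), starts, `+`)
  matrix(x[idx], nrow = L, ncol = M)
}

#' Per-frame energy
#'
#' Total energy of each frame: the sum of squared amplitudes over the frame.
#'
#' @param frames an `L x M` frame matrix from [frame_signal()], or a list of
#'   numeric frames.
#' @return numeric vector of `M` nonnegative energies.
#' @export
frame_energy <- function(frames) {
  if (is.list(frames)) {
    if (length(frames) == 0L) stopf("no frames")
    return(vapply(frames, function(f) sum(f^2), numeric(1)))
  }
  if (!is.matrix(frames) || ncol(frames) < 1L) stopf("no frames")
  colSums(frames^2)
}

#' Adaptive energy threshold
#'
#' The mean of a frame-energy series: `th = sum(En) / M`. Applied to the
#' energies of a designated region (or the whole trial) to obtain the onset
#' detection threshold.
#'
#' @param energies numeric vector of frame energies.
#' @return scalar threshold `th`.
#' @export
adaptive_threshold <- function(energies) {
  if (length(energies) == 0L) stopf("empty energy series")
  mean(energies)
}

no_onset_error <- function(msg = "no onset detected: no frame run exceeds the threshold") {
  structure(
    class = c("semgwfm_no_onset", "semgwfm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

#' Detect the action start frame
#'
#' Returns the smallest frame index `f` such that the frame energy exceeds
#' the threshold in frame `f` and in each of the next `run_length - 1` frames
#' (default: the current frame plus the next three). If no such run exists a
#' classed error `semgwfm_no_onset` is signalled, distinguishable from other
#' failures via `tryCatch(..., semgwfm_no_onset = )`.
#'
#' @param energies numeric vector of frame energies.
#' @param th scalar threshold (see [adaptive_threshold()]).
#' @param run_length number of consecutive supra-threshold frames required.
#' @return integer start frame index `FS` (1-based).
#' @export
detect_onset <- function(energies, th, run_length = 4L) {
  if (!is_count(run_length)) stopf("`run_length` must be a positive integer")
  M <- length(energies)
  if (M < run_length) stop(no_onset_error(
    sprintf("fewer frames (%d) than the required run length (%d)", M, run_length)))
  above <- as.integer(energies > th)
  cs <- cumsum(c(0L, above))
  run_sums <- cs[(run_length + 1L):(M + 1L)] - cs[seq_len(M - run_length + 1L)]
  hit <- which(run_sums == run_length)
  if (length(hit) == 0L) stop(no_onset_error())
  as.integer(hit[1L])
}

#' Channel-combined energy profile of a recording
#'
#' Frames every channel and returns the per-frame energy summed over
#' channels (the default single-trigger profile) or the per-channel energy
#' matrix.
#'
#' @param rec a [semg_recording].
#' @inheritParams frame_count
#' @param combine `"sum"` for the channel-summed profile (vector), `"none"`
#'   for an `M x n_channels` matrix.
#' @return numeric vector or matrix of frame energies.
#' @export
energy_profile <- function(rec, L = 64L, I = 32L, combine = c("sum", "none")) {
  combine <- match.arg(combine)
  per_ch <- vapply(seq_len(n_channels(rec)), function(ch) {
    frame_energy(frame_signal(rec$data[, ch], L, I))
  }, numeric(frame_count(n_samples(rec), L, I)))
  if (!is.matrix(per_ch)) per_ch <- matrix(per_ch, nrow = 1L)
  if (combine == "sum") rowSums(per_ch) else per_ch
}

#' Detect the onset frame of a recording
#'
#' Computes the channel-summed energy profile and the adaptive threshold,
#' then applies [detect_onset()]. With `threshold_from = "all"` (default) the
#' threshold is the mean frame energy of the whole trial, which for a trial
#' containing both rest and an action burst falls between the two energy
#' levels; `"rest"` instead averages only the frames of the leading
#' `rest_window` seconds, treating them as a standing-rest reference.
#'
#' @param rec a [semg_recording].
#' @inheritParams frame_count
#' @param run_length consecutive supra-threshold frames required (default 4).
#' @param threshold_from `"all"` or `"rest"`.
#' @param rest_window length in seconds of the leading rest region used when
#'   `threshold_from = "rest"`.
#' @return list with `FS` (start frame), `th`, and the `energies` profile.
#' @export
detect_onset_recording <- function(rec, L = 64L, I = 32L, run_length = 4L,
                                   threshold_from = c("all", "rest"),
                                   rest_window = 0.5) {
  threshold_from <- match.arg(threshold_from)
  en <- energy_profile(rec, L, I, combine = "sum")
  if (threshold_from == "rest") {
    n_rest <- floor((round(rest_window * rec$fs) - L) / I) + 1
    if (n_rest < 1) stopf("rest window too short for one frame")
    th <- adaptive_threshold(en[seq_len(min(n_rest, length(en)))])
  } else {
    th <- adaptive_threshold(en)
  }
  FS <- detect_onset(en, th, run_length = run_length)
  list(FS = FS, th = th, energies = en)
}

#' Extract the main feature segment
#'
#' Converts the start frame to its first sample, `SN = (FS - 1) * I + 1`,
#' skips the 0.5 s initial segment (`MSN = SN + round(0.5 * fs)`), and takes
#' the following 2 s (`MEN = MSN + 2 * fs`): the returned segment covers
#' samples `MSN ... MEN - 1`, exactly `2 * fs` samples on every channel.
#'
#' @param rec a [semg_recording].
#' @param FS start frame index from [detect_onset_recording()].
#' @inheritParams frame_count
#' @return list with `segment` (a [semg_recording]) and `bounds` (list with
#'   `FS`, `SN`, `MSN`, `MEN`, `fs`).
#' @export
extract_main_segment <- function(rec, FS, L = 64L, I = 32L) {
  if (!is_count(FS)) stopf("`FS` must be a positive integer frame index")
  FS <- as.integer(FS)
  N <- n_samples(rec)
  fs <- rec$fs
  SN <- (FS - 1L) * I + 1L
  MSN <- SN + as.integer(round(0.5 * fs))
  MEN <- MSN + as.integer(round(2 * fs))
  if (MEN > N) {
    stopf("recording too short after onset: need sample %d, have %d", MEN, N,
          class = "semgwfm_short_recording")
  }
  seg <- semg_recording(rec$data[MSN:(MEN - 1L), , drop = FALSE], fs = fs,
                        channel_labels = rec$channel_labels,
                        label = rec$label, subject_id = rec$subject_id)
  list(segment = seg,
       bounds = list(FS = as.integer(FS), SN = SN, MSN = MSN, MEN = MEN, fs = fs))
}

#' Denoise a recording
#'
#' Standard sEMG conditioning: a 4th-order Butterworth high-pass (default
#' corner 10 Hz, removes baseline drift and DC), a 2nd-order Butterworth
#' band-stop notch around the power-line frequency (default 50 Hz, +/- 2 Hz),
#' and per-channel wavelet soft-threshold denoising (db4, level 4, universal
#' threshold; see [wavelet_denoise()]). All filters are applied forward and
#' backward (zero phase). Each stage can be switched off.
#'
#' @param rec a [semg_recording].
#' @param highpass high-pass corner in Hz, or `NULL` to skip.
#' @param notch power-line frequency in Hz, or `NULL` to skip.
#' @param notch_halfwidth half-width of the stop band in Hz.
#' @param wavelet,wp_level wavelet family and decomposition depth for the
#'   thresholding stage; set `wavelet = NULL` to skip it.
#' @return the denoised [semg_recording].
#' @export
denoise <- function(rec, highpass = 10, notch = 50, notch_halfwidth = 2,
                    wavelet = "db4", wp_level = 4L) {
  stopifnot(inherits(rec, "semg_recording"))
  fs <- rec$fs
  N <- n_samples(rec)
  if (N < 64L) stopf("recording too short to filter (%d samples)", N)
  dat <- rec$data
  if (!is.null(highpass)) {
    if (highpass >= fs / 2) {
      stopf("sampling rate %g Hz too low for a %g Hz high-pass corner", fs, highpass)
    }
    hp <- signal::butter(4, highpass / (fs / 2), type = "high")
    dat <- apply(dat, 2L, function(x) signal::filtfilt(hp, x))
  }
  if (!is.null(notch) && notch < fs / 2) {
    ns <- signal::butter(2, c(notch - notch_halfwidth, notch + notch_halfwidth) / (fs / 2),
                         type = "stop")
    dat <- apply(dat, 2L, function(x) signal::filtfilt(ns, x))
  }
  if (!is.null(wavelet)) {
    dat <- apply(dat, 2L, function(x) wavelet_denoise(x, wavelet, wp_level))
  }
  semg_recording(dat, fs = fs, channel_labels = rec$channel_labels,
                 label = rec$label, subject_id = rec$subject_id)
}
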