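#' Feature extraction configuration
#'
#' @param wa_threshold amplitude threshold for the Willison amplitude, in the
#'   signal's units (default 1e-5, i.e. 10 uV for signals in volts). This is
#'   an amplitude threshold, independent of the energy threshold used for
#'   onset detection.
#' @param wavelet wavelet family for the packet-energy feature (default db4).
#' @param wp_level wavelet-packet depth (default 3).
#' @param log_floor positive lower clamp applied inside the log10 of the
#'   packet-energy feature so all-zero windows stay finite.
#' @param mav_denom `"printed"` uses the `1/(n-1)` window normaliser that the
#'   MAV and RMS definitions are written with; `"conventional"` restores the
#'   usual `1/n`.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(wa_threshold = 1e-5, wavelet = "db4", wp_level = 3L,
                           log_floor = 1e-12, mav_denom = c("printed", "conventional")) {
  mav_denom <- match.arg(mav_denom)
  if (wa_threshold < 0) stopf("`wa_threshold` must be >= 0")
  if (!is_count(wp_level)) stopf("`wp_level` must be a positive integer")
  if (!is.numeric(log_floor) || log_floor <= 0) stopf("`log_floor` must be > 0")
  structure(list(wa_threshold = wa_threshold, wavelet = wavelet,
                 wp_level = as.integer(wp_level), log_floor = log_floor,
                 mav_denom = mav_denom),
            class = "feature_config")
}

#' Window a main-feature segment
#'
#' Sliding windows with the same convention as [frame_signal()] (window `j`
#' covers samples `(j-1)*inc_win + 1 ... (j-1)*inc_win + n_win`; incomplete
#' trailing windows are dropped).
#'
#' @param x single-channel numeric vector (a main-feature segment).
#' @param n_win window length in samples (default 64).
#' @param inc_win window increment in samples (default 32).
#' @return an `n_win x M_win` matrix, one window per column.
#' @export
window_segment <- function(x, n_win = 64L, inc_win = 32L) {
  frame_signal(x, L = n_win, I = inc_win)
}

window_denom <- function(n, mav_denom) {
  if (n < 2L) stopf("windows must contain at least 2 samples")
  if (mav_denom == "printed") n - 1L else n
}

#' Mean absolute value (MAV)
#'
#' Mean over windows of the normalised absolute-amplitude sum. The window
#' normaliser follows the printed definition `1/(n-1)`; pass
#' `mav_denom = "conventional"` for `1/n`.
#'
#' @param windows window matrix from [window_segment()].
#' @param mav_denom see [feature_config()].
#' @return scalar MAV value (>= 0).
#' @export
feature_mav <- function(windows, mav_denom = "printed") {
  denom <- window_denom(nrow(windows), mav_denom)
  mean(colSums(abs(windows)) / denom)
}

#' Root mean square (RMS)
#'
#' Mean over windows of `sqrt(sum(x^2) / (n - 1))` — each window is rooted
#' individually, mirroring the per-window structure of the MAV.
#'
#' @inheritParams feature_mav
#' @return scalar RMS value (>= 0).
#' @export
feature_rms <- function(windows, mav_denom = "printed") {
  denom <- window_denom(nrow(windows), mav_denom)
  mean(sqrt(colSums(windows^2) / denom))
}

#' Willison amplitude (WA)
#'
#' Mean over windows of the number of consecutive-sample amplitude jumps
#' whose magnitude reaches the threshold: `sum over i of
#' 1(|x[i] - x[i+1]| >= wa_threshold)`.
#'
#' @inheritParams feature_mav
#' @param wa_threshold amplitude threshold (same units as the signal).
#' @return scalar WA value (>= 0; at most `n_win - 1`).
#' @export
feature_wa <- function(windows, wa_threshold = 1e-5) {
  if (nrow(windows) < 2L) stopf("windows must contain at least 2 samples")
  jumps <- abs(diff(windows)) >= wa_threshold
  mean(colSums(jumps))
}

#' Wavelet-packet coefficient energy (EC1)
#'
#' `log10` of the mean over windows of the total squared wavelet-packet
#' coefficient energy of the window, taken across all leaf nodes of a
#' depth-`wp_level` packet decomposition. The mean energy is clamped below at
#' `log_floor` so silent segments return `log10(log_floor)` instead of -Inf.
#'
#' Because the packet transform used here is orthonormal with periodic
#' boundaries and the energy is summed over the complete leaf set, the
#' per-window coefficient energy equals the window's signal energy exactly
#' (Parseval); the wavelet choice affects how energy is distributed across
#' leaves, not the total.
#'
#' @inheritParams feature_mav
#' @param wavelet,wp_level,log_floor see [feature_config()].
#' @return scalar EC1 value (log10 energy units).
#' @export
feature_ec1 <- function(windows, wavelet = "db4", wp_level = 3L,
                        log_floor = 1e-12) {
  n <- nrow(windows)
  if (n < 2L^wp_level) {
    stopf("window length %d shorter than 2^%d", n, wp_level)
  }
  if (n %% 2L^wp_level != 0L) {
    stopf("window length %d must be divisible by 2^%d for the packet transform",
          n, wp_level)
  }
  W <- wpt_matrix(n, wp_level, wavelet)
  energy <- colSums((W %*% windows)^2)
  log10(max(mean(energy), log_floor))
}

#' Per-channel feature vectors of a main-feature segment
#'
#' Windows every channel and computes the fixed-order feature vector
#' `[MAV, RMS, WA, EC1]`.
#'
#' @param segment a [semg_recording] (typically the 2 s main feature segment).
#' @param n_win,inc_win window length and increment in samples.
#' @param config a [feature_config()].
#' @return an `n_channels x 4` matrix with columns `MAV`, `RMS`, `WA`, `EC1`
#'   and one row per channel.
#' @export
extract_channel_features <- function(segment, n_win = 64L, inc_win = 32L,
                                     config = feature_config()) {
  stopifnot(inherits(segment, "semg_recording"))
  out <- t(vapply(seq_len(n_channels(segment)), function(ch) {
    w <- window_segment(segment$data[, ch], n_win, inc_win)
    c(MAV = feature_mav(w, config$mav_denom),
      RMS = feature_rms(w, config$mav_denom),
      WA = feature_wa(w, config$wa_threshold),
      EC1 = feature_ec1(w, config$wavelet, config$wp_level, config$log_floor))
  }, numeric(4)))
  rownames(out) <- segment$channel_labels
  out
}

#' Normalise feature matrices to (-1, 1)
#'
#' Fits a per-feature affine map on the training matrix sending the training
#' `[min, max]` range to `[-1, 1]`, and applies the same map to the test
#' matrix (whose values may therefore fall outside `[-1, 1]`). A feature that
#' is constant on the training set is mapped to 0, with a warning.
#'
#' @param train numeric matrix, one row per sample.
#' @param test optional numeric matrix with the same columns.
#' @return list with `train`, `test` (or `NULL`), and `scaler`
#'   (list with the per-feature `min` and `max` fitted on the training data).
#' @export
normalize_features <- function(train, test = NULL) {
  if (!is.matrix(train) || nrow(train) == 0L) stopf("empty training matrix")
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  flat <- hi - lo <= 0
  if (any(flat)) {
    warning(sprintf("%d constant feature(s) mapped to 0", sum(flat)))
  }
  scale_mat <- function(m) {
    out <- m
    for (j in seq_len(ncol(m))) {
      out[, j] <- if (flat[j]) 0 else 2 * (m[, j] - lo[j]) / (hi[j] - lo[j]) - 1
    }
    out
  }
  list(train = scale_mat(train),
       test = if (!is.null(test)) scale_mat(test),
       scaler = list(min = lo, max = hi))
}
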