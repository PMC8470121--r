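#' Per-channel absolute-amplitude energies
#'
#' The energy of a channel is the sum of absolute amplitudes of the
#' (denoised) signal over the given sample region — the quantity tabulated
#' per muscle and action in the packaged energy fixture ([table2_fixture()]).
#'
#' @param rec a [semg_recording] (typically denoised).
#' @param region integer vector of sample indices (1-based), or `NULL` for
#'   the whole recording. In the pipeline the region is the main feature
#'   segment.
#' @return an object of class `energy_table`: list with `energies` (named
#'   per-channel vector) and `total` (their sum).
#' @export
channel_energies <- function(rec, region = NULL) {
  stopifnot(inherits(rec, "semg_recording"))
  if (is.null(region)) region <- seq_len(n_samples(rec))
  if (length(region) == 0L) stopf("empty region")
  if (min(region) < 1L || max(region) > n_samples(rec)) {
    stopf("region [%d, %d] outside recording of %d samples",
          min(region), max(region), n_samples(rec))
  }
  e <- colSums(abs(rec$data[region, , drop = FALSE]))
  structure(list(energies = e, total = sum(e)), class = "energy_table")
}

#' Channel weights from energies
#'
#' The weighted feature method's muscle-action correlation coefficients:
#' `C[i] = n * e[i] / sum(e)` for `n` channels, so the weights always sum to
#' `n` and are invariant to a common rescaling of all energies. Applied to
#' the rows of [table2_fixture()] this reproduces the packaged correlation
#' table ([table3_fixture()]).
#'
#' @param energies an `energy_table` from [channel_energies()], or a numeric
#'   vector of per-channel energies.
#' @return numeric vector of weights `C[i]`, one per channel.
#' @export
channel_weights <- function(energies) {
  e <- if (inherits(energies, "energy_table")) energies$energies else energies
  if (!is.numeric(e) || length(e) < 1L) stopf("need at least one channel energy")
  if (any(e < 0)) stopf("energies must be nonnegative")
  total <- sum(e)
  if (total <= 0) stopf("total energy is zero; weights are undefined",
                        class = "semgwfm_degenerate")
  length(e) * e / total
}

#' Apply channel weights to per-channel features
#'
#' Scales each channel's feature vector by its weight and either concatenates
#' the scaled vectors (default, dimension `n_channels * n_features`) or sums
#' them (the literal fusion sum, dimension `n_features`).
#'
#' @param features an `n_channels x n_features` matrix, e.g. from
#'   [extract_channel_features()].
#' @param weights numeric vector of per-channel weights.
#' @param mode `"concat"` or `"sum"`.
#' @return named numeric fusion feature vector.
#' @export
apply_weights <- function(features, weights, mode = c("concat", "sum")) {
  mode <- match.arg(mode)
  if (!is.matrix(features)) stopf("`features` must be a matrix")
  if (length(weights) != nrow(features)) {
    stopf("%d weights for %d channels", length(weights), nrow(features))
  }
  scaled <- features * weights
  if (mode == "sum") {
    out <- colSums(scaled)
  } else {
    out <- as.vector(t(scaled))
    names(out) <- as.vector(t(outer(rownames(features), colnames(features),
                                    paste, sep = "_")))
  }
  out
}

#' Build a fusion-feature dataset from a manifest
#'
#' Runs each manifest entry through the full feature pipeline: optional
#' denoising, onset detection on the channel-summed energy profile, main
#' feature segment extraction, per-channel features, per-recording channel
#' weights from the segment's own absolute-amplitude energies, and weighted
#' fusion. Entries whose onset cannot be detected (or whose recording is too
#' short after onset) are excluded and reported.
#'
#' @param manifest a [semg_manifest].
#' @param L,I frame length and increment for onset detection.
#' @param n_win,inc_win window length and increment for feature extraction.
#' @param config a [feature_config()].
#' @param mode fusion mode, `"concat"` (default) or `"sum"`.
#' @param weighted apply the channel weights (`TRUE`) or fuse unweighted
#'   features (`FALSE`, the ablation baseline).
#' @param denoise_cfg `NULL` to skip denoising, or a list of arguments for
#'   [denoise()] (empty list for its defaults).
#' @param run_length,threshold_from,rest_window onset-detection parameters,
#'   see [detect_onset_recording()].
#' @return list with `X` (fusion matrix, one row per retained recording),
#'   `y` (factor of labels), `kept` (manifest indices of retained rows), and
#'   `excluded` (data.frame of indices and reasons; zero rows if none).
#' @export
build_dataset <- function(manifest, L = 64L, I = 32L, n_win = 64L,
                          inc_win = 32L, config = feature_config(),
                          mode = c("concat", "sum"), weighted = TRUE,
                          denoise_cfg = NULL, run_length = 4L,
                          threshold_from = "all", rest_window = 0.5) {
  stopifnot(inherits(manifest, "semg_manifest"))
  mode <- match.arg(mode)
  rows <- list()
  kept <- integer(0)
  exc_idx <- integer(0)
  exc_why <- character(0)
  for (i in seq_along(manifest$entries)) {
    entry <- manifest$entries[[i]]
    rec <- materialize_entry(entry)
    if (!is.null(denoise_cfg)) rec <- do.call(denoise, c(list(rec), denoise_cfg))
    res <- tryCatch({
      ons <- detect_onset_recording(rec, L = L, I = I, run_length = run_length,
                                    threshold_from = threshold_from,
                                    rest_window = rest_window)
      seg <- extract_main_segment(rec, ons$FS, L = L, I = I)
      feats <- extract_channel_features(seg$segment, n_win, inc_win, config)
      if (weighted) {
        w <- channel_weights(channel_energies(rec, seg$bounds$MSN:(seg$bounds$MEN - 1L)))
      } else {
        w <- rep(1, nrow(feats))
      }
      apply_weights(feats, w, mode)
    },
    semgwfm_no_onset = function(e) e,
    semgwfm_short_recording = function(e) e)
    if (inherits(res, "condition")) {
      exc_idx <- c(exc_idx, i)
      exc_why <- c(exc_why, conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
      kept <- c(kept, i)
    }
  }
  if (length(rows) == 0L) stopf("no recording survived the pipeline")
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  list(X = X,
       y = factor(manifest_labels(manifest)[kept]),
       kept = kept,
       excluded = data.frame(index = exc_idx, reason = exc_why,
                             stringsAsFactors = FALSE))
}
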