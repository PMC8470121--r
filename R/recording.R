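#' Multichannel sEMG recording
#'
#' Canonical container for one sEMG trial. Amplitudes are stored as a numeric
#' matrix with one row per sample and one column per channel (the transpose of
#' the conceptual channels-by-samples view; this matches the on-disk CSV layout
#' and makes per-channel column operations cheap). All sample indices exposed
#' to the user are 1-based.
#'
#' @param data numeric matrix, samples in rows, channels in columns. A vector
#'   is treated as a single channel.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_labels optional character vector of muscle names, one per
#'   channel. Defaults to `CH1..CHn`; the conventional montage is CH1 right
#'   rectus femoris through CH8 left gastrocnemius.
#' @param label optional action class label (e.g. `"y1"` for raise right leg).
#' @param subject_id optional subject identifier.
#' @return an object of class `semg_recording`.
#' @export
semg_recording <- function(data, fs, channel_labels = NULL, label = NULL,
                           subject_id = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, ncol = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric matrix (samples x channels)")
  }
  if (nrow(data) < 1L) stopf("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stopf("`fs` must be a positive scalar (Hz)")
  }
  nch <- ncol(data)
  if (is.null(channel_labels)) channel_labels <- paste0("CH", seq_len(nch))
  if (length(channel_labels) != nch) {
    stopf("expected %d channel labels, got %d", nch, length(channel_labels))
  }
  colnames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         label = label, subject_id = subject_id),
    class = "semg_recording"
  )
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param rec a `semg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Number of channels
#' @param rec a `semg_recording`.
#' @return integer channel count.
#' @export
n_channels <- function(rec) ncol(rec$data)

#' Read a recording from CSV
#'
#' Expects a comma-separated numeric table with one column per channel. A
#' single non-numeric first row is auto-detected and used as channel labels
#' (overridable via `channel_labels`); there must be no index column.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz.
#' @param channel_labels optional channel names; default taken from the header
#'   row if present, else `CH1..CHn`.
#' @param label,subject_id optional metadata, stored on the recording.
#' @return a [semg_recording].
#' @export
read_recording <- function(path, fs, channel_labels = NULL, label = NULL,
                           subject_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "character",
                    strip.white = TRUE, fill = FALSE, blank.lines.skip = TRUE),
    error = function(e) stopf("malformed CSV %s: %s", path, conditionMessage(e))
  )
  if (nrow(raw) == 0L) stopf("empty CSV: %s", path)
  first <- suppressWarnings(as.numeric(unlist(raw[1L, ], use.names = FALSE)))
  has_header <- anyNA(first)
  header <- NULL
  if (has_header) {
    header <- as.character(unlist(raw[1L, ], use.names = FALSE))
    raw <- raw[-1L, , drop = FALSE]
    if (nrow(raw) == 0L) stopf("CSV %s has a header but no data rows", path)
  }
  num <- suppressWarnings(
    vapply(raw, as.numeric, numeric(nrow(raw)), USE.NAMES = FALSE)
  )
  if (!is.matrix(num)) num <- matrix(num, ncol = ncol(raw))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    data_row <- bad[["row"]] + if (has_header) 1L else 0L
    stopf("non-numeric cell in %s at row %d, column %d",
          path, data_row, bad[["col"]])
  }
  if (is.null(channel_labels) && !is.null(header)) channel_labels <- header
  semg_recording(num, fs = fs, channel_labels = channel_labels,
                 label = label, subject_id = subject_id)
}

#' Write a recording to CSV
#'
#' One column per channel, header row of channel labels, full double
#' precision; [read_recording()] round-trips the data to within 1e-9.
#'
#' @param rec a [semg_recording].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "semg_recording"))
  if (n_samples(rec) < 1L) stopf("refusing to write an empty recording")
  df <- as.data.frame(rec$data)
  names(df) <- rec$channel_labels
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dataset manifest
#'
#' An ordered collection of labelled recordings with an optional train/test
#' split assignment. Each entry either holds the recording in memory
#' (`recording`), a CSV path (`path`), or a generator closure spec
#' (`generator`, as produced by [generate_dataset()] with
#' `materialize = FALSE`); [materialize_entry()] resolves any of the three.
#'
#' @param entries list of entries; each a list with at least `label`, plus one
#'   of `recording` / `path` / `generator`, and optionally `subject_id`,
#'   `true_onset`, `fs`.
#' @return an object of class `semg_manifest`.
#' @export
semg_manifest <- function(entries) {
  if (!is.list(entries) || length(entries) == 0L) {
    stopf("manifest needs at least one entry")
  }
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (is.null(e$label)) stopf("manifest entry %d has no label", i)
    if (is.null(e$recording) && is.null(e$path) && is.null(e$generator)) {
      stopf("manifest entry %d has no recording, path or generator", i)
    }
  }
  structure(list(entries = entries,
                 split = rep(NA_character_, length(entries))),
            class = "semg_manifest")
}

#' @export
print.semg_manifest <- function(x, ...) {
  lab <- manifest_labels(x)
  cat(sprintf("<semg_manifest> %d recordings, %d classes\n",
              length(x$entries), length(unique(lab))))
  print(table(label = lab, split = factor(x$split, c("train", "test"))))
  invisible(x)
}

#' Labels of all manifest entries
#' @param manifest a [semg_manifest].
#' @return character vector of class labels, in manifest order.
#' @export
manifest_labels <- function(manifest) {
  vapply(manifest$entries, function(e) as.character(e$label), character(1))
}

#' Resolve a manifest entry to an in-memory recording
#' @param entry one element of `manifest$entries`.
#' @return a [semg_recording].
#' @export
materialize_entry <- function(entry) {
  if (!is.null(entry$recording)) return(entry$recording)
  if (!is.null(entry$generator)) {
    g <- entry$generator
    return(generate_recording(g$profile, g$config, seed = g$seed)$recording)
  }
  read_recording(entry$path, fs = entry$fs, label = entry$label,
                 subject_id = entry$subject_id)
}

#' Split a manifest into training and test sets
#'
#' Stratified per-class split: for every class, `round(fraction * n_class)`
#' entries are drawn (uniformly, seeded) into the training set and the rest
#' into the test set, so the realised per-class fraction is within one record
#' of the request. Deterministic for a fixed seed.
#'
#' @param manifest a [semg_manifest].
#' @param fraction per-class training fraction in (0, 1].
#' @param seed integer seed.
#' @return the manifest with its `split` slot filled (`"train"`/`"test"`).
#' @export
split_dataset <- function(manifest, fraction = 0.5, seed = 1L) {
  stopifnot(inherits(manifest, "semg_manifest"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stopf("`fraction` must be in (0, 1]")
  }
  lab <- manifest_labels(manifest)
  split <- rep(NA_character_, length(lab))
  with_seed(seed, {
    for (cls in sort(unique(lab))) {
      idx <- which(lab == cls)
      if (length(idx) < 2L && fraction < 1) {
        stopf("class %s has %d record(s); need at least 2 to split", cls,
              length(idx))
      }
      n_train <- round(fraction * length(idx))
      n_train <- max(1L, min(length(idx), n_train))
      tr <- sample(idx, n_train)
      split[tr] <- "train"
      split[setdiff(idx, tr)] <- "test"
    }
  })
  manifest$split <- split
  manifest
}
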