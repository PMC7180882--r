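#' A single-lead ECG recording
#'
#' @param record_id Record identifier string.
#' @param samples Numeric vector of amplitudes (millivolts).
#' @param fs Sampling rate in Hz (300 for the Challenge 2017 data).
#' @param label One of [af_classes()].
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(record_id, samples, fs, label) {
  stopifnot(length(samples) > 0, is.numeric(samples), fs > 0)
  check_labels(label)
  structure(list(record_id = as.character(record_id),
                 samples = as.numeric(samples), fs = as.numeric(fs),
                 label = as.character(label)),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %s: %d samples (%.1f s at %g Hz), label %s\n",
              x$record_id, length(x$samples), length(x$samples) / x$fs,
              x$fs, x$label))
  invisible(x)
}

#' Length-normalization configuration
#'
#' @param bin_width_s Histogram bin width in seconds used for threshold
#'   selection (default 1 s).
#' @param overlap_fraction Overlap between adjacent windows of a long
#'   recording, in (0, 1); default 0.5.
#' @param threshold_samples Optional fixed segment length in samples,
#'   overriding histogram-based selection.
#' @return A `length_norm_config` list.
#' @export
length_norm_config <- function(bin_width_s = 1, overlap_fraction = 0.5,
                               threshold_samples = NULL) {
  stopifnot(bin_width_s > 0)
  if (overlap_fraction <= 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(bin_width_s = bin_width_s,
                 overlap_fraction = overlap_fraction,
                 threshold_samples = if (is.null(threshold_samples)) NULL
                                     else as.integer(threshold_samples)),
            class = "length_norm_config")
}

#' Histogram-based segment-length threshold
#'
#' Bins the recording durations into `bin_width_s`-wide bins and returns the
#' sample count at the left edge of the modal bin. On the Challenge 2017
#' length distribution (mode at 30 s, 300 Hz) this yields 9000 samples. Ties
#' between equally full bins are broken toward the smaller duration.
#'
#' @param lengths Integer vector of recording lengths in samples.
#' @param fs Sampling rate in Hz.
#' @param config A [length_norm_config()].
#' @return Integer threshold in samples.
#' @export
#' @examples
#' compute_length_threshold(rep(9000, 10), fs = 300)
compute_length_threshold <- function(lengths, fs,
                                     config = length_norm_config()) {
  if (length(lengths) == 0) stop("lengths must be non-empty", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  durations <- lengths / fs
  bins <- floor(durations / config$bin_width_s)
  tab <- table(bins)
  modal <- as.numeric(names(tab))[tab == max(tab)]
  as.integer(round(min(modal) * config$bin_width_s * fs))
}

#' Chop a long recording into overlapping fixed-length windows
#'
#' Windows of exactly `threshold` samples start at stride
#' `threshold * (1 - overlap_fraction)`; if the last stride-aligned window
#' does not reach the end of the recording, one extra end-anchored window
#' covering the final `threshold` samples is appended, so every sample is
#' covered. An 18,600-sample recording with threshold 9000 and 50% overlap
#' yields four windows (starts 0, 4500, 9000, 9600).
#'
#' @param samples Numeric vector longer than `threshold`.
#' @param threshold Window length in samples.
#' @param overlap_fraction Overlap fraction in (0, 1); default 0.5.
#' @return List with `starts` (0-based window offsets) and `windows` (list of
#'   numeric vectors).
#' @export
segment_long <- function(samples, threshold, overlap_fraction = 0.5) {
  threshold <- as.integer(threshold)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (overlap_fraction <= 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in (0, 1)", call. = FALSE)
  }
  L <- length(samples)
  if (L <= threshold) {
    stop("segment_long requires a recording longer than the threshold",
         call. = FALSE)
  }
  stride <- max(1L, as.integer(round(threshold * (1 - overlap_fraction))))
  starts <- seq.int(0L, L - threshold, by = stride)
  if (starts[length(starts)] + threshold < L) {
    starts <- c(starts, L - threshold)
  }
  list(starts = as.integer(starts),
       windows = lapply(starts, function(s) samples[(s + 1):(s + threshold)]))
}

#' Tile a short recording up to the threshold length
#'
#' The recording is repeated end-to-end and truncated to exactly `threshold`
#' samples (periodic tiling): `output[i] == input[i mod length(input)]`.
#'
#' @param samples Numeric vector shorter than `threshold` (non-empty).
#' @param threshold Target length in samples.
#' @return Numeric vector of length `threshold`.
#' @export
tile_short <- function(samples, threshold) {
  threshold <- as.integer(threshold)
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  if (length(samples) >= threshold) {
    stop("tile_short requires a recording shorter than the threshold",
         call. = FALSE)
  }
  rep_len(samples, threshold)
}

#' Construct a segment dataset
#'
#' @param samples Numeric matrix, one segment per row.
#' @param info Data frame with columns `source_id`, `label`, `start_index`
#'   (0-based offset in the source recording; `NA` marks a tiled segment).
#' @param threshold_samples Common segment length.
#' @return An object of class `segment_dataset` with a `class_counts` field.
#' @export
segment_dataset <- function(samples, info, threshold_samples) {
  stopifnot(is.matrix(samples), nrow(samples) == nrow(info),
            ncol(samples) == threshold_samples)
  check_labels(info$label)
  counts <- table(factor(info$label, levels = af_classes()))
  structure(list(samples = samples, info = info,
                 threshold_samples = as.integer(threshold_samples),
                 class_counts = as.integer(counts)),
            class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("<segment_dataset> %d segments of %d samples\n",
              nrow(x$samples), x$threshold_samples))
  cat("  class counts:",
      paste(sprintf("%s=%d", af_classes(), x$class_counts), collapse = ", "),
      "\n")
  invisible(x)
}

#' Normalize a set of recordings to equal-length labeled segments
#'
#' Selects the length threshold from the duration histogram (unless
#' overridden in `config`), then per recording: equal-length recordings pass
#' through unchanged; longer recordings are chopped into overlapping windows
#' ([segment_long()]); shorter recordings are periodically tiled
#' ([tile_short()]). Every segment inherits its source recording's label.
#' Segment order is deterministic: input order, then window order.
#'
#' @param recordings List of [ecg_recording()] objects sharing one sampling
#'   rate.
#' @param config A [length_norm_config()].
#' @return A `segment_dataset`.
#' @export
normalize_dataset <- function(recordings, config = length_norm_config()) {
  if (length(recordings) == 0) {
    stop("recordings must be non-empty", call. = FALSE)
  }
  stopifnot(all(vapply(recordings, inherits, logical(1), "ecg_recording")))
  fs <- unique(vapply(recordings, function(r) r$fs, numeric(1)))
  if (length(fs) != 1) {
    stop("all recordings must share one sampling rate", call. = FALSE)
  }
  lens <- vapply(recordings, function(r) length(r$samples), integer(1))
  threshold <- if (!is.null(config$threshold_samples)) {
    config$threshold_samples
  } else {
    compute_length_threshold(lens, fs, config)
  }
  rows <- list()
  mats <- list()
  for (r in recordings) {
    L <- length(r$samples)
    if (L == threshold) {
      mats[[length(mats) + 1L]] <- matrix(r$samples, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = r$record_id, label = r$label, start_index = 0L,
        stringsAsFactors = FALSE)
    } else if (L > threshold) {
      sl <- segment_long(r$samples, threshold, config$overlap_fraction)
      mats[[length(mats) + 1L]] <- do.call(rbind, sl$windows)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = r$record_id, label = r$label, start_index = sl$starts,
        stringsAsFactors = FALSE)
    } else {
      mats[[length(mats) + 1L]] <- matrix(tile_short(r$samples, threshold), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = r$record_id, label = r$label,
        start_index = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  segment_dataset(do.call(rbind, mats), do.call(rbind, rows), threshold)
}

# internal: subset a segment dataset by row index
subset_segments <- function(dataset, idx) {
  segment_dataset(dataset$samples[idx, , drop = FALSE],
                  dataset$info[idx, , drop = FALSE],
                  dataset$threshold_samples)
}
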