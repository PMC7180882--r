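# run an expression with a private, seeded RNG stream, restoring global state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Synthetic dataset configuration
#'
#' Describes a generated cohort that mimics the shape of the Challenge 2017
#' training set: 300 Hz single-lead recordings of 9-61 s with the mode of the
#' duration distribution at 30 s, in four classes. Durations are drawn from a
#' mixture: a point mass at `mode_s` with weight `mode_weight`, otherwise
#' uniform over `duration_range`.
#'
#' @param n_per_class Named integer vector of recording counts for AF,
#'   Normal, Noisy, Other.
#' @param fs Sampling rate in Hz (default 300).
#' @param mode_weight Weight of the point mass at the modal duration
#'   (default 0.7).
#' @param mode_s Modal duration in seconds (default 30).
#' @param duration_range Duration range in seconds (default `c(9, 61)`).
#' @param seed Integer master seed; every recording's stream derives from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_per_class = c(AF = 10L, Normal = 10L,
                                         Noisy = 10L, Other = 10L),
                         fs = 300, mode_weight = 0.7, mode_s = 30,
                         duration_range = c(9, 61), seed = 1L) {
  stopifnot(all(n_per_class >= 0), fs > 0,
            mode_weight >= 0, mode_weight <= 1,
            length(duration_range) == 2,
            duration_range[1] <= duration_range[2])
  if (is.null(names(n_per_class))) names(n_per_class) <- af_classes()
  stopifnot(setequal(names(n_per_class), af_classes()))
  structure(list(n_per_class = n_per_class[af_classes()], fs = fs,
                 mode_weight = mode_weight, mode_s = mode_s,
                 duration_range = duration_range, seed = as.integer(seed)),
            class = "synth_config")
}

# add one Gaussian bump to a signal, only touching a +-4 sigma window
add_bump <- function(x, fs, center_s, amp, sigma_s) {
  if (amp == 0) return(x)
  lo <- max(1L, floor((center_s - 4 * sigma_s) * fs) + 1L)
  hi <- min(length(x), ceiling((center_s + 4 * sigma_s) * fs) + 1L)
  if (lo > hi) return(x)
  t <- (seq(lo, hi) - 1) / fs
  x[lo:hi] <- x[lo:hi] + amp * exp(-(t - center_s)^2 / (2 * sigma_s^2))
  x
}

# draw a beat-onset train for one class; returns R-peak times in seconds.
# AF couples irregularity (gamma RR, CV 1/3) with the rapid ventricular
# response typical of untreated AF (mean RR 0.6 s vs 0.8 s in sinus rhythm).
draw_beat_train <- function(class, duration) {
  n_max <- ceiling(duration / 0.3) + 2L
  rr <- switch(class,
    AF = pmax(0.3, rgamma(n_max, shape = 9, scale = 0.6 / 9)),
    # regular rhythms: small Gaussian jitter around sinus rate
    pmax(0.4, rnorm(n_max, 0.8, 0.015)))
  onsets <- cumsum(c(runif(1, 0.1, 0.5), rr))
  onsets[onsets < duration - 0.3]
}

#' Generate one synthetic ECG recording
#'
#' Beat morphology is a sum of Gaussian bumps (P, Q, R, S, T). Class
#' signatures: Normal has a regular R-R interval (coefficient of variation
#' about 0.02) and a P wave before every QRS; AF has gamma-distributed
#' irregular R-R intervals (CV about 1/3), no P wave, and an additive 4-8 Hz
#' baseline oscillation; Other keeps a regular rhythm but widens the QRS and
#' inverts the T wave; Noisy is a faint beat template buried in white noise
#' and drift at a signal-to-noise ratio well below 0 dB. All classes carry a
#' small measurement noise and a slow respiratory drift. Output is
#' deterministic given the seed.
#'
#' @param class One of [af_classes()].
#' @param duration Duration in seconds, within 9-61.
#' @param fs Sampling rate in Hz (default 300).
#' @param seed Integer seed.
#' @param record_id Identifier for the resulting recording.
#' @return An [ecg_recording()] with amplitudes in millivolts.
#' @export
#' @examples
#' r <- gen_recording("AF", 30, seed = 7)
#' length(r$samples)  # 9000
gen_recording <- function(class, duration, fs = 300, seed = 1L,
                          record_id = sprintf("S%05d", seed %% 100000L)) {
  check_labels(class)
  if (duration < 9 || duration > 61) {
    stop("duration must be within [9, 61] seconds", call. = FALSE)
  }
  n <- round(duration * fs)
  with_local_seed(seed, {
    x <- numeric(n)
    if (class == "Noisy") {
      beats <- draw_beat_train("Normal", duration)
      for (b in beats) {
        x <- add_bump(x, fs, b, 0.2, 0.012)
      }
      t <- (seq_len(n) - 1) / fs
      x <- x + 0.5 * rnorm(n) +
        0.3 * sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi))
    } else {
      beats <- draw_beat_train(class, duration)
      qrs_w <- if (class == "Other") 2.5 else 1
      t_amp <- if (class == "Other") -0.35 else 0.35
      p_amp <- if (class == "AF") 0 else 0.15
      for (b in beats) {
        x <- add_bump(x, fs, b - 0.16, p_amp, 0.025)      # P
        x <- add_bump(x, fs, b - 0.04, -0.10, 0.010 * qrs_w)  # Q
        x <- add_bump(x, fs, b, if (class == "Other") 0.8 else 1.0,
                      0.012 * qrs_w)                       # R
        x <- add_bump(x, fs, b + 0.04, -0.25, 0.012 * qrs_w)  # S
        x <- add_bump(x, fs, b + 0.25, t_amp, 0.06)        # T
      }
      t <- (seq_len(n) - 1) / fs
      if (class == "AF") {
        f_af <- runif(1, 4, 8)
        x <- x + 0.2 * sin(2 * pi * f_af * t + runif(1, 0, 2 * pi))
      }
      x <- x + 0.02 * rnorm(n) +
        0.05 * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi))
    }
    ecg_recording(record_id, x, fs, class)
  })
}

#' Generate a labeled synthetic cohort
#'
#' @param config A [synth_config()].
#' @return List with `recordings` (list of [ecg_recording()]) and `labels`
#'   (a `label_table` mapping record ID to class).
#' @export
#' @examples
#' d <- gen_dataset(synth_config(c(AF = 2, Normal = 2, Noisy = 2, Other = 2)))
#' length(d$recordings)
gen_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  classes <- rep(af_classes(), times = config$n_per_class)
  n <- length(classes)
  durations <- with_local_seed(config$seed, {
    is_mode <- runif(n) < config$mode_weight
    ifelse(is_mode, config$mode_s,
           runif(n, config$duration_range[1], config$duration_range[2]))
  })
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    rec_seed <- (config$seed * 10007L + i * 7919L) %% 2147483647L
    recordings[[i]] <- gen_recording(classes[i], durations[i], config$fs,
                                     seed = rec_seed,
                                     record_id = sprintf("S%05d", i))
  }
  labels <- label_table(vapply(recordings, function(r) r$record_id,
                               character(1)), classes)
  list(recordings = recordings, labels = labels)
}

#' Detect R peaks in a clean synthetic signal
#'
#' Simple amplitude-and-refractory peak picker: local maxima above half the
#' signal maximum, at least `refractory_s` apart. Intended for the synthetic
#' generator's well-separated QRS complexes, not for clinical use.
#'
#' @param samples Numeric amplitude vector.
#' @param fs Sampling rate in Hz.
#' @param refractory_s Minimum peak spacing in seconds (default 0.3).
#' @return Integer vector of peak sample indices (1-based).
#' @export
detect_rpeaks <- function(samples, fs, refractory_s = 0.3) {
  thr <- 0.5 * max(samples)
  is_peak <- c(FALSE, diff(sign(diff(samples))) < 0, FALSE) & samples > thr
  cand <- which(is_peak)
  if (length(cand) == 0) return(integer(0))
  keep <- cand[1]
  gap <- round(refractory_s * fs)
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= gap) {
      keep <- c(keep, i)
    } else if (samples[i] > samples[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  keep
}

#' Hand-crafted rhythm features of a recording
#'
#' Two simple features that linearly separate synthetic AF from Normal:
#' the coefficient of variation of the R-R intervals, and the P-wave energy
#' (mean amplitude over the 0.12-0.20 s windows preceding each detected R
#' peak). The relative 4-8 Hz baseline band power is also returned.
#'
#' @param recording An [ecg_recording()] or numeric sample vector.
#' @param fs Sampling rate (taken from the recording if one is given).
#' @return Named numeric vector: `rr_cv`, `p_wave_energy`, `af_band_power`.
#' @export
ecg_features <- function(recording, fs = 300) {
  x <- if (inherits(recording, "ecg_recording")) recording$samples
       else as.numeric(recording)
  if (inherits(recording, "ecg_recording")) fs <- recording$fs
  peaks <- detect_rpeaks(x, fs)
  rr <- diff(peaks) / fs
  rr_cv <- if (length(rr) >= 2) stats::sd(rr) / mean(rr) else NA_real_
  # P-wave window 0.12-0.20 s before each R peak; cycles shorter than
  # 0.55 s are skipped because the preceding T wave intrudes there
  ok_prev <- c(FALSE, rr >= 0.55)
  p_win <- lapply(peaks[ok_prev], function(p) {
    lo <- p - round(0.20 * fs)
    hi <- p - round(0.12 * fs)
    if (lo < 1) return(NULL)
    x[lo:hi]
  })
  p_win <- unlist(p_win)
  p_energy <- if (length(p_win) > 0) mean(p_win) else NA_real_
  # relative power in the 4-8 Hz band, beats removed crudely by clipping
  xc <- pmin(pmax(x, -0.3), 0.3)
  xc <- xc - mean(xc)
  pw <- Mod(stats::fft(xc))^2
  freqs <- (seq_along(pw) - 1) * fs / length(pw)
  half <- freqs <= fs / 2
  band <- half & freqs >= 4 & freqs <= 8
  c(rr_cv = rr_cv, p_wave_energy = p_energy,
    af_band_power = sum(pw[band]) / sum(pw[half]))
}

#' Write recordings to disk in the Challenge 2017 layout
#'
#' Emits, per recording, a MAT-v5 array file holding the raw integer trace
#' (variable `val`, gain 1000 units/mV) and a WFDB-style `.hea` header, plus
#' a `REFERENCE.csv` label file — the exact layout [read_recording()] and
#' [read_label_table()] consume.
#'
#' @param recordings List of [ecg_recording()] objects.
#' @param dir Output directory (created if missing).
#' @param gain ADC units per millivolt (default 1000).
#' @return Invisibly, the directory path.
#' @export
write_fixture_tree <- function(recordings, dir, gain = 1000) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- character(0)
  labs <- character(0)
  for (r in recordings) {
    raw <- as.integer(pmin(pmax(round(r$samples * gain), -32768), 32767))
    write_mat_val(file.path(dir, paste0(r$record_id, ".mat")), raw)
    hea <- c(sprintf("%s 1 %g %d", r$record_id, r$fs, length(raw)),
             sprintf("%s.mat 16+24 %g/mV 16 0 %d %d 0 ECG", r$record_id,
                     gain, raw[1], as.integer(sum(raw) %% 65536L)))
    writeLines(hea, file.path(dir, paste0(r$record_id, ".hea")))
    ids <- c(ids, r$record_id)
    labs <- c(labs, r$label)
  }
  write_label_table(label_table(ids, labs), file.path(dir, "REFERENCE.csv"))
  invisible(dir)
}
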