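#' Subject profile for the synthetic recording generator
#'
#' Describes one wearer of the instrumented glasses. The pre-loads are the
#' resting compressive forces at the two hinge sensors (they differ with
#' head size and wearing conditions); `gain` is a per-subject overall
#' amplitude multiplier; `chew_freq` is the subject's mastication rate,
#' constrained to the 0.94--2.17 Hz range that covers the 5th--95th
#' percentiles of human chewing; `dominant_side_ratio` (> 1) is how much
#' larger the chewing-side force amplitude is than the contralateral one.
#'
#' @param subject_id character id.
#' @param preload_left,preload_right resting hinge force, newtons.
#' @param gain dimensionless amplitude multiplier (> 0).
#' @param noise_sd measurement noise standard deviation, newtons (>= 0).
#' @param chew_freq chewing frequency in Hz, within [0.94, 2.17].
#' @param dominant_side_ratio ipsilateral/contralateral chewing amplitude
#'   ratio (> 1).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            preload_left = 2, preload_right = 2,
                            gain = 1, noise_sd = 0.02,
                            chew_freq = 1.5, dominant_side_ratio = 3) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            preload_left >= 0, preload_right >= 0, gain > 0,
            noise_sd >= 0, dominant_side_ratio > 1)
  if (chew_freq < 0.94 || chew_freq > 2.17) {
    stop("chew_freq must lie in [0.94, 2.17] Hz")
  }
  structure(list(subject_id = subject_id,
                 preload_left = preload_left,
                 preload_right = preload_right,
                 gain = gain, noise_sd = noise_sd,
                 chew_freq = chew_freq,
                 dominant_side_ratio = dominant_side_ratio),
            class = "subject_profile")
}

# zero-phase low-pass used inside the generator (not the analysis filter)
gen_lowpass <- function(x, fs, cutoff, order = 2) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Per-class segment synthesizers: each returns list(left, right) of
# zero-baseline force structure (pre-load and sensor noise added later).
gen_nhm <- function(n, fs, gain, drift_sd) {
  mk <- function() {
    if (drift_sd <= 0) return(numeric(n))
    walk <- cumsum(stats::rnorm(n, 0, drift_sd / sqrt(fs)))
    if (n > 24) gen_lowpass(walk, fs, 0.5) else walk
  }
  list(left = gain * mk(), right = gain * mk())
}

gen_chew <- function(n, fs, side, freq, gain, ratio, texture, confusability) {
  tt <- seq_len(n) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  phase2 <- stats::runif(1, 0, 2 * pi)
  base <- sin(2 * pi * freq * tt + phase) +
    0.3 * sin(2 * pi * 2 * freq * tt + phase2)
  # per-cycle amplitude jitter
  cycle <- pmin(floor(tt * freq) + 1L, max(1L, ceiling(n / fs * freq)))
  ncyc <- max(cycle)
  jit <- pmax(0.2, 1 + texture$burst_irregularity * stats::rnorm(ncyc))
  amp_dom <- gain * texture$amplitude_scale * jit[cycle]
  ratio_eff <- 1 + (ratio - 1) * (1 - confusability)
  dom <- amp_dom * base
  oth <- dom / ratio_eff
  if (side == "L") list(left = dom, right = oth) else list(left = oth, right = dom)
}

gen_wink <- function(n, fs, side, gain) {
  x <- numeric(n)
  tt <- seq_len(n) / fs
  block_s <- 3
  n_blocks <- max(1L, floor(n / fs / block_s))
  for (b in seq_len(n_blocks)) {
    k <- sample(1:3, 1)
    for (j in seq_len(k)) {
      width <- stats::runif(1, 0.1, 0.3)            # pulse duration, s
      centre <- (b - 1) * block_s + stats::runif(1, width, block_s - width)
      height <- gain * 0.8 * (1 + 0.2 * stats::rnorm(1))
      x <- x + height * exp(-(tt - centre)^2 / (2 * (width / 4)^2))
    }
  }
  if (side == "L") list(left = x, right = numeric(n)) else list(left = numeric(n), right = x)
}

gen_talk <- function(n, fs, gain, confusability) {
  amp <- 0.15 * gain * (1 - 0.7 * confusability)
  env <- pmax(0, gen_lowpass(stats::rnorm(n), fs, 1.5))
  env <- env / max(stats::sd(env), 1e-12)
  shared <- gen_lowpass(stats::rnorm(n), fs, 8)
  mk <- function() {
    own <- gen_lowpass(stats::rnorm(n), fs, 8)
    amp * env * (0.9 * own + 0.3 * shared)
  }
  list(left = mk(), right = mk())
}

#' Generate a bilateral hinge-force recording
#'
#' Synthesizes a continuous two-channel (left/right hinge) force trace with
#' per-sample behavior labels, emulating the signal morphology observed at
#' the glasses hinges for six behaviors:
#' \describe{
#'   \item{NHM}{pre-load plus slow (<= 0.5 Hz) random-walk drift and
#'     Gaussian sensor noise on both channels.}
#'   \item{LC / RC}{a sinusoid-plus-harmonic chewing oscillation at the
#'     subject's chewing frequency, amplitude jittered per mastication
#'     cycle and scaled by food texture; the named side carries
#'     `dominant_side_ratio` times the contralateral amplitude.}
#'   \item{LW / RW}{1--3 smooth 100--300 ms transient pulses per 3 s on the
#'     named side only.}
#'   \item{TK}{irregular low-amplitude broadband bursts on both channels
#'     with weak inter-channel correlation.}
#' }
#'
#' @param profile a [subject_profile()].
#' @param schedule data frame with columns `behavior` (class codes) and
#'   `duration_s` (positive durations in seconds).
#' @param sample_rate sampling rate in Hz (>= 50).
#' @param texture a [texture_class()] controlling chewing amplitude.
#' @param seed integer seed; the output is deterministic given all
#'   arguments and the seed.
#' @param confusability in [0, 1]; 0 gives the default well-separated
#'   classes, larger values shrink the left/right chewing asymmetry and the
#'   talking-vs-head-movement amplitude gap to mimic harder, more
#'   confusable data.
#' @param drift_sd head-movement drift scale for NHM, N per sqrt(second).
#' @return An object of class `subject_recording` with elements `subject`,
#'   `sample_rate`, `left`, `right`, `labels`.
#' @export
generate_recording <- function(profile, schedule, sample_rate = 100,
                               texture = texture_class("bread"),
                               seed = 1, confusability = 0,
                               drift_sd = 0.05) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(texture, "texture_class"),
            sample_rate >= 50,
            confusability >= 0, confusability <= 1)
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("behavior", "duration_s") %in% names(schedule)))
  if (any(schedule$duration_s <= 0)) stop("segment durations must be positive")
  behavior_label(as.character(schedule$behavior)) # validates codes

  with_seed(seed, {
    left <- right <- numeric(0)
    labels <- character(0)
    for (i in seq_len(nrow(schedule))) {
      code <- as.character(schedule$behavior[i])
      n <- round(schedule$duration_s[i] * sample_rate)
      seg <- switch(code,
        NHM = gen_nhm(n, sample_rate, profile$gain, drift_sd),
        LC  = gen_chew(n, sample_rate, "L", profile$chew_freq, profile$gain,
                       profile$dominant_side_ratio, texture, confusability),
        RC  = gen_chew(n, sample_rate, "R", profile$chew_freq, profile$gain,
                       profile$dominant_side_ratio, texture, confusability),
        LW  = gen_wink(n, sample_rate, "L", profile$gain),
        RW  = gen_wink(n, sample_rate, "R", profile$gain),
        TK  = gen_talk(n, sample_rate, profile$gain, confusability))
      noise <- function() if (profile$noise_sd > 0) {
        stats::rnorm(n, 0, profile$noise_sd)
      } else numeric(n)
      left <- c(left, profile$preload_left + seg$left + noise())
      right <- c(right, profile$preload_right + seg$right + noise())
      labels <- c(labels, rep(code, n))
    }
    structure(list(subject = profile, sample_rate = sample_rate,
                   left = left, right = right, labels = labels),
              class = "subject_recording")
  })
}

#' Generate a cohort of subjects
#'
#' Draws per-subject profiles from documented distributions (pre-loads
#' uniform on 1--3 N per side, gain on 0.8--1.25, chewing frequency on
#' 1.0--2.0 Hz, dominant-side ratio on 2.5--4) and generates one recording
#' per subject containing all six behavior classes back to back, each
#' class lasting `per_class_windows` windows of `window_s` seconds, so the
#' recording segments into exactly
#' `n_subjects * 6 * per_class_windows` single-label windows.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param per_class_windows windows per class per subject (>= 1).
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @param window_s window length, seconds.
#' @param texture a [texture_class()].
#' @param confusability see [generate_recording()].
#' @return List of `subject_recording` objects.
#' @export
generate_cohort <- function(n_subjects, per_class_windows,
                            sample_rate = 100, seed = 1, window_s = 3,
                            texture = texture_class("bread"),
                            confusability = 0) {
  stopifnot(n_subjects >= 2)
  if (per_class_windows < 1) stop("per_class_windows must be >= 1")
  profiles <- with_seed(seed, lapply(seq_len(n_subjects), function(i) {
    subject_profile(
      subject_id = sprintf("S%02d", i),
      preload_left = stats::runif(1, 1, 3),
      preload_right = stats::runif(1, 1, 3),
      gain = stats::runif(1, 0.8, 1.25),
      noise_sd = 0.02,
      chew_freq = stats::runif(1, 1.0, 2.0),
      dominant_side_ratio = stats::runif(1, 2.5, 4)
    )
  }))
  schedule <- data.frame(behavior = behavior_codes(),
                         duration_s = per_class_windows * window_s)
  lapply(seq_len(n_subjects), function(i) {
    generate_recording(profiles[[i]], schedule, sample_rate = sample_rate,
                       texture = texture, seed = derive_seed(seed, i),
                       confusability = confusability)
  })
}

#' Write a recording as CSV
#'
#' Columns `time_s,left,right,label`, one row per sample.
#'
#' @param rec a `subject_recording`.
#' @param path output file.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "subject_recording"))
  df <- data.frame(
    time_s = (seq_along(rec$left) - 1) / rec$sample_rate,
    left = rec$left, right = rec$right, label = rec$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' @param path CSV written by [write_recording_csv()].
#' @param subject_id id to attach (defaults to file name).
#' @return A `subject_recording` (profile holds only the id).
#' @export
read_recording_csv <- function(path, subject_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "left", "right", "label") %in% names(df)))
  fs <- round(1 / stats::median(diff(df$time_s)))
  if (is.null(subject_id)) subject_id <- sub("\\.csv$", "", basename(path))
  prof <- subject_profile(subject_id)
  structure(list(subject = prof, sample_rate = fs,
                 left = df$left, right = df$right, labels = df$label),
            class = "subject_recording")
}

#' Write a cohort to a directory
#'
#' One CSV per subject plus a `manifest.csv` recording subject id, file
#' name, sample rate and profile parameters.
#'
#' @param cohort list of `subject_recording`.
#' @param dir output directory (created if missing).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    p <- rec$subject
    file <- paste0(p$subject_id, ".csv")
    write_recording_csv(rec, file.path(dir, file))
    data.frame(subject_id = p$subject_id, file = file,
               sample_rate = rec$sample_rate,
               preload_left = p$preload_left, preload_right = p$preload_right,
               gain = p$gain, noise_sd = p$noise_sd, chew_freq = p$chew_freq,
               dominant_side_ratio = p$dominant_side_ratio)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
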