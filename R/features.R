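# ---- small statistical helpers (safe on degenerate input) ----

safe_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

safe_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Find local maxima with a prominence threshold
#'
#' A sample is a peak if it exceeds its left neighbour and is at least its
#' right neighbour; its prominence is its height above the higher of the
#' two minima separating it from higher terrain (or from the signal edge).
#'
#' @param x numeric vector.
#' @param min_prominence minimum prominence for a peak to be kept.
#' @return Integer indices of the retained peaks.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  cand[prom >= min_prominence]
}

# ---- feature registry ----

temporal_feature_names <- c(
  "mean", "median", "sd", "var", "rms", "mad", "iqr", "skewness",
  "kurtosis", "min", "max", "p2p", "zero_cross", "n_peaks",
  "mean_peak_height", "mean_ipi", "mean_abs_d1", "mean_abs_d2",
  "waveform_length", "energy")

spectral_feature_names <- c(
  "total_power", "peak_freq", "peak_power", "centroid", "spread",
  "skewness", "kurtosis", "entropy", "median_freq", "sef95",
  "bp_0_0.5", "bp_0.5_1", "bp_1_1.5", "bp_1.5_2", "bp_2_3", "bp_3_5",
  "bp_5_10", "chew_band_frac", "peak_ratio", "n_peaks")

cross_feature_names <- c("corr", "sma", "log_rms_ratio", "xcorr_lag_s")

#' Names of the 84 features
#'
#' 20 temporal features per side, 20 spectral features per side, and 4
#' cross-channel features, in a fixed, documented order:
#' `t_<name>_left`, `t_<name>_right`, `s_<name>_left`, `s_<name>_right`,
#' then `x_corr`, `x_sma`, `x_log_rms_ratio`, `x_xcorr_lag_s`.
#'
#' @return Character vector of length 84.
#' @export
feature_names <- function() {
  c(paste0("t_", temporal_feature_names, "_left"),
    paste0("t_", temporal_feature_names, "_right"),
    paste0("s_", spectral_feature_names, "_left"),
    paste0("s_", spectral_feature_names, "_right"),
    paste0("x_", cross_feature_names))
}

temporal_features <- function(x, fs, peak_prominence_frac = 0.1) {
  pk <- find_peaks(x, min_prominence = peak_prominence_frac * stats::sd(x))
  d1 <- diff(x)
  d2 <- diff(x, differences = 2)
  c(mean = mean(x),
    median = stats::median(x),
    sd = stats::sd(x),
    var = stats::var(x),
    rms = sqrt(mean(x^2)),
    mad = mean(abs(x - mean(x))),
    iqr = stats::IQR(x),
    skewness = safe_skewness(x),
    kurtosis = safe_kurtosis(x),
    min = min(x),
    max = max(x),
    p2p = max(x) - min(x),
    zero_cross = as.numeric(zero_crossings(x)),
    n_peaks = as.numeric(length(pk)),
    mean_peak_height = if (length(pk)) mean(x[pk]) else 0,
    mean_ipi = if (length(pk) >= 2) mean(diff(pk)) / fs else 0,
    mean_abs_d1 = mean(abs(d1)),
    mean_abs_d2 = mean(abs(d2)),
    waveform_length = sum(abs(d1)),
    energy = sum(x^2))
}

spectral_features <- function(freqs, psd, band_max = 10,
                              chew_band = c(0.94, 2.17)) {
  sel <- freqs <= band_max
  f <- freqs[sel]
  p <- psd[sel]
  df <- if (length(freqs) > 1) freqs[2] - freqs[1] else 1
  tot <- sum(p) * df
  if (tot <= 0) {
    out <- numeric(length(spectral_feature_names))
    names(out) <- spectral_feature_names
    return(out)
  }
  w <- p / sum(p)
  cen <- sum(f * w)
  spr <- sqrt(sum((f - cen)^2 * w))
  csum <- cumsum(p) / sum(p)
  bandpow <- function(lo, hi) sum(p[f >= lo & f < hi]) * df
  # local maxima of the in-band PSD above 10% of the maximum
  npk_big <- sum(p[find_peaks(p, min_prominence = 0)] > 0.1 * max(p))
  ent <- -sum(w[w > 0] * log(w[w > 0])) / log(length(w))
  c(total_power = tot,
    peak_freq = f[which.max(p)],
    peak_power = max(p),
    centroid = cen,
    spread = spr,
    skewness = if (spr > 0) sum(((f - cen) / spr)^3 * w) else 0,
    kurtosis = if (spr > 0) sum(((f - cen) / spr)^4 * w) else 0,
    entropy = ent,
    median_freq = f[which(csum >= 0.5)[1]],
    sef95 = f[which(csum >= 0.95)[1]],
    bp_0_0.5 = bandpow(0, 0.5),
    `bp_0.5_1` = bandpow(0.5, 1),
    bp_1_1.5 = bandpow(1, 1.5),
    `bp_1.5_2` = bandpow(1.5, 2),
    bp_2_3 = bandpow(2, 3),
    bp_3_5 = bandpow(3, 5),
    bp_5_10 = sum(p[f >= 5 & f <= 10]) * df,
    chew_band_frac = sum(p[f >= chew_band[1] & f <= chew_band[2]]) / sum(p),
    peak_ratio = max(p) / sum(p),
    n_peaks = as.numeric(npk_big))
}

cross_features <- function(left, right, fs, max_lag_s = 0.5) {
  eps <- 1e-12
  rms_l <- sqrt(mean(left^2))
  rms_r <- sqrt(mean(right^2))
  corr <- if (stats::sd(left) > 0 && stats::sd(right) > 0) {
    stats::cor(left, right)
  } else 0
  lag_s <- 0
  if (stats::sd(left) > 0 && stats::sd(right) > 0) {
    lmax <- min(round(max_lag_s * fs), length(left) - 1L)
    cc <- stats::ccf(left, right, lag.max = lmax, plot = FALSE)
    lag_s <- cc$lag[which.max(cc$acf)] / fs # ccf lags are in samples here
  }
  c(corr = corr,
    sma = mean(abs(left) + abs(right)),
    log_rms_ratio = log((rms_l + eps) / (rms_r + eps)),
    xcorr_lag_s = lag_s)
}

#' Extract the 84-dimensional feature vector of a window
#'
#' Computes, for each side separately, 20 temporal statistics of the
#' filtered, median-centered signal and 20 spectral statistics of its
#' 0--10 Hz power spectral density, plus 4 cross-channel features (Pearson
#' correlation, signal magnitude area, log left/right RMS ratio, and the
#' lag of the maximum normalized cross-correlation within +/- 0.5 s). The
#' left/right chewing classes are separated mainly by the cross-channel
#' and per-side amplitude features; chewing versus other behavior mainly
#' by the 0.94--2.17 Hz chewing-band features.
#'
#' @param w a preprocessed (median-centered, low-pass filtered)
#'   `labeled_window`.
#' @param s the `spectrum_pair` of the same window.
#' @param peak_prominence_frac temporal peak-detection prominence as a
#'   fraction of the channel standard deviation.
#' @return Named numeric vector of length 84 with attributes `label` and
#'   `subject_id`.
#' @export
extract_features <- function(w, s, peak_prominence_frac = 0.1) {
  stopifnot(inherits(w, "labeled_window"), inherits(s, "spectrum_pair"))
  if (anyNA(w$left) || anyNA(w$right)) stop("NaN/NA in window channels")
  v <- c(temporal_features(w$left, w$sample_rate, peak_prominence_frac),
         temporal_features(w$right, w$sample_rate, peak_prominence_frac),
         spectral_features(s$freqs, s$psd_left),
         spectral_features(s$freqs, s$psd_right),
         cross_features(w$left, w$right, w$sample_rate))
  names(v) <- feature_names()
  if (any(!is.finite(v))) stop("non-finite feature value")
  attr(v, "label") <- w$label
  attr(v, "subject_id") <- w$subject_id
  v
}

#' Build the feature table of a window set
#'
#' Runs the preprocessing chain ([median_center()], [lowpass()],
#' [window_spectrum()]) and [extract_features()] on every window and
#' returns one data frame row per window: the 84 features followed by
#' `label` and `subject_id` columns.
#'
#' @param windows list of `labeled_window` objects.
#' @param cutoff,order low-pass filter parameters.
#' @return Data frame with 86 columns.
#' @export
features_table <- function(windows, cutoff = 10, order = 5) {
  stopifnot(length(windows) >= 1)
  rows <- lapply(windows, function(w) {
    pw <- preprocess_window(w, cutoff = cutoff, order = order)
    extract_features(pw$window, pw$spectrum)
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- vapply(windows, function(w) w$label, character(1))
  df$subject_id <- vapply(windows, function(w) w$subject_id, character(1))
  df
}

#' Fit a z-score scaler on a feature table
#'
#' Per-feature location (mean) and scale (standard deviation). Features
#' with zero variance get scale 1 (with a warning) so they map to zero
#' rather than NaN. Scalers are fitted on training folds only and applied
#' unchanged to held-out folds, so no information leaks from test
#' subjects.
#'
#' @param features data frame from [features_table()] (or a matrix of the
#'   84 feature columns).
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(features) {
  X <- as.matrix(features[, feature_names(), drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 feature vectors to fit a scaler")
  centre <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    warning("zero-variance features scaled by 1: ",
            paste(colnames(X)[scl == 0], collapse = ", "))
    scl[scl == 0] <- 1
  }
  structure(list(center = centre, scale = scl), class = "feature_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler a [fit_scaler()] result.
#' @param features feature table.
#' @return The table with the 84 feature columns standardized; `label` and
#'   `subject_id` untouched.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "feature_scaler"))
  nm <- feature_names()
  X <- as.matrix(features[, nm, drop = FALSE])
  X <- sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
  features[, nm] <- X
  features
}

#' Write a feature table as CSV
#'
#' @param features data frame from [features_table()].
#' @param path output file.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
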