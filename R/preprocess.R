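#' Labeled 3-second window
#'
#' @param subject_id character id.
#' @param label one behavior code.
#' @param sample_rate Hz.
#' @param left,right channel samples, length `round(window_s * sample_rate)`.
#' @param window_s window duration, seconds.
#' @return An object of class `labeled_window`.
#' @export
labeled_window <- function(subject_id, label, sample_rate, left, right,
                           window_s = 3) {
  n <- round(window_s * sample_rate)
  stopifnot(length(left) == n, length(right) == n)
  behavior_label(label)
  structure(list(subject_id = subject_id, label = label,
                 sample_rate = sample_rate, left = left, right = right),
            class = "labeled_window")
}

#' Segment a recording into consecutive single-label windows
#'
#' Cuts the trace into consecutive, non-overlapping windows of `window_s`
#' seconds. A window is emitted only if every sample in it carries the same
#' behavior label (mixed-label windows at behavior transitions are
#' dropped, keeping training labels pure); a trailing partial window is
#' dropped.
#'
#' @param rec a `subject_recording`.
#' @param window_s window length, seconds (default 3: long enough to
#'   contain several mastication cycles at 0.94--2.17 Hz).
#' @return List of `labeled_window` objects.
#' @export
segment <- function(rec, window_s = 3) {
  stopifnot(inherits(rec, "subject_recording"))
  n <- length(rec$left)
  wlen <- round(window_s * rec$sample_rate)
  if (n < wlen) stop("recording shorter than one window")
  n_win <- n %/% wlen
  out <- vector("list", n_win)
  keep <- logical(n_win)
  for (i in seq_len(n_win)) {
    idx <- ((i - 1) * wlen + 1):(i * wlen)
    labs <- unique(rec$labels[idx])
    if (length(labs) == 1L) {
      keep[i] <- TRUE
      out[[i]] <- labeled_window(rec$subject$subject_id, labs,
                                 rec$sample_rate, rec$left[idx],
                                 rec$right[idx], window_s = window_s)
    }
  }
  out[keep]
}

#' Remove the per-window pre-load by median subtraction
#'
#' Each subject's resting pre-load (head size, wearing conditions) shifts
#' both channels by an arbitrary offset, so every window is centered by
#' subtracting each channel's own median. This makes the downstream
#' pipeline offset-invariant.
#'
#' @param w a `labeled_window`.
#' @return The window with both channels median-centered.
#' @export
median_center <- function(w) {
  stopifnot(inherits(w, "labeled_window"))
  w$left <- w$left - stats::median(w$left)
  w$right <- w$right - stats::median(w$right)
  w
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth low-pass filter to
#' both channels. Chewing does not exceed about 3 Hz and frequencies above
#' 10 Hz carry little between-class variation, so the default is a
#' 5th-order filter with 10 Hz cutoff. Forward-backward filtering squares
#' the magnitude response; for the bilinear-transform digital design the
#' squared response is
#' `1 / (1 + (tan(pi f/fs) / tan(pi fc/fs))^(2 * order))`.
#'
#' @param w a `labeled_window`.
#' @param cutoff cutoff frequency, Hz (must be below Nyquist).
#' @param order filter order.
#' @return The filtered window.
#' @export
lowpass <- function(w, cutoff = 10, order = 5) {
  stopifnot(inherits(w, "labeled_window"))
  if (cutoff >= w$sample_rate / 2) stop("cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff / (w$sample_rate / 2), type = "low")
  w$left <- filtfilt_padded(bf, w$left, order)
  w$right <- filtfilt_padded(bf, w$right, order)
  w
}

# forward-backward filtering with odd-reflection end padding, so edge
# transients decay inside the pad and DC passes unchanged
filtfilt_padded <- function(bf, x, order) {
  n <- length(x)
  pad <- min(n - 1L, 30L * order)
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xe))
  y[(pad + 1):(pad + n)]
}

#' Hann taper
#'
#' `h[n] = 0.5 * (1 - cos(2 pi n / (N - 1)))`, n = 0..N-1: zero at both
#' endpoints, one at the midpoint (odd N).
#'
#' @param n taper length.
#' @return Numeric vector of length `n`.
#' @export
hann_taper <- function(n) {
  stopifnot(n >= 2)
  k <- seq_len(n) - 1
  0.5 * (1 - cos(2 * pi * k / (n - 1)))
}

# single-channel single-sided amplitude spectrum and periodogram PSD
single_sided <- function(x, fs, taper) {
  n <- length(x)
  if (taper) x <- x * hann_taper(n)
  X <- stats::fft(x)
  n_half <- n %/% 2 + 1L
  amp <- Mod(X[seq_len(n_half)]) / n
  psd <- Mod(X[seq_len(n_half)])^2 / (fs * n)
  # double interior bins (not DC; not Nyquist when n is even)
  interior <- seq_len(n_half) > 1 & !(n %% 2 == 0 & seq_len(n_half) == n_half)
  amp[interior] <- 2 * amp[interior]
  psd[interior] <- 2 * psd[interior]
  list(amp = amp, psd = psd)
}

#' Single-sided amplitude spectrum and periodogram PSD of a window
#'
#' Applies a Hann taper to each channel (reducing spectral leakage), takes
#' the FFT and returns the single-sided amplitude spectrum and periodogram
#' power spectral density for both channels. For a 3-s window the frequency
#' resolution is 1/3 Hz. With `taper = "none"` the raw periodogram
#' satisfies Parseval's identity:
#' `mean(x^2) == sum(psd) * df` (single-sided, with the interior-bin
#' doubling accounting for negative frequencies).
#'
#' @param w a median-centered `labeled_window`.
#' @param taper `"hann"` (default) or `"none"`.
#' @return An object of class `spectrum_pair` with fields `freqs`,
#'   `amp_left`, `amp_right`, `psd_left`, `psd_right`.
#' @export
window_spectrum <- function(w, taper = c("hann", "none")) {
  stopifnot(inherits(w, "labeled_window"))
  taper <- match.arg(taper)
  n <- length(w$left)
  if (n < 8) stop("window too short for spectral analysis")
  fs <- w$sample_rate
  freqs <- (seq_len(n %/% 2 + 1L) - 1) * fs / n
  l <- single_sided(w$left, fs, taper == "hann")
  r <- single_sided(w$right, fs, taper == "hann")
  structure(list(freqs = freqs,
                 amp_left = l$amp, amp_right = r$amp,
                 psd_left = l$psd, psd_right = r$psd),
            class = "spectrum_pair")
}

#' Standard per-window preprocessing chain
#'
#' Median-center, zero-phase low-pass filter, and compute the spectrum.
#'
#' @param w a `labeled_window`.
#' @param cutoff,order low-pass parameters, see [lowpass()].
#' @return List with the processed `window` and its `spectrum`.
#' @export
preprocess_window <- function(w, cutoff = 10, order = 5) {
  w <- median_center(w)
  w <- lowpass(w, cutoff = cutoff, order = order)
  list(window = w, spectrum = window_spectrum(w))
}
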