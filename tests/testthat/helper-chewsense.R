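# Construct a recording directly from raw channels (bypasses the generator)
make_recording <- function(left, right, labels, fs = 100, id = "S1") {
  structure(list(subject = subject_profile(id), sample_rate = fs,
                 left = left, right = right, labels = labels),
            class = "subject_recording")
}

# One 3-s window from raw channels
make_window <- function(left, right, fs = 100, label = "NHM", id = "S1") {
  labeled_window(id, label, fs, left, right)
}

# Bin-aligned sinusoid window: freq must be a multiple of 1/3 Hz for a 3-s
# window so its energy sits on one FFT bin
sine_window <- function(freq, fs = 100, amp = 1, label = "LC", id = "S1") {
  tt <- seq_len(3 * fs) / fs
  make_window(amp * sin(2 * pi * freq * tt),
              amp * sin(2 * pi * freq * tt), fs, label, id)
}

# Feature table of two well-separated synthetic Gaussian classes, built
# directly in feature space (no signal generation)
gaussian_feature_table <- function(n_per_class = 20, classes = c("LC", "RC"),
                                   sep = 6, n_subjects = 2, seed = 1) {
  set.seed(seed)
  p <- length(feature_names())
  rows <- lapply(seq_along(classes), function(k) {
    mu <- numeric(p)
    mu[seq_len(10)] <- sep * (k - 1)
    m <- matrix(rnorm(n_per_class * p), n_per_class, p) +
      matrix(mu, n_per_class, p, byrow = TRUE)
    df <- as.data.frame(m)
    names(df) <- feature_names()
    df$label <- classes[k]
    df$subject_id <- rep_len(sprintf("S%02d", seq_len(n_subjects)), n_per_class)
    df
  })
  do.call(rbind, rows)
}
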