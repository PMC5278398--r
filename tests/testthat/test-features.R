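extract_from <- function(w) {
  pw <- preprocess_window(w)
  extract_features(pw$window, pw$spectrum)
}

test_that("feature vectors have 84 uniquely named finite values", {
  expect_length(feature_names(), 84)
  expect_false(anyDuplicated(feature_names()) > 0)
  set.seed(4)
  w <- make_window(rnorm(300), rnorm(300), label = "TK", id = "S7")
  v <- extract_from(w)
  expect_length(v, 84)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), feature_names())
  expect_identical(attr(v, "label"), "TK")
  expect_identical(attr(v, "subject_id"), "S7")
  expect_identical(v, extract_from(w)) # deterministic
})

test_that("cross-channel features behave on identical and inverted channels", {
  set.seed(5)
  x <- rnorm(300)
  v <- extract_from(make_window(x, x))
  expect_equal(unname(v["x_corr"]), 1.0)
  expect_equal(unname(v["x_log_rms_ratio"]), 0)
  expect_equal(unname(v["x_xcorr_lag_s"]), 0)
  v2 <- extract_from(make_window(x, -x))
  expect_equal(unname(v2["x_corr"]), -1.0)
})

test_that("a one-sided chewing-band sinusoid drives the expected features", {
  fs <- 100
  tt <- seq_len(3 * fs) / fs
  set.seed(6)
  w <- make_window(sin(2 * pi * (5 / 3) * tt), 0.01 * rnorm(300), fs)
  v <- extract_from(w)
  expect_equal(unname(v["s_peak_freq_left"]), 5 / 3)
  expect_gt(unname(v["s_chew_band_frac_left"]), 0.9)
  expect_gt(unname(v["x_log_rms_ratio"]), 1) # left side much louder
})

test_that("swapping channels mirrors the per-side blocks", {
  p <- subject_profile("S1", noise_sd = 0.02)
  rec <- generate_recording(p, data.frame(behavior = "LC", duration_s = 3),
                            seed = 20)
  w <- segment(rec)[[1]]
  ws <- w
  ws$left <- w$right
  ws$right <- w$left
  v <- extract_from(w)
  vs <- extract_from(ws)
  tl <- grep("^t_.*_left$", feature_names())
  tr <- grep("^t_.*_right$", feature_names())
  sl <- grep("^s_.*_left$", feature_names())
  sr <- grep("^s_.*_right$", feature_names())
  expect_equal(unname(vs[tl]), unname(v[tr]))
  expect_equal(unname(vs[tr]), unname(v[tl]))
  expect_equal(unname(vs[sl]), unname(v[sr]))
  expect_equal(unname(vs[sr]), unname(v[sl]))
  expect_equal(vs["x_corr"], v["x_corr"])
  expect_equal(vs["x_sma"], v["x_sma"])
  expect_equal(unname(vs["x_log_rms_ratio"]), -unname(v["x_log_rms_ratio"]))
  expect_equal(unname(vs["x_xcorr_lag_s"]), -unname(v["x_xcorr_lag_s"]))
})

test_that("the correlation feature is invariant to positive rescaling", {
  set.seed(7)
  w <- make_window(rnorm(300), rnorm(300))
  w2 <- w
  w2$left <- 5 * w$left
  w2$right <- 0.2 * w$right
  # correlation is computed on the filtered signals; rescale after filtering
  pw <- preprocess_window(w)
  pw2 <- pw
  pw2$window$left <- 5 * pw$window$left
  pw2$window$right <- 0.2 * pw$window$right
  v <- extract_features(pw$window, pw$spectrum)
  v2 <- extract_features(pw2$window, pw2$spectrum)
  expect_equal(v2["x_corr"], v["x_corr"])
})

test_that("temporal peak features count sinusoid cycles", {
  v <- extract_from(sine_window(2)) # 2 Hz for 3 s: 6 maxima
  expect_equal(unname(v["t_n_peaks_left"]), 6)
  expect_equal(unname(v["t_mean_ipi_left"]), 0.5, tolerance = 0.02)
  flatv <- extract_from(make_window(rep(0, 300), rep(0, 300)))
  expect_equal(unname(flatv["t_n_peaks_left"]), 0)
  expect_equal(unname(flatv["t_mean_ipi_left"]), 0)
})

test_that("the scaler standardizes the fitting set without leaking", {
  cohort <- generate_cohort(3, 4, seed = 30)
  windows <- unlist(lapply(cohort, segment), recursive = FALSE)
  feats <- features_table(windows)
  expect_equal(ncol(feats), 86)
  expect_equal(nrow(feats), 3 * 6 * 4)

  train <- feats[feats$subject_id != "S03", ]
  test <- feats[feats$subject_id == "S03", ]
  sc <- fit_scaler(train)
  scaled <- apply_scaler(sc, train)
  X <- as.matrix(scaled[, feature_names()])
  expect_equal(max(abs(colMeans(X))), 0, tolerance = 1e-9)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 84), tolerance = 1e-9)
  expect_identical(scaled$label, train$label)

  held <- as.matrix(apply_scaler(sc, test)[, feature_names()])
  expect_gt(max(abs(colMeans(held))), 0.01) # held-out fold is not re-centered
})

test_that("degenerate scaler input falls back to unit scale", {
  one <- gaussian_feature_table(1, classes = "LC", seed = 8)
  two <- rbind(one, one)
  expect_warning(sc <- fit_scaler(two), "zero-variance")
  out <- apply_scaler(sc, two)
  expect_true(all(as.matrix(out[, feature_names()]) == 0))
  expect_error(fit_scaler(one), "at least 2")
})
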