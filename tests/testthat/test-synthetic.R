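test_that("behavior codes map to fixed labels 1..6", {
  expect_identical(behavior_codes(), c("NHM", "LC", "RC", "LW", "RW", "TK"))
  expect_identical(behavior_label(behavior_codes()), 1:6)
  expect_error(behavior_label("EAT"), "unknown")
})

test_that("recordings are deterministic given the seed", {
  p <- subject_profile("S1")
  sched <- data.frame(behavior = c("NHM", "LC", "TK"), duration_s = 6)
  r1 <- generate_recording(p, sched, seed = 5)
  r2 <- generate_recording(p, sched, seed = 5)
  expect_identical(r1, r2)
  r3 <- generate_recording(p, sched, seed = 6)
  expect_false(identical(r1$left, r3$left))
})

test_that("chewing is louder on the named side by the dominance ratio", {
  p <- subject_profile("S1", dominant_side_ratio = 3, noise_sd = 0.01)
  rms0 <- function(x) sqrt(mean((x - median(x))^2))
  lc <- generate_recording(p, data.frame(behavior = "LC", duration_s = 30),
                           seed = 2)
  expect_gte(rms0(lc$left), 2 * rms0(lc$right))
  rc <- generate_recording(p, data.frame(behavior = "RC", duration_s = 30),
                           seed = 2)
  expect_gte(rms0(rc$right), 2 * rms0(rc$left))
})

test_that("noise-free drift-free head movement is constant at the pre-loads", {
  p <- subject_profile("S1", preload_left = 1.5, preload_right = 2.5,
                       noise_sd = 0)
  rec <- generate_recording(p, data.frame(behavior = "NHM", duration_s = 6),
                            seed = 1, drift_sd = 0)
  expect_equal(rec$left, rep(1.5, 600))
  expect_equal(rec$right, rep(2.5, 600))
})

test_that("chewing PSD peaks at the chewing frequency", {
  p <- subject_profile("S1", chew_freq = 1.5, noise_sd = 0.01)
  rec <- generate_recording(p, data.frame(behavior = "LC", duration_s = 30),
                            seed = 8)
  w <- segment(rec)
  peaks <- vapply(w, function(wi) {
    s <- window_spectrum(median_center(wi))
    s$freqs[which.max(s$psd_left)]
  }, numeric(1))
  expect_true(all(abs(peaks - 1.5) <= 0.34))
})

test_that("winks pulse only on the named side", {
  p <- subject_profile("S1", noise_sd = 0.005)
  rw <- generate_recording(p, data.frame(behavior = "RW", duration_s = 30),
                           seed = 3, drift_sd = 0)
  p2p <- function(x) diff(range(x - median(x)))
  expect_gt(p2p(rw$right), 10 * p2p(rw$left))
  lw <- generate_recording(p, data.frame(behavior = "LW", duration_s = 30),
                           seed = 3, drift_sd = 0)
  expect_gt(p2p(lw$left), 10 * p2p(lw$right))
})

test_that("generator rejects bad schedules", {
  p <- subject_profile("S1")
  expect_error(generate_recording(
    p, data.frame(behavior = "XX", duration_s = 3)), "unknown")
  expect_error(generate_recording(
    p, data.frame(behavior = "LC", duration_s = -1)), "positive")
  expect_error(subject_profile("S1", chew_freq = 0.5), "0.94")
  expect_error(subject_profile("S1", dominant_side_ratio = 0.9))
})

test_that("cohorts have the expected window count and composition", {
  cohort <- generate_cohort(2, 2, seed = 4)
  expect_length(cohort, 2)
  windows <- unlist(lapply(cohort, segment), recursive = FALSE)
  expect_length(windows, 2 * 6 * 2)
  labs <- vapply(windows, `[[`, character(1), "label")
  ids <- vapply(windows, `[[`, character(1), "subject_id")
  expect_equal(sort(unique(labs)), sort(behavior_codes()))
  for (id in unique(ids)) {
    expect_setequal(unique(labs[ids == id]), behavior_codes())
  }
  expect_identical(cohort, generate_cohort(2, 2, seed = 4))
  expect_error(generate_cohort(1, 2), "n_subjects")
  expect_error(generate_cohort(2, 0), "per_class_windows")
})

test_that("chewing-band power separates chewing from head movement", {
  cohort <- generate_cohort(2, 50, seed = 10)
  windows <- unlist(lapply(cohort, segment), recursive = FALSE)
  labs <- vapply(windows, `[[`, character(1), "label")
  band_power <- vapply(windows, function(w) {
    s <- window_spectrum(median_center(w))
    sel <- s$freqs >= 0.94 & s$freqs <= 2.17
    sum(s$psd_left[sel] + s$psd_right[sel])
  }, numeric(1))
  chew <- labs %in% c("LC", "RC")
  expect_gte(sum(chew), 100)
  expect_gte(sum(labs == "NHM"), 100)
  expect_gt(mean(band_power[chew]), mean(band_power[labs == "NHM"]))
})

test_that("recordings and cohorts round-trip through CSV", {
  p <- subject_profile("S1", preload_left = 1.2)
  rec <- generate_recording(p, data.frame(behavior = "LC", duration_s = 6),
                            seed = 12)
  path <- tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path, subject_id = "S1")
  expect_equal(back$left, rec$left, tolerance = 1e-6)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_identical(back$labels, rec$labels)

  dir <- tempfile()
  write_cohort_csv(generate_cohort(2, 1, seed = 1), dir)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 2)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
})
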