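const_rec <- function(values, fs = 3000, n_ch = 1, seconds = 1) {
  structure(
    list(
      samples = matrix(values, n_ch, fs * seconds), sampling_rate = fs,
      layout = NULL, schedule = NULL, filtered = TRUE, ground_truth = NULL
    ),
    class = "emg_recording"
  )
}

test_that("RMS of a constant signal is its absolute value, in 300-sample bins", {
  ft <- rms_bins(const_rec(-2.5, seconds = 2.5))
  expect_equal(nrow(ft$rms), 25) # 2.5 s at 100 ms bins
  expect_true(all(abs(ft$rms - 2.5) < 1e-12))
})

test_that("binned RMS equals a loop-based oracle and is scale-equivariant", {
  set.seed(21)
  rec <- const_rec(0, n_ch = 2, seconds = 1.3)
  rec$samples <- matrix(rnorm(2 * 3900), 2)
  ft <- rms_bins(rec)
  expect_equal(nrow(ft$rms), 13) # trailing partial bin discarded
  expect_equal(ft$rms, rms_oracle(rec$samples, 3000), tolerance = 1e-10)
  rec7 <- rec
  rec7$samples <- -7 * rec$samples
  expect_equal(rms_bins(rec7)$rms, 7 * ft$rms, tolerance = 1e-12)
})

test_that("history stacking concatenates the current and three preceding bins", {
  set.seed(22)
  rec <- const_rec(0, n_ch = 3, seconds = 2)
  rec$samples <- matrix(rnorm(3 * 6000), 3)
  ft <- rms_bins(rec)
  st <- stack_history(ft, 4)
  expect_equal(ncol(st$stacked), 12) # 3 channels x 4 bins = 400 ms of context
  expect_false(any(st$valid[1:3]))
  expect_true(all(st$valid[4:20]))
  # direct-indexing oracle: row t concatenates rms rows t-3..t, oldest first
  for (t in c(4, 11, 20)) {
    expect_identical(st$stacked[t, ], as.vector(t(ft$rms[(t - 3):t, ])))
  }
  # k = 1 reduces to the rms matrix with every bin valid
  st1 <- stack_history(ft, 1)
  expect_identical(st1$stacked, ft$rms)
  expect_true(all(st1$valid))
  expect_error(stack_history(ft, 0), ">= 1")
})

test_that("normalization standardizes training data and reuses stats on test data", {
  set.seed(23)
  m <- matrix(rnorm(300, mean = 5, sd = 3), 100, 3)
  ns <- fit_normalizer(m)
  z <- apply_normalizer(m, ns)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-9)
  expect_equal(colMeans(z^2), rep(1, 3), tolerance = 1e-9)

  # constant feature maps to 0 through the variance floor
  mc <- cbind(m[, 1], rep(4, 100))
  zc <- apply_normalizer(mc, fit_normalizer(mc))
  expect_true(all(zc[, 2] == 0))

  # hand computation on a 3-sample toy: train mean 2, population sd sqrt(2/3)
  train <- matrix(c(1, 2, 3), ncol = 1)
  ns3 <- fit_normalizer(train)
  expect_equal(ns3$mean, 2)
  expect_equal(ns3$sd, sqrt(2 / 3))
  test <- matrix(c(2, 3, 4), ncol = 1) # shifted by +1
  zt <- apply_normalizer(test, ns3)
  expect_equal(zt[, 1], (c(2, 3, 4) - 2) / sqrt(2 / 3))
  expect_gt(mean(zt), 0) # offset survives train-stats normalization
  expect_error(fit_normalizer(matrix(0, 0, 3)), "Empty")
})

test_that("center windows yield round(W/0.1) - 3 samples per segment", {
  sched <- toy_schedule(
    c("Rest", "Hand Close", "Rest", "Hand Open", "Rest"),
    c(8, 4.4, 5.3, 4.7, 4)
  )
  rec <- const_rec(0, n_ch = 2, seconds = 27)
  set.seed(24)
  rec$samples <- matrix(rnorm(2 * 27 * 3000), 2)
  rec$schedule <- sched
  ft <- stack_history(rms_bins(rec), 4)
  for (w in c(2.5, 1.5, 0.4)) {
    ds <- extract_center_windows(ft, sched, w)
    per_seg <- table(ds$info$segment)
    expect_true(all(per_seg == round(w / 0.1) - 3),
      info = sprintf("width %g", w)
    )
  }
  # labels come from the segment
  ds <- extract_center_windows(ft, sched, 2.5)
  expect_setequal(unique(ds$y), c("Rest", "Hand Close", "Hand Open"))
  # a segment shorter than the window is skipped with a warning
  sched2 <- toy_schedule(c("Rest", "Hand Close", "Rest"), c(8, 1.2, 8))
  expect_warning(
    ds2 <- extract_center_windows(ft, sched2, 2.5),
    "shorter"
  )
  expect_false(2 %in% ds2$info$segment)
})

test_that("the feature pipeline is deterministic", {
  blk <- cached_block()
  rec <- blk$recording
  f1 <- rms_bins(bandpass_notch(rec))
  f2 <- rms_bins(bandpass_notch(rec))
  expect_identical(f1$rms, f2$rms)
})
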