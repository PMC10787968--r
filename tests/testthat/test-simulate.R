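small_sched <- function(seed = 1) {
  make_cue_schedule(c("Hand Close", "Hand Open"), 2, "able", seed = seed)
}

test_that("identical parameters and seed reproduce a recording bit-for-bit", {
  lay <- make_sleeve_layout("small")
  s <- small_sched()
  p <- sim_params(seed = 10)
  r1 <- simulate_emg(s, lay, p)
  r2 <- simulate_emg(s, lay, p)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$ground_truth$latencies, r2$ground_truth$latencies)
})

test_that("true activity boundaries differ from cues by exactly the drawn latencies", {
  lay <- make_sleeve_layout("small")
  s <- small_sched(2)
  r <- simulate_emg(s, lay, sim_params(seed = 11))
  lat <- r$ground_truth$latencies
  ts <- r$ground_truth$true_segments
  expect_equal(
    ts$onset_s[lat$segment] - s$onset_s[lat$segment],
    lat$onset_delay_s
  )
  expect_true(all(lat$onset_delay_s >= 0.2 & lat$onset_delay_s <= 1.2))
})

test_that("movement score 0 silences activity: cue RMS is indistinguishable from rest", {
  lay <- make_sleeve_layout("small")
  s <- small_sched(3)
  r <- simulate_emg(s, lay, sim_params(
    seed = 12, latency_range = c(0, 0),
    movement_scores = c("Hand Close" = 0L, "Hand Open" = 0L)
  ))
  ft <- rms_bins(bandpass_notch(r))
  is_cue <- ft$labels != "Rest"
  pvals <- vapply(seq_len(ncol(ft$rms)), function(ch) {
    t.test(ft$rms[is_cue, ch], ft$rms[!is_cue, ch])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("at high SNR the pattern's top channels carry cue energy (brute-force RMS)", {
  lay <- make_sleeve_layout("small")
  s <- small_sched(4)
  r <- simulate_emg(s, lay, sim_params(seed = 13, snr_db = 20, latency_range = c(0, 0)))
  filt <- bandpass_notch(r)
  # brute-force RMS oracle on raw samples, independent of rms_bins
  rms_by <- function(idx, ch) sqrt(mean(filt$samples[ch, idx]^2))
  fs <- r$sampling_rate
  for (m in c("Hand Close", "Hand Open")) {
    top5 <- order(r$ground_truth$patterns[, m], decreasing = TRUE)[1:5]
    cue_rows <- which(s$label == m)
    rest_rows <- which(s$label == "Rest")
    cue_idx <- unlist(lapply(cue_rows, function(i) {
      (round(s$onset_s[i] * fs) + 1):round(s$offset_s[i] * fs)
    }))
    rest_idx <- unlist(lapply(rest_rows, function(i) {
      (round(s$onset_s[i] * fs) + 1):round(s$offset_s[i] * fs)
    }))
    for (ch in top5) {
      expect_gt(rms_by(cue_idx, ch), rms_by(rest_idx, ch))
    }
  }
})

test_that("increasing pattern spread de-localizes patterns (higher cosine similarity)", {
  lay <- make_sleeve_layout("small")
  mv <- movement_classes()$label[-1]
  mean_cos <- vapply(c(0.8, 1.6, 3.2, 6.4), function(spread) {
    w <- movement_patterns(mv, lay, spread)
    cs <- crossprod(sweep(w, 2, sqrt(colSums(w^2)), `/`))
    mean(cs[upper.tri(cs)])
  }, numeric(1))
  expect_true(all(diff(mean_cos) > 0))
})

test_that("with zero latency and high SNR, inter-class RMS contrast sits inside cues", {
  lay <- make_sleeve_layout("small")
  # bin-grid-aligned schedule so boundary bins are unambiguous
  s <- toy_schedule(
    c("Rest", "Hand Close", "Rest", "Hand Open", "Rest"),
    c(4, 3, 4, 3, 4)
  )
  r <- simulate_emg(s, lay, sim_params(
    seed = 14, snr_db = 20,
    latency_range = c(0, 0), line_noise_amp = 0
  ))
  ft <- rms_bins(bandpass_notch(r))
  # contrast = per-bin RMS exceeding the rest level by > 3 rest SDs,
  # a brute-force noise-robust excess measure
  rest <- ft$rms[ft$labels == "Rest", , drop = FALSE]
  floor_level <- apply(rest, 2, median) + 3 * apply(rest, 2, sd)
  excess <- rowSums(pmax(sweep(ft$rms, 2, floor_level, `-`), 0))
  inside <- sum(excess[ft$labels != "Rest"])
  expect_gte(inside / sum(excess), 0.99)
})

test_that("flexion and extension movements land on their forearm aspects", {
  lay <- make_sleeve_layout("large")
  w <- movement_patterns(c("Hand Close", "Hand Open"), lay, 1.2)
  peak_side <- function(m) lay$side[which.max(w[, m])]
  expect_equal(peak_side("Hand Close"), "flexor")
  expect_equal(peak_side("Hand Open"), "extensor")
})
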