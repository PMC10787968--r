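test_that("the summary signal is the across-channel mean, per bin", {
  one <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(summarize_activity(one), c(1, 2, 3))
  two <- cbind(c(1, 2), c(3, 6))
  expect_equal(summarize_activity(two), c(2, 4))
  set.seed(31)
  m <- matrix(rnorm(75 * 40), 40, 75)
  loop <- vapply(1:40, function(b) {
    s <- 0
    for (ch in 1:75) s <- s + m[b, ch]
    s / 75
  }, numeric(1))
  expect_equal(summarize_activity(m), loop, tolerance = 1e-12)
})

step_summary <- function(schedule, delay_bins = 0, n_bins = NULL, hi = 2, lo = 0) {
  nb <- n_bins
  if (is.null(nb)) nb <- round(hdemg:::schedule_duration(schedule) / 0.1)
  x <- rep(lo, nb)
  for (r in which(schedule$label != "Rest")) {
    b0 <- round(schedule$onset_s[r] / 0.1) + 1 + delay_bins
    b1 <- round(schedule$offset_s[r] / 0.1) + delay_bins
    x[max(1, b0):min(nb, b1)] <- hi
  }
  x
}

test_that("boundaries already on activity steps do not move", {
  s <- toy_schedule(c("Rest", "Hand Close", "Rest", "Hand Open", "Rest"), c(4, 4, 4, 4, 4))
  x <- step_summary(s)
  res <- dynamic_shift(x, s)
  expect_equal(res$per_boundary_shift_s, rep(0, 4))
  expect_equal(res$total_ssr, res$initial_ssr)
})

test_that("a uniform 0.5 s activity delay is recovered at every onset boundary", {
  s <- toy_schedule(c("Rest", "Hand Close", "Rest", "Hand Open", "Rest"), c(4, 4, 4, 4, 4))
  x <- step_summary(s, delay_bins = 5)
  res <- dynamic_shift(x, s)
  onsets <- c(1, 3) # boundaries into the movement segments
  expect_true(all(abs(res$per_boundary_shift_s[onsets] - 0.5) <= 0.1))
  expect_lte(res$total_ssr, res$initial_ssr)
  # labels, count, order unchanged
  expect_identical(res$shifted_schedule$label, s$label)
})

test_that("dynamic shift matches an exhaustive joint search on 3-segment instances", {
  set.seed(32)
  for (rep in 1:5) {
    s <- toy_schedule(c("Rest", "Hand Close", "Rest"), c(4, 4, 4))
    delay <- sample(2:9, 1)
    x <- step_summary(s, delay_bins = delay) + rnorm(120, 0, 0.05)
    res <- dynamic_shift(x, s)
    oracle <- exhaustive_shift_oracle(x, s)
    expect_equal(res$total_ssr, oracle$ssr, tolerance = 1e-9)
  }
})

test_that("shifts saturate at the 2 s cap for very late activity", {
  s <- toy_schedule(c("Rest", "Hand Close", "Rest"), c(6, 6, 8))
  x <- step_summary(s, delay_bins = 30) # 3 s late
  res <- dynamic_shift(x, s)
  expect_equal(res$per_boundary_shift_s[1], 2.0)
  expect_true(all(abs(res$per_boundary_shift_s) <= 2 + 1e-9))
})

test_that("forward-only mode never moves a boundary earlier than the cue", {
  s <- toy_schedule(c("Rest", "Hand Close", "Rest"), c(4, 4, 4))
  x <- step_summary(s, delay_bins = -3) # activity 0.3 s early
  res_both <- dynamic_shift(x, s)
  expect_lt(res_both$per_boundary_shift_s[1], 0)
  res_fwd <- dynamic_shift(x, s, forward_only = TRUE)
  expect_true(all(res_fwd$per_boundary_shift_s >= 0))
})

test_that("SSR never increases across sweeps and the search terminates", {
  set.seed(33)
  s <- toy_schedule(
    c("Rest", "Hand Close", "Rest", "Hand Open", "Rest", "Wrist Flexion", "Rest"),
    c(4, 5, 4, 5, 4, 5, 4)
  )
  x <- step_summary(s, delay_bins = 6) + rnorm(310, 0, 0.3)
  res <- dynamic_shift(x, s)
  expect_lte(res$total_ssr, res$initial_ssr)
  expect_lte(res$iterations, 50)
  # the shifted schedule still tiles time and keeps every segment alive
  sh <- res$shifted_schedule
  expect_true(all(sh$offset_s - sh$onset_s > 0))
  expect_equal(sh$onset_s[-1], sh$offset_s[-nrow(sh)])
})

test_that("alignment errors are caught", {
  s <- toy_schedule(c("Rest", "Hand Close", "Rest"), c(4, 4, 4))
  expect_error(dynamic_shift(rep(0, 5), s), "cover|shorter")
  expect_error(dynamic_shift(rep(0, 120), s, max_shift_s = -1), ">= 0")
  expect_error(summarize_activity(matrix(0, 0, 3)), "Empty")
})
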