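pv <- function(...) {
  v <- c(...)
  stopifnot(abs(sum(v) - 1) < 1e-9)
  v
}

run_policy <- function(traces, policy) {
  st <- decoder_state(policy)
  out <- character(length(traces))
  for (i in seq_along(traces)) {
    r <- decoder_step(st, traces[[i]], policy)
    st <- r$state
    out[i] <- r$emitted
  }
  out
}

test_that("the fastest legal switch takes two supra-threshold bins", {
  pol <- online_policy()
  tr <- list(
    pv(Rest = 0, A = 1), pv(Rest = 0, A = 1)
  )
  expect_equal(run_policy(tr, pol), c("Rest", "A"))
})

test_that("probabilities at or below 0.6 never change the state", {
  pol <- online_policy()
  tr <- replicate(20, pv(Rest = 0.41, A = 0.59), simplify = FALSE)
  expect_equal(unique(run_policy(tr, pol)), "Rest")
  # exactly at the threshold also fails (strict inequality)
  tr2 <- replicate(5, pv(Rest = 0.4, A = 0.6), simplify = FALSE)
  expect_equal(unique(run_policy(tr2, pol)), "Rest")
})

test_that("an 8-bin trace reproduces the hand-simulated debounce exactly", {
  pol <- online_policy()
  mk <- function(cls, p) {
    v <- c(Rest = 0, A = 0, B = 0)
    v[cls] <- p
    v["Rest"] <- v["Rest"] + (1 - sum(v))
    v
  }
  tr <- list(
    mk("A", 0.7), mk("A", 0.5), mk("A", 0.7), mk("A", 0.7),
    mk("B", 0.9), mk("B", 0.9), mk("A", 0.7), mk("A", 0.7)
  )
  # hand simulation: A0.7 pends; A0.5 resets; A0.7 pends; A0.7 switches;
  # B0.9 pends; B0.9 switches; A0.7 pends; A0.7 switches.
  expect_equal(
    run_policy(tr, pol),
    c("Rest", "Rest", "Rest", "A", "A", "B", "B", "A")
  )
})

test_that("degenerate policies behave as closed forms predict", {
  # threshold above 1: constant initial state
  pol_hi <- online_policy(prob_threshold = 1.01)
  tr <- replicate(10, pv(Rest = 0, A = 1), simplify = FALSE)
  expect_equal(unique(run_policy(tr, pol_hi)), "Rest")
  # stability 1 and threshold ~0: raw argmax
  pol_raw <- online_policy(prob_threshold = 1e-9, stability_count = 1)
  set.seed(71)
  tr2 <- replicate(30, {
    v <- runif(3)
    v <- v / sum(v)
    names(v) <- c("Rest", "A", "B")
    v
  }, simplify = FALSE)
  argmax <- vapply(tr2, function(v) names(v)[which.max(v)], "")
  expect_equal(run_policy(tr2, pol_raw), argmax)
  # emitted changes are never more frequent than once per stability_count bins
  pol <- online_policy(prob_threshold = 0.1, stability_count = 2)
  out <- run_policy(tr2, pol)
  changes <- which(out[-1] != out[-length(out)])
  if (length(changes) > 1) expect_true(all(diff(changes) >= 2))
})

test_that("decoder state serializes mid-stream without changing the output", {
  pol <- online_policy()
  set.seed(72)
  tr <- replicate(40, {
    v <- runif(3)^3
    v <- v / sum(v)
    names(v) <- c("Rest", "A", "B")
    v
  }, simplify = FALSE)
  full <- run_policy(tr, pol)
  st <- decoder_state(pol)
  out <- character(40)
  for (i in 1:20) {
    r <- decoder_step(st, tr[[i]], pol)
    st <- r$state
    out[i] <- r$emitted
  }
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(st, path)
  st2 <- readRDS(path)
  for (i in 21:40) {
    r <- decoder_step(st2, tr[[i]], pol)
    st2 <- r$state
    out[i] <- r$emitted
  }
  expect_equal(out, full)
  expect_error(decoder_step(st, c(a = 0.7, b = 0.7), pol), "summing to 1")
})

test_that("replay equals the batch pipeline bin for bin", {
  blk <- cached_block()
  ds <- blk$dataset
  m <- fit_linear(ds$x, ds$y, "LR", grid = grid_search_spec(c_grid = c(1, 100)), seed = 3)
  pol <- online_policy()
  streamed <- replay(blk$recording, m, blk$norm_stats, pol)

  ft <- blk$features # batch: filtered, normalized, stacked
  proba <- predict_proba(m, ft$stacked[ft$valid, , drop = FALSE])
  st <- decoder_state(pol)
  batch_cls <- character(nrow(proba))
  for (i in seq_len(nrow(proba))) {
    r <- decoder_step(st, proba[i, ], pol)
    st <- r$state
    batch_cls[i] <- r$emitted
  }
  expect_equal(streamed$class[streamed$bin >= 4], batch_cls)
  expect_equal(streamed$class[1:3], rep("Rest", 3))
})

test_that("a silent stream with a rest-predicting model stays at Rest", {
  blk <- cached_block()
  ds <- blk$dataset
  m <- fit_linear(ds$x, ds$y, "LR", grid = grid_search_spec(c_grid = 1), seed = 3)
  silent <- blk$recording
  silent$samples <- matrix(0, nrow(silent$samples), 6000)
  out <- replay(silent, m, blk$norm_stats)
  expect_equal(unique(out$class), "Rest")
})
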