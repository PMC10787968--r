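test_that("bin accuracy counts matching bins and equals 1 - normalized Hamming", {
  expect_equal(bin_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(bin_accuracy(c("a", "b"), c("b", "a")), 0)
  pred <- c("a", "a", "b", "b", "a", "b", "a", "a", "b", "a")
  truth <- c("a", "b", "b", "b", "a", "a", "a", "b", "b", "a")
  expect_equal(bin_accuracy(pred, truth), 0.7) # 7 matches by hand count
  set.seed(61)
  p <- sample(letters[1:3], 200, replace = TRUE)
  t <- sample(letters[1:3], 200, replace = TRUE)
  hamming <- sum(p != t)
  expect_equal(bin_accuracy(p, t), 1 - hamming / 200)
  expect_error(bin_accuracy("a", c("a", "b")), "mismatch")
})

test_that("chance level is the majority-class fraction", {
  expect_equal(chance_level(c(rep("Rest", 6), rep("Move", 4))), 0.6)
  expect_equal(chance_level(rep(movement_classes()$label, 3)), 1 / 13)
  set.seed(62)
  v <- sample(letters[1:5], 321, replace = TRUE)
  counts <- integer(5)
  for (x in v) counts[match(x, letters[1:5])] <- counts[match(x, letters[1:5])] + 1
  expect_equal(chance_level(v), max(counts) / 321)
  expect_error(chance_level(character()), "Empty")
})

test_that("success requires at least 10 consecutive correct bins inside the cue", {
  s <- toy_schedule(c("Rest", "Hand Close", "Rest"), c(4, 4, 4))
  base <- schedule_bin_labels(s, 120)
  # fully correct cue -> success
  expect_equal(success_rate(base, s)$rate, 1)
  # exactly 9 consecutive correct, rest of cue wrong -> failure
  cue_bins <- 41:80
  p9 <- base
  p9[cue_bins] <- "Hand Open"
  p9[41:49] <- "Hand Close"
  expect_equal(success_rate(p9, s)$rate, 0)
  # exactly 10 consecutive correct -> success
  p10 <- p9
  p10[41:50] <- "Hand Close"
  expect_equal(success_rate(p10, s)$rate, 1)
})

test_that("a 5-cue toy is scored exactly as hand tallies say", {
  s <- toy_schedule(
    c("Rest", "Hand Close", "Rest", "Hand Open", "Rest", "Hand Close", "Rest",
      "Hand Open", "Rest", "Wrist Flexion", "Rest"),
    c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2)
  )
  pred <- schedule_bin_labels(s, 220)
  # cue 2 (Hand Open, bins 61-80): only 9 correct -> fail
  pred[61:80] <- c(rep("Hand Open", 9), rep("Rest", 11))
  # cue 3 (Hand Close, bins 101-120): correct run of 12 -> success
  pred[101:120] <- c(rep("Rest", 4), rep("Hand Close", 12), rep("Rest", 4))
  # cue 4 (Hand Open, bins 141-160): alternating -> fail
  pred[141:160] <- rep(c("Hand Open", "Rest"), 10)
  # cue 5 (Wrist Flexion, bins 181-200): all wrong class -> fail
  pred[181:200] <- "Hand Close"
  sr <- success_rate(pred, s)
  expect_equal(sr$rate, 2 / 5) # cues 1 and 3 succeed
  pc <- sr$per_class
  expect_equal(pc$successes[pc$label == "Hand Close"], 2)
  expect_equal(pc$attempts[pc$label == "Hand Open"], 2)
  expect_equal(pc$successes[pc$label == "Wrist Flexion"], 0)
  # flipping a wrong bin to correct never decreases the rate (monotonicity)
  for (i in c(70, 145, 190)) {
    pred2 <- pred
    pred2[i] <- schedule_bin_labels(s, 220)[i]
    expect_gte(success_rate(pred2, s)$rate, sr$rate)
  }
  # rest periods can be scored too
  expect_equal(success_rate(schedule_bin_labels(s, 220), s, include_rest = TRUE)$rate, 1)
})

test_that("confusion matrices count, total, and permute correctly", {
  truth <- c("a", "a", "b", "b", "c", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a", "c")
  cm <- confusion(pred, truth, classes = c("a", "b", "c"))
  # hand tally
  expect_equal(unname(cm["a", ]), c(1, 1, 0))
  expect_equal(unname(cm["b", ]), c(0, 2, 0))
  expect_equal(unname(cm["c", ]), c(1, 0, 2))
  expect_equal(sum(cm), 7)
  perfect <- confusion(truth, truth, classes = c("a", "b", "c"))
  expect_true(all(perfect[upper.tri(perfect)] == 0) && all(perfect[lower.tri(perfect)] == 0))
  expect_error(confusion(c("a", "z"), c("a", "a"), classes = c("a", "b")), "outside")
  # metrics are invariant to class-order permutation
  cm2 <- confusion(pred, truth, classes = c("c", "a", "b"))
  expect_equal(sum(diag(cm2)), sum(diag(cm)))
})

test_that("subset construction balances rest at 50% with the preceding rest cues", {
  blk <- cached_block()
  ds <- blk$dataset
  sub <- build_subset(ds, blk$schedule, subset_spec("binary_rest_move"))
  expect_setequal(unique(sub$y), c("Rest", "Move"))
  expect_lte(abs(mean(sub$y == "Rest") - 0.5), 1 / length(sub$y))
  expect_equal(chance_level(sub$y), 0.5, tolerance = 1 / length(sub$y))

  sub3 <- build_subset(ds, blk$schedule, subset_spec("fixed_three"))
  expect_setequal(unique(sub3$y), c("Rest", "Hand Close", "Hand Open"))
  expect_lte(abs(mean(sub3$y == "Rest") - 0.5), 1 / length(sub3$y))

  acc <- c("Hand Close" = 0.9, "Hand Open" = 0.7, "Wrist Flexion" = 0.4)
  top <- build_subset(ds, blk$schedule, subset_spec("top_k", k = 2), acc)
  expect_setequal(unique(top$y), c("Rest", "Hand Close", "Hand Open"))
  expect_error(
    build_subset(ds, blk$schedule, subset_spec("top_k", k = 9), acc),
    "exceeds"
  )
  expect_error(build_subset(ds, blk$schedule, subset_spec("top_k", k = 2)), "per_class_accuracy")
})

test_that("evaluation reports bundle the metrics coherently", {
  blk <- cached_block()
  truth <- schedule_bin_labels(blk$schedule, nrow(blk$features$rms))
  pred <- truth
  pred[5:10] <- "Hand Close"
  rep <- eval_report(pred, truth, blk$schedule)
  expect_equal(rep$bin_accuracy, 1 - 6 / length(truth))
  expect_equal(sum(rep$confusion), length(truth))
  expect_equal(rep$success$rate, 1)
  g <- glance(rep)
  expect_true(all(c("bin_accuracy", "chance_level", "success_rate") %in% names(g)))
  expect_true(all(g$bin_accuracy >= 0 & g$bin_accuracy <= 1))
})
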