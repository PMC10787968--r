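test_that("the default architecture has the stated dimensions and parameter count", {
  spec <- mlp_spec(64 * 4)
  expect_equal(spec$hidden, c(1000L, 500L))
  expect_equal(spec$n_classes, 13L)
  # closed-form count: linear layers + batch-norm scale/shift
  expected <- (256 * 1000 + 1000) + (1000 * 500 + 500) + (500 * 13 + 13) +
    2 * (1000 + 500)
  expect_equal(mlp_n_params(spec), expected)
})

test_that("forward probabilities are a proper distribution and match an independent oracle", {
  set.seed(51)
  spec <- mlp_spec(10, hidden = c(7, 5), n_classes = 4, epochs = 3, batch_size = 8)
  x <- matrix(rnorm(30 * 10), 30, 10)
  y <- sample(c("Rest", "Hand Close", "Hand Open", "Key Pinch"), 30, replace = TRUE)
  m <- fit_mlp(x, y, spec, seed = 1)
  p <- predict_proba(m, x)
  expect_equal(unname(rowSums(p)), rep(1, 30), tolerance = 1e-6)
  expect_true(all(p > 0))
  # independent eval-mode forward pass
  p_oracle <- mlp_forward_oracle(m$par, x, spec)
  expect_equal(unname(p), p_oracle, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences through batchnorm and dropout-off path", {
  set.seed(52)
  spec <- mlp_spec(6, hidden = c(5, 4), n_classes = 3, dropout = 0, smoothing = 0.9)
  par <- hdemg:::mlp_init(spec)
  x <- matrix(rnorm(7 * 6), 7, 6)
  y_idx <- sample(1:3, 7, replace = TRUE)
  tgt <- hdemg:::smoothed_targets(y_idx, 3, 0.9)

  loss_of <- function(par) {
    fw <- hdemg:::mlp_forward(par, x, spec, training = TRUE)
    hdemg:::smoothed_ce(fw$proba, tgt)
  }
  fw <- hdemg:::mlp_forward(par, x, spec, training = TRUE)
  gr <- hdemg:::mlp_backward(par, fw, tgt, spec)

  eps <- 1e-6
  check <- function(get, set, g) {
    v <- get(par)
    idx <- sample(length(v), min(8, length(v)))
    for (i in idx) {
      pp <- par
      vv <- v
      vv[i] <- vv[i] + eps
      pp <- set(pp, vv)
      up <- loss_of(pp)
      vv[i] <- vv[i] - 2 * eps
      pp <- set(pp, vv)
      dn <- loss_of(pp)
      expect_equal((up - dn) / (2 * eps), g[i], tolerance = 1e-4)
    }
  }
  check(
    function(p) p$layers[[1]]$W,
    function(p, v) {
      p$layers[[1]]$W <- matrix(v, nrow(p$layers[[1]]$W))
      p
    },
    gr$layers[[1]]$W
  )
  check(
    function(p) p$layers[[3]]$W,
    function(p, v) {
      p$layers[[3]]$W <- matrix(v, nrow(p$layers[[3]]$W))
      p
    },
    gr$layers[[3]]$W
  )
  check(
    function(p) p$bn[[2]]$gamma,
    function(p, v) {
      p$bn[[2]]$gamma <- v
      p
    },
    gr$bn[[2]]$gamma
  )
  check(
    function(p) p$layers[[2]]$b,
    function(p, v) {
      p$layers[[2]]$b <- v
      p
    },
    gr$layers[[2]]$b
  )
})

test_that("well-separated 13-class features are decoded near-perfectly", {
  set.seed(53)
  classes <- movement_classes()$label
  d <- 24
  centers <- matrix(rnorm(13 * d), 13, d) * 6 # inter-class distance >> noise SD
  make_split <- function(n_per) {
    x <- do.call(rbind, lapply(1:13, function(i) {
      matrix(rnorm(n_per * d), n_per, d) + matrix(centers[i, ], n_per, d, byrow = TRUE)
    }))
    list(x = x, y = rep(classes, each = n_per))
  }
  train <- make_split(20)
  test <- make_split(8)
  # nearest-centroid oracle must itself find the task easy
  cent <- do.call(rbind, lapply(classes, function(cl) colMeans(train$x[train$y == cl, ])))
  d2 <- as.matrix(dist(rbind(cent, test$x)))[-(1:13), 1:13]
  nc_acc <- mean(classes[apply(d2, 1, which.min)] == test$y)
  expect_gte(nc_acc, 0.99)

  m <- fit_mlp(train$x, train$y,
    mlp_spec(d, epochs = 40, batch_size = 32),
    seed = 2
  )
  expect_gte(mean(predict(m, test$x) == test$y), 0.99)
})

test_that("training is deterministic under a seed and validates dimensions", {
  set.seed(54)
  x <- matrix(rnorm(40 * 8), 40, 8)
  y <- rep(c("Rest", "Hand Close"), 20)
  spec <- mlp_spec(8, hidden = c(6, 4), n_classes = 2, epochs = 5)
  m1 <- fit_mlp(x, y, spec, seed = 9)
  m2 <- fit_mlp(x, y, spec, seed = 9)
  expect_identical(m1$par, m2$par)
  expect_error(fit_mlp(x[, 1:5], y, spec, seed = 1), "does not match")
  expect_error(
    fit_mlp(x, y, mlp_spec(8, hidden = c(6, 4), n_classes = 5, epochs = 2), 1),
    "classes"
  )
})
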