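#' Neural-network architecture and training recipe
#'
#' The decoding network is a fully-connected multilayer perceptron: the
#' flattened channels x 4 RMS input feeds two hidden layers of 1000 and 500
#' units, each followed by batch normalization and ReLU with 20% dropout,
#' and a softmax output over the classes (13 for the full movement set).
#' Training uses label-smoothing cross entropy (true-class probability 0.9),
#' the Adam optimizer under a one-cycle learning-rate schedule, and early
#' stopping on a 10% validation split.
#'
#' @param input_dim Input dimension (channels x stacked bins).
#' @param hidden Hidden layer sizes (default `c(1000, 500)`).
#' @param n_classes Output classes (default 13).
#' @param dropout Dropout probability per hidden layer (default 0.2).
#' @param smoothing Label-smoothing target probability for the true class
#'   (default 0.9; the remaining 0.1 is spread uniformly over other classes).
#' @param epochs Maximum training epochs (default 400).
#' @param batch_size Minibatch size (default 64).
#' @param max_lr Peak learning rate of the one-cycle schedule (default 1e-3).
#' @param val_frac Validation fraction for early stopping (default 0.1).
#' @param patience Early-stopping patience in epochs (default 20).
#' @return A list of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim, hidden = c(1000L, 500L), n_classes = 13L,
                     dropout = 0.2, smoothing = 0.9, epochs = 400L,
                     batch_size = 64L, max_lr = 1e-3, val_frac = 0.1,
                     patience = 20L) {
  stopifnot_scalar_number(input_dim, "input_dim")
  structure(
    list(
      input_dim = as.integer(input_dim), hidden = as.integer(hidden),
      n_classes = as.integer(n_classes), dropout = dropout,
      smoothing = smoothing, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), max_lr = max_lr,
      val_frac = val_frac, patience = as.integer(patience)
    ),
    class = "mlp_spec"
  )
}

#' Trainable parameter count of the network
#'
#' Linear layers contribute `in * out + out`; each batch-norm layer adds a
#' scale and shift per unit.
#'
#' @param spec An [mlp_spec()].
#' @return Integer parameter count.
#' @export
mlp_n_params <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden, spec$n_classes)
  lin <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  bn <- 2L * sum(spec$hidden)
  as.integer(lin + bn)
}

mlp_init <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden, spec$n_classes)
  layers <- list()
  for (i in seq_len(length(dims) - 1L)) {
    fan_in <- dims[i]
    layers[[i]] <- list(
      W = matrix(rnorm(fan_in * dims[i + 1], 0, sqrt(2 / fan_in)), fan_in, dims[i + 1]),
      b = numeric(dims[i + 1])
    )
  }
  bn <- lapply(spec$hidden, function(h) {
    list(
      gamma = rep(1, h), beta = numeric(h),
      run_mean = numeric(h), run_var = rep(1, h)
    )
  })
  list(layers = layers, bn = bn)
}

bn_eps <- 1e-5

# Forward pass. In training mode uses batch statistics (updating running
# stats) and applies inverted dropout; in eval mode uses running statistics
# and no dropout. Returns activations needed for the backward pass.
mlp_forward <- function(par, x, spec, training = FALSE) {
  n_hidden <- length(spec$hidden)
  cache <- list(x = x)
  a <- x
  for (i in seq_len(n_hidden)) {
    z <- sweep(a %*% par$layers[[i]]$W, 2, par$layers[[i]]$b, `+`)
    bn <- par$bn[[i]]
    if (training) {
      mu <- colMeans(z)
      v <- colMeans(sweep(z, 2, mu)^2)
      par$bn[[i]]$run_mean <- 0.9 * bn$run_mean + 0.1 * mu
      par$bn[[i]]$run_var <- 0.9 * bn$run_var + 0.1 * v
    } else {
      mu <- bn$run_mean
      v <- bn$run_var
    }
    xhat <- sweep(sweep(z, 2, mu), 2, sqrt(v + bn_eps), `/`)
    zn <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
    h <- pmax(zn, 0)
    if (training && spec$dropout > 0) {
      mask <- matrix(
        rbinom(length(h), 1, 1 - spec$dropout) / (1 - spec$dropout),
        nrow(h), ncol(h)
      )
      h <- h * mask
      cache[[paste0("mask", i)]] <- mask
    }
    cache[[paste0("z", i)]] <- z
    cache[[paste0("xhat", i)]] <- xhat
    cache[[paste0("mu", i)]] <- mu
    cache[[paste0("v", i)]] <- v
    cache[[paste0("zn", i)]] <- zn
    cache[[paste0("a", i)]] <- h
    a <- h
  }
  out_i <- n_hidden + 1L
  logits <- sweep(a %*% par$layers[[out_i]]$W, 2, par$layers[[out_i]]$b, `+`)
  p <- softmax_rows(logits, colnames(logits))
  list(proba = p, logits = logits, cache = cache, par = par)
}

# Backward pass for smoothed cross entropy; returns gradients shaped like par.
mlp_backward <- function(par, fw, target, spec) {
  n <- nrow(target)
  n_hidden <- length(spec$hidden)
  grads <- list(layers = vector("list", n_hidden + 1L), bn = vector("list", n_hidden))
  delta <- (fw$proba - target) / n # dL/dlogits
  a_prev <- fw$cache[[paste0("a", n_hidden)]]
  out_i <- n_hidden + 1L
  grads$layers[[out_i]] <- list(
    W = crossprod(a_prev, delta),
    b = colSums(delta)
  )
  da <- delta %*% t(par$layers[[out_i]]$W)
  for (i in rev(seq_len(n_hidden))) {
    mask <- fw$cache[[paste0("mask", i)]]
    if (!is.null(mask)) da <- da * mask
    zn <- fw$cache[[paste0("zn", i)]]
    dzn <- da * (zn > 0)
    xhat <- fw$cache[[paste0("xhat", i)]]
    bn <- par$bn[[i]]
    grads$bn[[i]] <- list(
      gamma = colSums(dzn * xhat),
      beta = colSums(dzn)
    )
    dxhat <- sweep(dzn, 2, bn$gamma, `*`)
    v <- fw$cache[[paste0("v", i)]]
    inv_sd <- 1 / sqrt(v + bn_eps)
    m <- nrow(dxhat)
    # batch-norm backward (batch statistics)
    dz <- sweep(
      dxhat - matrix(colMeans(dxhat), m, ncol(dxhat), byrow = TRUE) -
        sweep(xhat, 2, colMeans(dxhat * xhat), `*`),
      2, inv_sd, `*`
    )
    a_prev <- if (i == 1L) fw$cache$x else fw$cache[[paste0("a", i - 1L)]]
    grads$layers[[i]] <- list(
      W = crossprod(a_prev, dz),
      b = colSums(dz)
    )
    if (i > 1L) da <- dz %*% t(par$layers[[i]]$W)
  }
  grads
}

smoothed_targets <- function(y_idx, n_classes, p) {
  t <- matrix((1 - p) / (n_classes - 1), length(y_idx), n_classes)
  t[cbind(seq_along(y_idx), y_idx)] <- p
  t
}

smoothed_ce <- function(proba, target) {
  -mean(rowSums(target * log(pmax(proba, 1e-12))))
}

# One-cycle schedule: cosine warmup from max_lr/25 to max_lr over the first
# 30% of steps, cosine anneal to max_lr/1e4 over the rest.
one_cycle_lr <- function(step, total_steps, max_lr) {
  pct <- step / max(total_steps, 1)
  if (pct <= 0.3) {
    lo <- max_lr / 25
    lo + (max_lr - lo) * (1 - cos(pi * pct / 0.3)) / 2
  } else {
    hi <- max_lr
    lo <- max_lr / 1e4
    lo + (hi - lo) * (1 + cos(pi * (pct - 0.3) / 0.7)) / 2
  }
}

adam_new <- function(par) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(
    m = list(
      layers = lapply(par$layers, zero_like),
      bn = lapply(par$bn, function(b) list(gamma = b$gamma * 0, beta = b$beta * 0))
    ),
    v = list(
      layers = lapply(par$layers, zero_like),
      bn = lapply(par$bn, function(b) list(gamma = b$gamma * 0, beta = b$beta * 0))
    ),
    t = 0L
  )
}

adam_step <- function(par, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(par$layers)) {
    for (nm in c("W", "b")) {
      u <- upd(par$layers[[i]][[nm]], grads$layers[[i]][[nm]],
               opt$m$layers[[i]][[nm]], opt$v$layers[[i]][[nm]])
      par$layers[[i]][[nm]] <- u$p
      opt$m$layers[[i]][[nm]] <- u$m
      opt$v$layers[[i]][[nm]] <- u$v
    }
  }
  for (i in seq_along(par$bn)) {
    for (nm in c("gamma", "beta")) {
      u <- upd(par$bn[[i]][[nm]], grads$bn[[i]][[nm]],
               opt$m$bn[[i]][[nm]], opt$v$bn[[i]][[nm]])
      par$bn[[i]][[nm]] <- u$p
      opt$m$bn[[i]][[nm]] <- u$m
      opt$v$bn[[i]][[nm]] <- u$v
    }
  }
  list(par = par, opt = opt)
}

#' Train the multilayer-perceptron decoder
#'
#' Trains the [mlp_spec()] network on stacked RMS samples with
#' label-smoothing cross entropy, Adam, a one-cycle learning-rate schedule,
#' and early stopping (validation loss, configurable patience, best weights
#' restored). Fully deterministic given `seed`.
#'
#' @param x Training samples x features matrix (normalized, stacked).
#' @param y Character labels.
#' @param spec An [mlp_spec()]; its `input_dim` must match `ncol(x)`.
#' @param seed RNG seed controlling initialization, the validation split,
#'   batch shuffling and dropout.
#' @return An object of class `emg_mlp` / `emg_model` with the trained
#'   parameters and a per-epoch training log.
#' @export
fit_mlp <- function(x, y, spec = NULL, seed = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort_classes(unique(y))
  if (length(classes) < 2L) abort("Need at least 2 classes.")
  if (is.null(spec)) spec <- mlp_spec(ncol(x), n_classes = length(classes))
  if (spec$input_dim != ncol(x)) {
    abort(sprintf("Input dim %d does not match spec (%d).", ncol(x), spec$input_dim))
  }
  if (spec$n_classes != length(classes)) {
    abort(sprintf(
      "Spec declares %d classes but the data have %d.",
      spec$n_classes, length(classes)
    ))
  }
  y_idx <- match(y, classes)

  with_rng(seed, {
    par <- mlp_init(spec)
    opt <- adam_new(par)

    n <- nrow(x)
    n_val <- max(1L, round(spec$val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    xt <- x[tr_idx, , drop = FALSE]
    yt <- y_idx[tr_idx]
    xv <- x[val_idx, , drop = FALSE]
    tv <- smoothed_targets(y_idx[val_idx], spec$n_classes, spec$smoothing)

    steps_per_epoch <- max(1L, ceiling(length(tr_idx) / spec$batch_size))
    total_steps <- steps_per_epoch * spec$epochs
    best <- list(loss = Inf, par = par, epoch = 0L)
    log <- vector("list", spec$epochs)
    step <- 0L
    for (epoch in seq_len(spec$epochs)) {
      perm <- sample(seq_along(tr_idx))
      ep_loss <- 0
      for (bstart in seq(1L, length(perm), by = spec$batch_size)) {
        bi <- perm[bstart:min(bstart + spec$batch_size - 1L, length(perm))]
        step <- step + 1L
        fw <- mlp_forward(par, xt[bi, , drop = FALSE], spec, training = TRUE)
        par <- fw$par # running BN stats updated
        tgt <- smoothed_targets(yt[bi], spec$n_classes, spec$smoothing)
        ep_loss <- ep_loss + smoothed_ce(fw$proba, tgt) * length(bi)
        grads <- mlp_backward(par, fw, tgt, spec)
        st <- adam_step(par, grads, opt, one_cycle_lr(step, total_steps, spec$max_lr))
        par <- st$par
        opt <- st$opt
      }
      val_p <- mlp_forward(par, xv, spec, training = FALSE)$proba
      val_loss <- smoothed_ce(val_p, tv)
      log[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = ep_loss / length(tr_idx),
        val_loss = val_loss
      )
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, par = par, epoch = epoch)
      } else if (epoch - best$epoch >= spec$patience) {
        break
      }
    }

    structure(
      list(
        kind = "MLP", classes = classes, pca = NULL,
        par = best$par, spec = spec,
        hyper = list(max_lr = spec$max_lr, epochs_run = epoch,
                     best_epoch = best$epoch),
        log = dplyr::bind_rows(log)
      ),
      class = c("emg_mlp", "emg_model")
    )
  })
}

#' @export
predict_proba.emg_mlp <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$spec$input_dim) {
    abort(sprintf(
      "Feature dimension %d does not match the model's %d.",
      ncol(x), model$spec$input_dim
    ))
  }
  p <- mlp_forward(model$par, x, model$spec, training = FALSE)$proba
  colnames(p) <- model$classes
  p
}

#' @export
glance.emg_mlp <- function(x, ...) {
  tibble::tibble(
    kind = "MLP",
    n_classes = length(x$classes),
    n_params = mlp_n_params(x$spec),
    epochs_run = x$hyper$epochs_run,
    best_epoch = x$hyper$best_epoch,
    best_val_loss = min(x$log$val_loss)
  )
}

#' @export
tidy.emg_mlp <- function(x, ...) x$log
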