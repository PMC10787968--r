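#' Hyperparameter grid for the linear classifiers
#'
#' Both regularized classifiers are tuned by grid search with fivefold
#' cross-validation on the training data: the inverse-regularization
#' strength C spans 1e-4 to 1e4 (log-spaced), and the RBF kernel width gamma
#' (SVM only) spans the same range.
#'
#' @param c_grid Candidate C values.
#' @param gamma_grid Candidate gamma values (SVM only).
#' @param folds Number of cross-validation folds (default 5).
#' @return A list of class `grid_search_spec`.
#' @export
grid_search_spec <- function(c_grid = 10^seq(-4, 4, length.out = 9),
                             gamma_grid = 10^seq(-4, 4, length.out = 9),
                             folds = 5L) {
  if (!length(c_grid) || !length(gamma_grid)) abort("Grids must be non-empty.")
  if (folds < 2L) abort("`folds` must be >= 2.")
  structure(
    list(c_grid = sort(c_grid), gamma_grid = sort(gamma_grid), folds = as.integer(folds)),
    class = "grid_search_spec"
  )
}

# PCA retaining the fewest leading components explaining >= `threshold`
# of the training variance.
fit_pca <- function(x, threshold = 0.95) {
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  ratio <- cumsum(ev) / sum(ev)
  m <- which(ratio >= threshold)[1]
  list(
    mean = p$center,
    rotation = p$rotation[, seq_len(m), drop = FALSE],
    explained = ratio[m],
    n_components = m
  )
}

pca_project <- function(pca, x) {
  sweep(as.matrix(x), 2, pca$mean, `-`) %*% pca$rotation
}

# Stratified fold assignment: shuffle within class, deal folds round-robin.
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a PCA + logistic regression or PCA + SVM classifier
#'
#' Features are reduced by PCA (components covering at least 95% of the
#' training variance), then classified by multinomial L2-regularized
#' logistic regression (`kind = "LR"`) or an RBF-kernel support vector
#' machine (`kind = "SVM"`). Hyperparameters are chosen by grid search with
#' stratified fivefold cross-validation on the training data (best mean CV
#' accuracy; ties go to the smallest C, then the smallest gamma), and the
#' winning model is refitted on all training data.
#'
#' @param x Training samples (rows) x features matrix, already normalized.
#' @param y Training labels (character).
#' @param kind `"LR"` or `"SVM"`.
#' @param grid A [grid_search_spec()].
#' @param seed RNG seed for fold assignment.
#' @param pca_var PCA explained-variance threshold (default 0.95).
#' @return An object of class `emg_model` (and `emg_lr` / `emg_svm`).
#' @export
fit_linear <- function(x, y, kind = c("LR", "SVM"), grid = grid_search_spec(),
                       seed = 1, pca_var = 0.95) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort_classes(unique(y))
  if (length(classes) < 2L) abort("Need at least 2 classes.")
  if (nrow(x) < grid$folds) abort("Fewer samples than folds.")

  with_rng(seed, {
    pca <- fit_pca(x, pca_var)
    z <- pca_project(pca, x)
    fold <- make_folds(y, grid$folds)

    if (kind == "LR") {
      cv <- cv_accuracy_lr(z, y, fold, grid)
      best <- pick_best(cv, c("c"))
      fit <- fit_lr_full(z, y, classes, best$c)
      model <- structure(
        list(
          kind = "LR", classes = classes, pca = pca,
          coef = fit, hyper = list(C = best$c),
          cv = cv
        ),
        class = c("emg_lr", "emg_model")
      )
    } else {
      cv <- cv_accuracy_svm(z, y, fold, grid)
      best <- pick_best(cv, c("c", "gamma"))
      svm_fit <- e1071::svm(
        x = z, y = factor(y, levels = classes),
        kernel = "radial", cost = best$c, gamma = best$gamma, scale = FALSE
      )
      model <- structure(
        list(
          kind = "SVM", classes = classes, pca = pca,
          svm = svm_fit, hyper = list(C = best$c, gamma = best$gamma),
          cv = cv
        ),
        class = c("emg_svm", "emg_model")
      )
    }
    model
  })
}

# Rest (class index 0) first, then the field's fixed movement order, then
# anything else alphabetically; gives stable argmax tie-breaking.
sort_classes <- function(classes) {
  mc <- movement_classes()
  known <- mc$label[mc$label %in% classes]
  c(known, sort(setdiff(classes, known)))
}

# glmnet multinomial ridge; C maps to lambda = 1 / (n * C) (larger C =
# weaker regularization, as in the usual C parameterization).
lambda_of <- function(c_val, n) 1 / (n * c_val)

# On separable data ridge coefficients diverge as lambda -> 0 and glmnet
# truncates the path with a convergence warning; this is expected for the
# largest C values and harmless (ties break toward small C). Muffle only
# that specific warning.
quiet_glmnet <- function(expr) {
  withCallingHandlers(
    expr,
    warning = function(w) {
      if (grepl("Convergence for .* lambda value not reached", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

cv_accuracy_lr <- function(z, y, fold, grid) {
  res <- matrix(NA_real_, length(grid$c_grid), max(fold))
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    lam <- lambda_of(grid$c_grid, sum(tr)) # decreasing in C; sort for glmnet
    fit <- quiet_glmnet(glmnet::glmnet(
      z[tr, , drop = FALSE], factor(y[tr]), family = "multinomial",
      alpha = 0, lambda = sort(lam, decreasing = TRUE), standardize = FALSE
    ))
    pred <- predict(fit, z[!tr, , drop = FALSE], s = lam, type = "class")
    res[, f] <- colMeans(pred == y[!tr])
  }
  tibble::tibble(c = grid$c_grid, accuracy = rowMeans(res))
}

fit_lr_full <- function(z, y, classes, c_val) {
  lam <- lambda_of(c_val, length(y))
  # glmnet's coordinate descent needs a warm-started descending path from
  # heavy regularization down to the target lambda to converge there
  lam_hi <- max(lambda_of(1e-4, length(y)), lam * 1e4)
  path <- exp(seq(log(lam_hi), log(lam), length.out = 30))
  path <- sort(unique(path), decreasing = TRUE)
  fit <- quiet_glmnet(glmnet::glmnet(
    z, factor(y, levels = classes), family = "multinomial",
    alpha = 0, lambda = path, standardize = FALSE
  ))
  cf <- predict(fit, s = lam, type = "coefficients")
  # -> (n_features + 1) x n_classes coefficient matrix, intercept first
  do.call(cbind, lapply(cf, function(m) as.matrix(m)[, 1]))
}

cv_accuracy_svm <- function(z, y, fold, grid) {
  combos <- expand.grid(c = grid$c_grid, gamma = grid$gamma_grid)
  acc <- matrix(NA_real_, nrow(combos), max(fold))
  yf <- factor(y)
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    for (i in seq_len(nrow(combos))) {
      fit <- e1071::svm(
        x = z[tr, , drop = FALSE], y = yf[tr], kernel = "radial",
        cost = combos$c[i], gamma = combos$gamma[i], scale = FALSE
      )
      pred <- predict(fit, z[!tr, , drop = FALSE])
      acc[i, f] <- mean(pred == y[!tr])
    }
  }
  tibble::as_tibble(cbind(combos, accuracy = rowMeans(acc)))
}

pick_best <- function(cv, hyper_cols) {
  ord <- do.call(order, c(list(-cv$accuracy), lapply(hyper_cols, function(h) cv[[h]])))
  as.list(cv[ord[1], ])
}

#' Class probabilities from a trained model
#'
#' Rows sum to 1; the hard prediction is the arg-max with ties broken toward
#' the lowest class index (Rest first). For the SVM, probabilities are a
#' softmax over per-class sums of signed pairwise decision values (a
#' deterministic surrogate for Platt scaling; see the methods vignette).
#'
#' @param model An `emg_model`.
#' @param x Samples x features matrix on the model's input scale.
#' @return Matrix samples x classes of probabilities (columns named by
#'   class, in the model's class order).
#' @export
predict_proba <- function(model, x) UseMethod("predict_proba")

#' @export
predict_proba.emg_lr <- function(model, x) {
  z <- pca_project(model$pca, check_dim(model, x))
  scores <- cbind(1, z) %*% model$coef
  softmax_rows(scores, model$classes)
}

#' @export
predict_proba.emg_svm <- function(model, x) {
  z <- pca_project(model$pca, check_dim(model, x))
  dv <- attr(predict(model$svm, z, decision.values = TRUE), "decision.values")
  classes <- model$classes
  scores <- matrix(0, nrow(z), length(classes), dimnames = list(NULL, classes))
  pair_names <- colnames(dv)
  for (j in seq_along(pair_names)) {
    pair <- strsplit(pair_names[j], "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, j]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, j]
  }
  softmax_rows(scores / (length(classes) - 1), classes)
}

check_dim <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$pca) && ncol(x) != length(model$pca$mean)) {
    abort(sprintf(
      "Feature dimension %d does not match the model's %d.",
      ncol(x), length(model$pca$mean)
    ))
  }
  x
}

softmax_rows <- function(scores, classes) {
  scores <- scores - apply(scores, 1, max)
  e <- exp(scores)
  p <- e / rowSums(e)
  colnames(p) <- classes
  p
}

#' Hard class labels from probabilities
#'
#' @param proba Samples x classes probability matrix (named columns).
#' @return Character labels; exact ties resolve to the earliest column
#'   (Rest first in the canonical order).
#' @export
proba_to_class <- function(proba) {
  colnames(proba)[max.col(proba, ties.method = "first")]
}

#' Predict hard labels
#'
#' @param object An `emg_model`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @export
predict.emg_model <- function(object, newdata, ...) {
  proba_to_class(predict_proba(object, newdata))
}

#' @export
print.emg_model <- function(x, ...) {
  hp <- paste(names(x$hyper), signif(unlist(x$hyper), 3), sep = "=", collapse = ", ")
  cat(sprintf(
    "<emg_model %s: %d classes%s%s>\n", x$kind, length(x$classes),
    if (!is.null(x$pca)) sprintf(", %d PCs", x$pca$n_components) else "",
    if (nzchar(hp)) paste0(", ", hp) else ""
  ))
  invisible(x)
}

#' @export
glance.emg_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_classes = length(x$classes),
    n_components = x$pca$n_components %||% NA_integer_,
    best_cv_accuracy = if (!is.null(x$cv)) max(x$cv$accuracy) else NA_real_
  )
}

#' @export
tidy.emg_model <- function(x, ...) {
  if (!is.null(x$cv)) return(tibble::as_tibble(x$cv))
  tibble::tibble(kind = x$kind)
}
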