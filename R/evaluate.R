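#' Bin accuracy
#'
#' Fraction of 100 ms time bins whose predicted class equals ground truth.
#'
#' @param pred,truth Equal-length label vectors.
#' @return A fraction in `[0, 1]`.
#' @export
bin_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("Prediction/truth length mismatch.")
  if (!length(pred)) abort("Empty label streams.")
  mean(pred == truth)
}

#' Majority-class chance level
#'
#' The accuracy of a naive decoder that always predicts the most frequent
#' class (Rest, for the canonical cue structure) -- the highest chance
#' accuracy any label-independent strategy can reach.
#'
#' @param truth Label vector.
#' @return Fraction of labels belonging to the majority class.
#' @export
chance_level <- function(truth) {
  if (!length(truth)) abort("Empty labels.")
  max(table(truth)) / length(truth)
}

#' Per-cue success rate
#'
#' A cue is successful if at least 1 s of *continuously* correct decoding
#' (10 consecutive 100 ms bins, strictly inside the cue interval) of the
#' cued class occurs. The rate is successes / cues; rest segments are
#' excluded by default (set `include_rest = TRUE` to score them too).
#'
#' @param pred Predicted label per bin over the record.
#' @param schedule Cue schedule defining the (possibly shifted) cue
#'   intervals.
#' @param bin_width_s Bin width (default 0.1 s).
#' @param min_run_s Required continuous duration (default 1 s).
#' @param include_rest Score rest segments as cues too (default `FALSE`).
#' @return A list with `rate`, and `per_class` (tibble: `label`,
#'   `successes`, `attempts`).
#' @export
success_rate <- function(pred, schedule, bin_width_s = 0.1, min_run_s = 1,
                         include_rest = FALSE) {
  validate_schedule(schedule)
  n_bins <- length(pred)
  if (n_bins * bin_width_s < schedule$onset_s[nrow(schedule)] - 1e-9) {
    abort("Predictions do not cover the schedule extent.")
  }
  need <- as.integer(round(min_run_s / bin_width_s))
  rows <- which(if (include_rest) rep(TRUE, nrow(schedule)) else schedule$label != "Rest")
  if (!length(rows)) abort("Schedule contains no cues to score.")
  res <- purrr::map(rows, function(r) {
    # bins strictly within the cue: bin b covers [(b-1)bw, b*bw)
    b0 <- as.integer(ceiling(schedule$onset_s[r] / bin_width_s - 1e-9)) + 1L
    b1 <- as.integer(floor(schedule$offset_s[r] / bin_width_s + 1e-9))
    b1 <- min(b1, n_bins)
    ok <- if (b1 >= b0) pred[b0:b1] == schedule$label[r] else logical(0)
    success <- FALSE
    if (length(ok)) {
      r_le <- rle(ok)
      success <- any(r_le$values & r_le$lengths >= need)
    }
    tibble::tibble(label = schedule$label[r], success = success)
  })
  res <- dplyr::bind_rows(res)
  per_class <- dplyr::summarise(
    dplyr::group_by(res, label),
    successes = sum(success), attempts = dplyr::n(), .groups = "drop"
  )
  list(rate = mean(res$success), per_class = per_class)
}

#' Confusion matrix of a label stream
#'
#' @param pred,truth Label vectors of equal length.
#' @param classes Class order for rows/columns (default: canonical order of
#'   the classes present).
#' @param normalize Row-normalize to per-true-class fractions.
#' @return A true x predicted matrix of counts (or row fractions).
#' @export
confusion <- function(pred, truth, classes = NULL, normalize = FALSE) {
  classes <- classes %||% sort_classes(unique(c(pred, truth)))
  bad <- setdiff(unique(c(pred, truth)), classes)
  if (length(bad)) abort(paste0("Labels outside the class set: ", paste(bad, collapse = ", ")))
  m <- table(
    factor(truth, levels = classes),
    factor(pred, levels = classes)
  )
  m <- unclass(m)
  names(dimnames(m)) <- c("truth", "predicted")
  if (normalize) {
    rs <- rowSums(m)
    m <- sweep(m, 1, pmax(rs, 1), `/`)
  }
  m
}

#' Movement-subset specification
#'
#' Decoding subsets of the full movement set: `binary_rest_move` collapses
#' all 12 movements into one Move class; `fixed_three` keeps Rest, Hand
#' Close and Hand Open; `top_k` keeps Rest plus the `k` movements with the
#' highest per-class accuracy. In every mode the rest bins are subsampled
#' from the rest cues directly preceding each retained movement so that Rest
#' makes up 50% of the dataset.
#'
#' @param mode One of `"binary_rest_move"`, `"fixed_three"`, `"top_k"`.
#' @param k Number of movements kept in `top_k` mode.
#' @param rest_fraction_target Target rest fraction (default 0.5).
#' @return A list of class `subset_spec`.
#' @export
subset_spec <- function(mode = c("binary_rest_move", "fixed_three", "top_k"),
                        k = 2L, rest_fraction_target = 0.5) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode, k = as.integer(k), rest_fraction_target = rest_fraction_target),
    class = "subset_spec"
  )
}

#' Build a movement-subset dataset
#'
#' Applies a [subset_spec()] to a center-window dataset: retains (and in
#' binary mode relabels) movement samples, then fills Rest up to 50% of the
#' result using the bins of the rest cue immediately preceding each retained
#' movement cue, in temporal order.
#'
#' @param dataset An `emg_dataset` from [extract_center_windows()].
#' @param schedule The cue schedule the dataset was extracted under.
#' @param spec A [subset_spec()].
#' @param per_class_accuracy Named accuracy per movement (required for
#'   `top_k`); compute it on training data, never on the test set.
#' @return A new `emg_dataset` with the subset's samples and labels.
#' @export
build_subset <- function(dataset, schedule, spec, per_class_accuracy = NULL) {
  stopifnot(inherits(dataset, "emg_dataset"), inherits(spec, "subset_spec"))
  info <- dataset$info
  movements <- unique(info$label[info$label != "Rest"])
  keep <- switch(spec$mode,
    binary_rest_move = movements,
    fixed_three = intersect(c("Hand Close", "Hand Open"), movements),
    top_k = {
      if (is.null(per_class_accuracy)) {
        abort("`top_k` mode needs `per_class_accuracy`.")
      }
      acc <- per_class_accuracy[names(per_class_accuracy) %in% movements]
      if (spec$k > length(acc)) {
        abort(sprintf("k = %d exceeds the %d movements available.", spec$k, length(acc)))
      }
      names(sort(acc, decreasing = TRUE))[seq_len(spec$k)]
    }
  )
  if (!length(keep)) abort("No movements retained by the subset.")

  mv_rows <- which(info$label %in% keep)
  n_mv <- length(mv_rows)
  # rest cues directly preceding each retained movement segment
  mv_segs <- unique(info$segment[mv_rows])
  rest_segs <- vapply(mv_segs, function(s) {
    prev <- info$segment[info$label == "Rest" & info$segment < s]
    if (!length(prev)) NA_integer_ else max(prev)
  }, integer(1))
  rest_segs <- unique(rest_segs[!is.na(rest_segs)])
  rest_pool <- which(info$segment %in% rest_segs & info$label == "Rest")
  rest_pool <- rest_pool[order(info$bin[rest_pool])]
  n_rest <- round(n_mv * spec$rest_fraction_target / (1 - spec$rest_fraction_target))
  if (length(rest_pool) < n_rest) {
    abort(sprintf(
      "Only %d rest samples available from preceding rest cues; need %d for a %.0f%% rest fraction.",
      length(rest_pool), n_rest, 100 * spec$rest_fraction_target
    ))
  }
  rest_rows <- rest_pool[seq_len(n_rest)]

  rows <- sort(c(mv_rows, rest_rows))
  y <- info$label[rows]
  if (spec$mode == "binary_rest_move") {
    y[y != "Rest"] <- "Move"
  }
  structure(
    list(
      x = dataset$x[rows, , drop = FALSE],
      y = y,
      info = dplyr::mutate(info[rows, ], label = y)
    ),
    class = "emg_dataset"
  )
}

#' Full evaluation report
#'
#' Bundles the pipeline's performance metrics for a predicted label stream:
#' bin accuracy, majority-class chance level, the confusion matrix,
#' per-class accuracy, and (when a schedule is supplied) the per-cue
#' success rate.
#'
#' @param pred Predicted labels per bin.
#' @param truth Ground-truth labels per bin.
#' @param schedule Optional cue schedule for success-rate scoring.
#' @param classes Optional class order.
#' @param include_rest Passed to [success_rate()].
#' @return An object of class `emg_eval`.
#' @export
eval_report <- function(pred, truth, schedule = NULL, classes = NULL,
                        include_rest = FALSE) {
  classes <- classes %||% sort_classes(unique(c(pred, truth)))
  cm <- confusion(pred, truth, classes)
  per_class <- diag(cm) / pmax(rowSums(cm), 1)
  sr <- if (!is.null(schedule)) {
    success_rate(pred, schedule, include_rest = include_rest)
  }
  structure(
    list(
      bin_accuracy = bin_accuracy(pred, truth),
      chance_level = chance_level(truth),
      confusion = cm,
      per_class_accuracy = per_class,
      success = sr,
      n_bins = length(pred)
    ),
    class = "emg_eval"
  )
}

#' @export
print.emg_eval <- function(x, ...) {
  cat(sprintf(
    "<emg_eval: accuracy %.1f%% (chance %.1f%%) over %d bins%s>\n",
    100 * x$bin_accuracy, 100 * x$chance_level, x$n_bins,
    if (!is.null(x$success)) sprintf(", success rate %.1f%%", 100 * x$success$rate) else ""
  ))
  invisible(x)
}

#' @export
tidy.emg_eval <- function(x, ...) {
  tibble::tibble(
    class = names(x$per_class_accuracy),
    accuracy = unname(x$per_class_accuracy),
    n_bins = unname(rowSums(x$confusion))
  )
}

#' @export
glance.emg_eval <- function(x, ...) {
  tibble::tibble(
    bin_accuracy = x$bin_accuracy,
    chance_level = x$chance_level,
    success_rate = if (!is.null(x$success)) x$success$rate else NA_real_,
    n_bins = x$n_bins
  )
}
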