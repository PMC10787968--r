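#' Binned RMS features from a recording
#'
#' The amplitude feature underlying the whole pipeline: per channel, the
#' root-mean-square over consecutive non-overlapping 100 ms windows. At
#' 3 kHz each bin spans 300 samples; a trailing partial bin is discarded.
#'
#' @param recording An [emg_recording][simulate_emg] (normally filtered with
#'   [bandpass_notch()] first).
#' @param bin_width_s Bin width in seconds (default 0.1).
#' @return An object of class `emg_features`: list with `rms` (bins x
#'   channels matrix), `bin_width_s`, `sampling_rate`, `schedule`,
#'   `labels` (per-bin label from the schedule), plus slots filled by later
#'   stages (`norm_stats`, `stacked`, `valid`).
#' @export
rms_bins <- function(recording, bin_width_s = 0.1) {
  stopifnot(inherits(recording, "emg_recording"))
  n_t <- ncol(recording$samples)
  width <- as.integer(round(bin_width_s * recording$sampling_rate))
  if (width < 1L || n_t < width) abort("Recording shorter than one bin.")
  rms <- bin_rms_cpp(t(recording$samples), width)
  labels <- if (!is.null(recording$schedule)) {
    schedule_bin_labels(recording$schedule, nrow(rms), bin_width_s)
  }
  structure(
    list(
      rms = rms, bin_width_s = bin_width_s,
      sampling_rate = recording$sampling_rate,
      schedule = recording$schedule, labels = labels,
      normalized = FALSE, norm_stats = NULL, stacked = NULL, valid = NULL,
      k = NULL
    ),
    class = "emg_features"
  )
}

#' @export
print.emg_features <- function(x, ...) {
  cat(sprintf(
    "<emg_features: %d bins x %d channels (%g s bins)%s%s>\n",
    nrow(x$rms), ncol(x$rms), x$bin_width_s,
    if (isTRUE(x$normalized)) ", normalized" else "",
    if (!is.null(x$stacked)) sprintf(", stacked k=%d", x$k) else ""
  ))
  invisible(x)
}

#' Tidy view of binned RMS features
#'
#' @param x An `emg_features` object.
#' @param ... Unused.
#' @return A long tibble with `bin`, `time_s`, `label`, `channel`, `rms`.
#' @export
tidy.emg_features <- function(x, ...) {
  nb <- nrow(x$rms)
  tibble::tibble(
    bin = rep(seq_len(nb), ncol(x$rms)),
    time_s = rep((seq_len(nb) - 1) * x$bin_width_s, ncol(x$rms)),
    label = rep(x$labels %||% NA_character_, ncol(x$rms)),
    channel = rep(seq_len(ncol(x$rms)), each = nb),
    rms = as.vector(x$rms)
  )
}

#' Fit / apply per-feature standardization
#'
#' Training features are standardized to mean 0, variance 1 per feature;
#' test (and online) features reuse the training mean and variance so the
#' model sees one consistent scale. Variances are floored at `1e-12` so
#' constant features map to 0 rather than NaN.
#'
#' @param features An `emg_features` object or a numeric matrix
#'   (rows = observations).
#' @return `fit_normalizer()`: a `norm_stats` list with `mean`, `sd`.
#'   `apply_normalizer()`: the input with standardized values (and
#'   `norm_stats` recorded, for `emg_features` input).
#' @export
fit_normalizer <- function(features) {
  m <- if (inherits(features, "emg_features")) features$rms else as.matrix(features)
  if (is.null(dim(m)) || nrow(m) == 0L) abort("Empty training features.")
  mu <- colMeans(m)
  v <- apply(m, 2, var)
  # population variance to make "apply to own training set" give exactly var 1
  v <- v * (nrow(m) - 1) / nrow(m)
  structure(list(mean = mu, sd = sqrt(pmax(v, 1e-12))), class = "norm_stats")
}

#' @rdname fit_normalizer
#' @param norm_stats A fitted `norm_stats` object.
#' @export
apply_normalizer <- function(features, norm_stats) {
  stopifnot(inherits(norm_stats, "norm_stats"))
  if (inherits(features, "emg_features")) {
    features$rms <- sweep(
      sweep(features$rms, 2, norm_stats$mean, `-`),
      2, norm_stats$sd, `/`
    )
    features$normalized <- TRUE
    features$norm_stats <- norm_stats
    features
  } else {
    m <- as.matrix(features)
    sweep(sweep(m, 2, norm_stats$mean, `-`), 2, norm_stats$sd, `/`)
  }
}

#' Stack temporal context onto each bin
#'
#' Each prediction uses the current 100 ms bin and the `k - 1` preceding
#' bins (default `k = 4`, i.e. 400 ms of RMS context), concatenated oldest
#' first into one row. Bins with incomplete history within the record are
#' flagged invalid (and zero-filled).
#'
#' @param features An `emg_features` object (normalize first; models expect
#'   standardized inputs).
#' @param k Number of bins per prediction sample (default 4).
#' @return The `emg_features` object with `stacked` (bins x channels*k)
#'   and `valid` filled in.
#' @export
stack_history <- function(features, k = 4L) {
  stopifnot(inherits(features, "emg_features"))
  if (k < 1L) abort("`k` must be >= 1.")
  rms <- features$rms
  nb <- nrow(rms)
  nc <- ncol(rms)
  stacked <- matrix(0, nb, nc * k)
  for (j in seq_len(k)) {
    lagj <- k - j # column block j holds bin t - (k - j)
    rows <- (1L + lagj):nb
    stacked[rows, ((j - 1L) * nc + 1L):(j * nc)] <- rms[rows - lagj, , drop = FALSE]
  }
  features$stacked <- stacked
  features$valid <- seq_len(nb) >= k
  features$k <- as.integer(k)
  features
}

#' Center-window dataset for classifier training
#'
#' Extracts, for every cue and rest segment, the bins lying wholly inside a
#' window of `width_s` seconds centered on the segment (2.5 s for stroke
#' recordings, 1.5 s for able-bodied), then drops the first 3 bins of each
#' window since their stacked context reaches outside the window. With
#' 100 ms bins this yields `round(width_s / 0.1) - 3` samples per segment
#' (22 for 2.5 s, 12 for 1.5 s).
#'
#' @param features A stacked, normalized `emg_features` object.
#' @param schedule Cue schedule supplying segment labels (default: the one
#'   attached to the features; pass a shifted schedule to use aligned
#'   labels).
#' @param width_s Center-window width in seconds.
#' @param drop_bins Leading bins dropped per window (default 3).
#' @return An object of class `emg_dataset`: list with `x` (samples x
#'   features matrix), `y` (character labels), and `info` (tibble: `segment`,
#'   `label`, `bin`). Segments shorter than `width_s` are skipped with a
#'   warning.
#' @export
extract_center_windows <- function(features, schedule = NULL, width_s = 2.5,
                                   drop_bins = 3L) {
  stopifnot(inherits(features, "emg_features"))
  if (is.null(features$stacked)) abort("Call stack_history() before extracting windows.")
  schedule <- schedule %||% features$schedule
  if (is.null(schedule)) abort("No schedule available for labeling.")
  bw <- features$bin_width_s
  nb <- nrow(features$rms)
  rows <- list()
  for (s in seq_len(nrow(schedule))) {
    on <- schedule$onset_s[s]
    off <- schedule$offset_s[s]
    if (off - on < width_s - 1e-9) {
      warn(sprintf(
        "Segment %d (%s) of %.2f s is shorter than the %.2f s window; skipped.",
        s, schedule$label[s], off - on, width_s
      ))
      next
    }
    mid <- (on + off) / 2
    w0 <- mid - width_s / 2
    w1 <- mid + width_s / 2
    # bins whose centers fall in [w0, w1): exactly round(width_s/bw) bins
    # for any window position, since the window spans that many bin widths
    b0 <- as.integer(ceiling(w0 / bw + 0.5 - 1e-9))
    b1 <- as.integer(ceiling(w1 / bw + 0.5 - 1e-9)) - 1L
    b0 <- b0 + drop_bins
    if (b1 < b0) next
    b0 <- max(b0, 1L)
    b1 <- min(b1, nb)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      segment = s, label = schedule$label[s], bin = b0:b1
    )
  }
  info <- dplyr::bind_rows(rows)
  structure(
    list(
      x = features$stacked[info$bin, , drop = FALSE],
      y = info$label,
      info = info
    ),
    class = "emg_dataset"
  )
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf(
    "<emg_dataset: %d samples x %d features, %d classes>\n",
    nrow(x$x), ncol(x$x), length(unique(x$y))
  ))
  invisible(x)
}

#' @export
tidy.emg_dataset <- function(x, ...) {
  dplyr::mutate(x$info, row = dplyr::row_number())
}
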