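#' Across-channel summary signal for cue alignment
#'
#' The alignment objective works on one per-bin series: the mean across
#' channels of the normalized RMS. Averaging after standardization weights
#' every channel equally regardless of its baseline amplitude.
#'
#' @param features A normalized `emg_features` object (or any bins x
#'   channels matrix).
#' @return Numeric vector, one value per 100 ms bin.
#' @export
summarize_activity <- function(features) {
  m <- if (inherits(features, "emg_features")) features$rms else as.matrix(features)
  if (is.null(dim(m)) || nrow(m) == 0L) abort("Empty features.")
  rowMeans(m)
}

# Segment-wise SSR of a series given boundary bins.
# bounds: start bin (1-based) of segments 2..S; prefix sums give O(1) SSR of
# any [i, j] slice: ssr = sum(x^2) - sum(x)^2 / n.
seg_ssr <- function(cs, cs2, i, j) {
  s <- cs[j + 1L] - cs[i]
  s2 <- cs2[j + 1L] - cs2[i]
  s2 - s * s / (j - i + 1L)
}

total_ssr <- function(cs, cs2, starts, n_bins) {
  ends <- c(starts[-1] - 1L, n_bins)
  sum(vapply(seq_along(starts), function(k) {
    seg_ssr(cs, cs2, starts[k], ends[k])
  }, numeric(1)))
}

#' Dynamically align cue boundaries to EMG activity
#'
#' The cue-label stream assumes the subject moves exactly when cued; after
#' stroke, EMG onset lags the cue by a variable reaction latency. This
#' procedure moves each boundary between consecutive segments to minimize
#' the sum over segments of squared residuals of the summary signal around
#' its segment mean -- a piecewise-constant fit with movable breakpoints.
#' Boundaries move on the 100 ms bin grid by coordinate descent (each
#' boundary searched exhaustively within `max_shift_s` of its original
#' position, sweeping boundaries in temporal order until no boundary moves
#' or `max_sweeps` sweeps). Shifts are capped at `max_shift_s` (2 s), the
#' segment order is preserved, and every segment keeps at least one bin.
#'
#' @param summary Per-bin summary signal (see [summarize_activity()]).
#' @param schedule The intended cue schedule.
#' @param max_shift_s Maximum absolute boundary shift in seconds (default 2).
#' @param forward_only If `TRUE`, boundaries may only move later in time
#'   (beyond the intended cue time); default allows both directions.
#' @param max_sweeps Sweep limit (default 50).
#' @param bin_width_s Bin width of the summary signal.
#' @return An object of class `shift_result`: list with `shifted_schedule`,
#'   `per_boundary_shift_s`, `total_ssr`, `initial_ssr`, `iterations`.
#' @export
dynamic_shift <- function(summary, schedule, max_shift_s = 2,
                          forward_only = FALSE, max_sweeps = 50L,
                          bin_width_s = 0.1) {
  if (max_shift_s < 0) abort("`max_shift_s` must be >= 0.")
  validate_schedule(schedule)
  if (nrow(schedule) < 2L) abort("Need at least 2 segments to align.")
  n_bins <- length(summary)
  if (n_bins < nrow(schedule)) abort("Summary shorter than the schedule.")
  if (n_bins * bin_width_s < schedule_duration(schedule) - 0.5) {
    abort("Summary does not cover the schedule extent.")
  }

  cs <- c(0, cumsum(summary))
  cs2 <- c(0, cumsum(summary^2))
  ssr_of <- function(i, j) seg_ssr(cs, cs2, i, j)

  # segment start bins (1-based); boundary k = start of segment k+1
  orig <- pmin(pmax(as.integer(round(schedule$onset_s / bin_width_s)) + 1L, 1L), n_bins)
  starts <- orig
  ends_of <- function(st) c(st[-1] - 1L, n_bins)
  max_move <- as.integer(round(max_shift_s / bin_width_s))

  n_seg <- length(starts)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    moved <- FALSE
    for (k in 2:n_seg) {
      lo <- starts[k - 1L] + 1L # left segment keeps >= 1 bin
      hi <- (if (k < n_seg) starts[k + 1L] else n_bins + 1L) - 1L # right keeps >= 1
      lo <- max(lo, orig[k] - max_move)
      hi <- min(hi, orig[k] + max_move)
      if (forward_only) lo <- max(lo, orig[k])
      if (lo > hi) next
      cand <- lo:hi
      left0 <- starts[k - 1L]
      right1 <- if (k < n_seg) starts[k + 1L] - 1L else n_bins
      obj <- vapply(cand, function(b) {
        ssr_of(left0, b - 1L) + ssr_of(b, right1)
      }, numeric(1))
      # ties broken toward zero shift, then toward the earlier bin
      pick <- order(obj, abs(cand - orig[k]), cand)[1L]
      if (cand[pick] != starts[k]) {
        starts[k] <- cand[pick]
        moved <- TRUE
      }
    }
    if (!moved || iterations >= max_sweeps) break
  }

  shifts <- (starts - orig) * bin_width_s
  out <- schedule
  new_onsets <- schedule$onset_s
  new_onsets[-1] <- (starts[-1] - 1L) * bin_width_s
  out$onset_s <- new_onsets
  out$offset_s <- c(new_onsets[-1], schedule$offset_s[n_seg])
  attr(out, "shifts_s") <- shifts[-1]
  structure(
    list(
      shifted_schedule = out,
      per_boundary_shift_s = shifts[-1],
      total_ssr = total_ssr(cs, cs2, starts, n_bins),
      initial_ssr = total_ssr(cs, cs2, orig, n_bins),
      iterations = iterations
    ),
    class = "shift_result"
  )
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf(
    "<shift_result: %d boundaries, mean |shift| %.0f ms, SSR %.4g -> %.4g, %d sweeps>\n",
    length(x$per_boundary_shift_s), 1000 * mean(abs(x$per_boundary_shift_s)),
    x$initial_ssr, x$total_ssr, x$iterations
  ))
  invisible(x)
}

#' @export
tidy.shift_result <- function(x, ...) {
  tibble::tibble(
    boundary = seq_along(x$per_boundary_shift_s),
    shift_s = x$per_boundary_shift_s
  )
}

#' @export
glance.shift_result <- function(x, ...) {
  tibble::tibble(
    n_boundaries = length(x$per_boundary_shift_s),
    mean_abs_shift_s = mean(abs(x$per_boundary_shift_s)),
    initial_ssr = x$initial_ssr,
    total_ssr = x$total_ssr,
    iterations = x$iterations
  )
}
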