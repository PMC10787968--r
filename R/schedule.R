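#' Build a cue schedule for a recording block
#'
#' A recording block opens with an 8 s lead-in rest, then alternates movement
#' cues with interleaved rest periods. Cue/rest durations are drawn uniformly
#' from the profile's range: 4-6 s for the `"stroke"` profile, 2-3 s for the
#' `"able"` (able-bodied) profile. Movement order is a random permutation of
#' `reps_per_movement` repetitions of each requested movement.
#'
#' @param movements Character vector: subset of the 12 non-rest classes in
#'   [movement_classes()].
#' @param reps_per_movement Repetitions of each movement in the block.
#' @param profile `"stroke"` or `"able"`; sets the cue/rest duration range.
#' @param seed RNG seed; the same seed reproduces the schedule exactly.
#' @param lead_in_s Duration of the opening rest (default 8 s).
#' @return A tibble of class `cue_schedule` with columns `segment`, `label`,
#'   `onset_s`, `offset_s`; segments tile time with no gaps. Attributes:
#'   `profile`, `lead_in_s`.
#' @export
#' @examples
#' sched <- make_cue_schedule("Hand Close", 10, "stroke", seed = 1)
#' nrow(sched) # 21: lead-in + 10 x (cue, rest)
make_cue_schedule <- function(movements, reps_per_movement = 1L,
                              profile = c("stroke", "able"), seed = NULL,
                              lead_in_s = 8) {
  profile <- match.arg(profile)
  mc <- movement_classes()
  valid <- mc$label[mc$index > 0]
  if (length(movements) == 1L && identical(movements, "all")) movements <- valid
  if (length(movements) == 0L) abort("`movements` must be non-empty.")
  bad <- setdiff(movements, valid)
  if (length(bad)) {
    abort(paste0("Unknown movement(s): ", paste(bad, collapse = ", ")))
  }
  if (reps_per_movement < 1L) abort("`reps_per_movement` must be >= 1.")
  rng <- switch(profile, stroke = c(4, 6), able = c(2, 3))
  with_rng(seed, {
    cues <- sample(rep(movements, each = reps_per_movement))
    n_cue <- length(cues)
    durs <- runif(2L * n_cue, rng[1], rng[2])
    labels <- c("Rest", rbind(cues, rep("Rest", n_cue)))
    lens <- c(lead_in_s, durs)
    offs <- cumsum(lens)
    new_cue_schedule(
      tibble::tibble(
        segment = seq_along(labels),
        label = labels,
        onset_s = c(0, offs[-length(offs)]),
        offset_s = offs
      ),
      profile = profile, lead_in_s = lead_in_s
    )
  })
}

new_cue_schedule <- function(df, profile = "stroke", lead_in_s = df$offset_s[1]) {
  structure(
    df,
    profile = profile,
    lead_in_s = lead_in_s,
    class = c("cue_schedule", setdiff(class(tibble::as_tibble(df)), "cue_schedule"))
  )
}

validate_schedule <- function(schedule) {
  if (nrow(schedule) < 1L) abort("Schedule has no segments.")
  if (any(schedule$offset_s <= schedule$onset_s)) {
    abort("Schedule has a non-positive-duration segment.")
  }
  gaps <- schedule$onset_s[-1] - schedule$offset_s[-nrow(schedule)]
  if (any(abs(gaps) > 1e-9)) {
    abort("Schedule segments must tile time with no gaps or overlaps.")
  }
  invisible(schedule)
}

schedule_duration <- function(schedule) {
  schedule$offset_s[nrow(schedule)]
}

#' Labels of 100 ms bins under a schedule
#'
#' A bin belongs to the segment containing its start time (half-open bins
#' `[t, t + bin_width)`).
#'
#' @param schedule A [cue_schedule][make_cue_schedule].
#' @param n_bins Number of bins to label.
#' @param bin_width_s Bin width in seconds (default 0.1).
#' @return Character vector of length `n_bins`.
#' @export
schedule_bin_labels <- function(schedule, n_bins, bin_width_s = 0.1) {
  starts <- (seq_len(n_bins) - 1L) * bin_width_s
  idx <- findInterval(starts + 1e-9, schedule$onset_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  schedule$label[idx]
}

#' Shift every interior cue boundary by a fixed amount
#'
#' The classic static correction for subject reaction time: every boundary
#' except the record start and end is translated by `delta_s` (e.g. 0.3 s
#' online, 0.8 s as an offline baseline) and clipped to the record extent.
#'
#' @param schedule A [cue_schedule][make_cue_schedule].
#' @param delta_s Signed shift in seconds.
#' @return A shifted `cue_schedule` with identical labels.
#' @export
static_shift <- function(schedule, delta_s) {
  stopifnot_scalar_number(delta_s, "delta_s")
  validate_schedule(schedule)
  durs <- schedule$offset_s - schedule$onset_s
  if (abs(delta_s) >= min(durs)) {
    abort(sprintf(
      "Static shift of %g s would collapse a segment (min duration %g s).",
      delta_s, min(durs)
    ))
  }
  total <- schedule_duration(schedule)
  onset <- schedule$onset_s
  offset <- schedule$offset_s
  onset[-1] <- pmin(pmax(onset[-1] + delta_s, 0), total)
  offset[-length(offset)] <- pmin(pmax(offset[-length(offset)] + delta_s, 0), total)
  out <- schedule
  out$onset_s <- onset
  out$offset_s <- offset
  validate_schedule(out)
  out
}

#' Fraction of the label stream changed between two schedules
#'
#' Quantifies how much cue data an alignment procedure moved: the fraction of
#' 100 ms bins whose label differs between the original and shifted
#' schedules, and the mean absolute boundary displacement.
#'
#' @param original,shifted Two [cue_schedule][make_cue_schedule]s covering
#'   the same extent with the same segment labels.
#' @param bin_width_s Bin width for the relabel count (default 0.1 s).
#' @return A tibble with `fraction_changed`, `mean_abs_shift_s`,
#'   `n_boundaries`.
#' @export
shift_fraction <- function(original, shifted, bin_width_s = 0.1) {
  if (!near(schedule_duration(original), schedule_duration(shifted), 1e-6)) {
    abort("Schedules must cover the same extent.")
  }
  n_bins <- floor(schedule_duration(original) / bin_width_s + 1e-9)
  a <- schedule_bin_labels(original, n_bins, bin_width_s)
  b <- schedule_bin_labels(shifted, n_bins, bin_width_s)
  shifts <- shifted$onset_s[-1] - original$onset_s[-1]
  tibble::tibble(
    fraction_changed = mean(a != b),
    mean_abs_shift_s = mean(abs(shifts)),
    n_boundaries = length(shifts)
  )
}

#' Write / read a cue schedule as JSON
#'
#' Schedules serialize to `{"profile", "lead_in_s", "segments": [{"label",
#' "onset_s", "offset_s"}, ...]}`. Reading validates that segments tile time.
#'
#' @param schedule A cue schedule.
#' @param path File path.
#' @return `read_schedule()` returns a `cue_schedule`; `write_schedule()`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  obj <- list(
    profile = attr(schedule, "profile") %||% "stroke",
    lead_in_s = attr(schedule, "lead_in_s") %||% schedule$offset_s[1],
    shifts_s = attr(schedule, "shifts_s"),
    segments = purrr::pmap(
      list(schedule$label, schedule$onset_s, schedule$offset_s),
      function(l, on, off) list(label = l, onset_s = on, offset_s = off)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path)
  segs <- purrr::map(obj$segments, function(s) {
    tibble::tibble(
      label = s$label,
      onset_s = as.numeric(s$onset_s),
      offset_s = as.numeric(s$offset_s)
    )
  })
  df <- dplyr::bind_rows(segs)
  df <- tibble::add_column(df, segment = seq_len(nrow(df)), .before = 1)
  sched <- new_cue_schedule(df,
    profile = obj$profile %||% "stroke",
    lead_in_s = as.numeric(obj$lead_in_s %||% df$offset_s[1])
  )
  if (!is.null(obj$shifts_s)) {
    attr(sched, "shifts_s") <- as.numeric(unlist(obj$shifts_s))
  }
  validate_schedule(sched)
  sched
}
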