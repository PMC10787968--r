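#' Simulation parameters for synthetic sleeve recordings
#'
#' Controls the synthetic HD-EMG signal model. Movement activity is
#' band-limited (20-400 Hz) amplitude-modulated noise placed on the electrode
#' grid as a Gaussian spatial blob per movement; impairment de-localizes the
#' blobs (larger spatial spread). Each cue's EMG onset/offset lags the visual
#' cue by a per-boundary reaction latency, and 60 Hz mains interference plus
#' baseline noise are superimposed.
#'
#' @param sampling_rate Sampling rate in Hz (default 3000).
#' @param impairment Impairment level in `[0, 1]`; increases the spatial
#'   spread of movement activation patterns (0 = well-localized).
#' @param pattern_spread Spatial SD of each movement's activation blob in
#'   grid units. Default `1.2 + 2.4 * impairment`.
#' @param snr_db Movement-to-rest RMS ratio in dB at the blob center
#'   (default 15).
#' @param baseline_rms Baseline (rest) noise RMS per channel, in µV
#'   (default 10).
#' @param latency_range Uniform range (s) of the per-cue-boundary delay
#'   between cue onset/offset and EMG onset/offset. Default `c(0.2, 1.2)`,
#'   within the 2 s alignment bound. Use `c(0, 0)` for perfectly punctual
#'   activity.
#' @param amplitude_cv Per-cue log-normal amplitude variability (sdlog);
#'   models rep-to-rep effort differences. Default 0.15.
#' @param line_noise_amp Amplitude of the 60 Hz mains component, µV
#'   (default 2).
#' @param movement_scores Named integer vector (0-3) per movement: observed
#'   movement score controlling activity amplitude via scale factors
#'   `c(0, 0.33, 0.66, 1)`; unnamed movements default to 3 (normal).
#' @param seed RNG seed; identical parameters and seed reproduce the
#'   recording bit-for-bit.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(sampling_rate = 3000, impairment = 0,
                       pattern_spread = NULL, snr_db = 15, baseline_rms = 10,
                       latency_range = c(0.2, 1.2), amplitude_cv = 0.15,
                       line_noise_amp = 2,
                       movement_scores = NULL, seed = 1) {
  stopifnot_scalar_number(sampling_rate, "sampling_rate")
  stopifnot_scalar_number(snr_db, "snr_db")
  stopifnot_scalar_number(impairment, "impairment")
  if (impairment < 0 || impairment > 1) abort("`impairment` must be in [0, 1].")
  if (length(latency_range) != 2 || any(!is.finite(latency_range)) ||
      latency_range[1] > latency_range[2] || latency_range[1] < 0 ||
      latency_range[2] > 2) {
    abort("`latency_range` must be an ordered pair within [0, 2] s.")
  }
  if (is.null(pattern_spread)) pattern_spread <- 1.2 + 2.4 * impairment
  structure(
    list(
      sampling_rate = sampling_rate, impairment = impairment,
      pattern_spread = pattern_spread, snr_db = snr_db,
      baseline_rms = baseline_rms, latency_range = latency_range,
      amplitude_cv = amplitude_cv, line_noise_amp = line_noise_amp,
      movement_scores = movement_scores, seed = seed
    ),
    class = "sim_params"
  )
}

score_scale <- c(`0` = 0, `1` = 0.33, `2` = 0.66, `3` = 1)

# Deterministic blob center for a movement: hash the label onto the grid,
# constrained to the flexor or extensor sectors per the movement's
# musculature.
pattern_center <- function(label, layout) {
  mc <- movement_classes()
  side <- mc$side[match(label, mc$label)]
  n_rings <- attr(layout, "n_rings")
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  ring <- (h %% 1009L) %% n_rings
  sector_pool <- if (identical(side, "extensor")) 4:7 else 0:3
  sector <- sector_pool[((h %/% 7L) %% 4L) + 1L]
  c(ring = ring, sector = sector)
}

#' Per-movement channel-weight patterns
#'
#' Gaussian spatial blobs on the sleeve grid (circular distance around the
#' forearm, linear along it), peak weight 1 at the blob center. Centers are
#' placed deterministically from the movement label, flexion-type movements
#' over the flexor sectors and extension-type over the extensor sectors.
#'
#' @param movements Character vector of movement labels.
#' @param layout A [make_sleeve_layout()] layout.
#' @param spread Spatial SD in grid units.
#' @return A channels x movements matrix of weights in `[0, 1]`.
#' @export
movement_patterns <- function(movements, layout, spread) {
  n_sectors <- attr(layout, "n_sectors")
  w <- vapply(movements, function(m) {
    ctr <- pattern_center(m, layout)
    dr <- layout$ring - ctr[["ring"]]
    ds <- abs(layout$sector - ctr[["sector"]])
    ds <- pmin(ds, n_sectors - ds) # circular around the forearm
    exp(-(dr^2 + ds^2) / (2 * spread^2))
  }, numeric(nrow(layout)))
  colnames(w) <- movements
  w
}

#' Simulate a synthetic sleeve recording
#'
#' Generates a channels x time µV signal following a cue schedule: every
#' channel carries band-limited (20-400 Hz) baseline noise plus a 60 Hz
#' mains sinusoid; during a movement's *true* activity interval (the cue
#' interval delayed by per-boundary reaction latencies) additional
#' band-limited activity is added with per-channel RMS set by the movement's
#' spatial pattern, the target SNR, the movement's observed movement score,
#' and a per-cue amplitude factor. The drawn latencies, spatial patterns and
#' per-movement scores are attached as ground truth.
#'
#' @param schedule A [make_cue_schedule()] cue schedule.
#' @param layout A [make_sleeve_layout()] layout.
#' @param params A [sim_params()] object.
#' @return An object of class `emg_recording`: list with `samples`
#'   (channels x time matrix, µV), `sampling_rate`, `layout`, `schedule`,
#'   and `ground_truth` (list: `true_segments` cue schedule of actual
#'   activity, `latencies` tibble, `patterns` matrix,
#'   `movement_scores`).
#' @export
simulate_emg <- function(schedule, layout, params = sim_params()) {
  validate_schedule(schedule)
  if (!inherits(layout, "sleeve_layout")) abort("`layout` must be a sleeve_layout.")
  if (!inherits(params, "sim_params")) abort("`params` must come from sim_params().")
  fs <- params$sampling_rate
  n_ch <- attr(layout, "n_channels")
  duration <- schedule_duration(schedule)
  n_t <- as.integer(round(duration * fs))
  movements <- unique(schedule$label[schedule$label != "Rest"])
  scores <- setNames(rep(3L, length(movements)), movements)
  if (!is.null(params$movement_scores)) {
    known <- intersect(names(params$movement_scores), movements)
    scores[known] <- as.integer(params$movement_scores[known])
  }
  if (any(scores < 0 | scores > 3)) abort("movement scores must be in 0..3.")

  with_rng(params$seed, {
    patterns <- movement_patterns(movements, layout, params$pattern_spread)

    # per-boundary latencies for each movement cue (onset and offset delays)
    cue_rows <- which(schedule$label != "Rest")
    lat_on <- runif(length(cue_rows), params$latency_range[1], params$latency_range[2])
    lat_off <- runif(length(cue_rows), params$latency_range[1], params$latency_range[2])
    amp_fac <- exp(rnorm(length(cue_rows), 0, params$amplitude_cv))

    true_seg <- schedule
    true_seg$onset_s[cue_rows] <- schedule$onset_s[cue_rows] + lat_on
    true_seg$offset_s[cue_rows] <- schedule$offset_s[cue_rows] + lat_off
    # keep activity inside the record and ahead of the next cue
    nxt <- c(schedule$onset_s[cue_rows][-1], duration)
    true_seg$offset_s[cue_rows] <- pmin(true_seg$offset_s[cue_rows], nxt - 1e-3, duration)

    sos <- butter_bandpass_sos(20, 400, fs, 10)
    # white -> band-limited changes RMS by the impulse-response energy
    g_band <- sqrt(sum(sos_filter(sos, c(1, rep(0, as.integer(2 * fs))))$y^2))

    act_rms <- params$baseline_rms * 10^(params$snr_db / 20)
    t_idx <- seq_len(n_t)
    # envelope construction is per-channel cheap: build per-cue sample spans once
    spans <- lapply(seq_along(cue_rows), function(i) {
      r <- cue_rows[i]
      i0 <- max(1L, as.integer(floor(true_seg$onset_s[r] * fs)) + 1L)
      i1 <- min(n_t, as.integer(floor(true_seg$offset_s[r] * fs)))
      if (i1 < i0) integer(0) else i0:i1
    })
    cue_amp <- vapply(seq_along(cue_rows), function(i) {
      m <- schedule$label[cue_rows[i]]
      act_rms * score_scale[[as.character(scores[[m]])]] * amp_fac[i]
    }, numeric(1))

    line_phase <- runif(n_ch, 0, 2 * pi)
    line_arg <- 2 * pi * 60 * (t_idx - 1) / fs

    samples <- matrix(0, n_ch, n_t)
    env <- numeric(n_t)
    for (ch in seq_len(n_ch)) {
      env[] <- params$baseline_rms
      for (i in seq_along(cue_rows)) {
        sp <- spans[[i]]
        if (!length(sp)) next
        m <- schedule$label[cue_rows[i]]
        a <- cue_amp[i] * patterns[ch, m]
        env[sp] <- sqrt(params$baseline_rms^2 + a^2)
      }
      x <- rnorm(n_t) * (env / g_band)
      samples[ch, ] <- sos_filter(sos, x)$y +
        params$line_noise_amp * sin(line_arg + line_phase[ch])
    }

    structure(
      list(
        samples = samples,
        sampling_rate = fs,
        layout = layout,
        schedule = schedule,
        filtered = FALSE,
        ground_truth = list(
          true_segments = true_seg,
          latencies = tibble::tibble(
            segment = cue_rows,
            label = schedule$label[cue_rows],
            onset_delay_s = lat_on,
            offset_delay_s = lat_off,
            amplitude_factor = amp_fac
          ),
          patterns = patterns,
          movement_scores = scores
        )
      ),
      class = "emg_recording"
    )
  })
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording: %d channels x %d samples (%.1f s at %g Hz), %d cue segments%s>\n",
    nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$sampling_rate,
    x$sampling_rate, nrow(x$schedule),
    if (isTRUE(x$filtered)) ", filtered" else ""
  ))
  invisible(x)
}

#' Ground-truth activity labels per 100 ms bin
#'
#' Labels each bin by the movement whose *true* (latency-delayed) activity
#' interval contains the bin start, falling back to Rest. This is the
#' reference stream that cue-alignment quality is judged against.
#'
#' @param recording A simulated [emg_recording][simulate_emg] with ground truth.
#' @param n_bins Number of bins (default: full record).
#' @param bin_width_s Bin width, s.
#' @return Character vector of labels.
#' @export
true_bin_labels <- function(recording, n_bins = NULL, bin_width_s = 0.1) {
  gt <- recording$ground_truth
  if (is.null(gt)) abort("Recording carries no ground truth.")
  if (is.null(n_bins)) {
    n_bins <- floor(ncol(recording$samples) / (recording$sampling_rate * bin_width_s))
  }
  labs <- rep("Rest", n_bins)
  starts <- (seq_len(n_bins) - 1L) * bin_width_s
  ts <- gt$true_segments
  for (r in which(ts$label != "Rest")) {
    inside <- starts >= ts$onset_s[r] - 1e-9 & starts < ts$offset_s[r] - 1e-9
    labs[inside] <- ts$label[r]
  }
  labs
}
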