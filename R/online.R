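#' Online decoding policy
#'
#' To avoid unintentional flipping between states, the online decoder only
#' changes its output when a candidate class (the arg-max of the model
#' probabilities) exceeds a probability threshold of 0.6 on
#' `stability_count` consecutive bins (default 2). The threshold applies to
#' every bin of the pending run -- the stricter reading, maximizing flip
#' resistance -- and any bin that breaks the run (different candidate or
#' sub-threshold probability) resets it.
#'
#' @param prob_threshold Probability that the candidate class must exceed
#'   (default 0.6).
#' @param stability_count Consecutive qualifying bins required to switch
#'   (default 2).
#' @param initial_state Starting decoded class (default `"Rest"`).
#' @return A list of class `online_policy`.
#' @export
online_policy <- function(prob_threshold = 0.6, stability_count = 2L,
                          initial_state = "Rest") {
  if (prob_threshold <= 0) abort("`prob_threshold` must be positive.")
  if (stability_count < 1L) abort("`stability_count` must be >= 1.")
  structure(
    list(
      prob_threshold = prob_threshold,
      stability_count = as.integer(stability_count),
      initial_state = initial_state
    ),
    class = "online_policy"
  )
}

#' Fresh decoder state
#'
#' @param policy An [online_policy()].
#' @return A list of class `decoder_state` with `current_class`,
#'   `pending_class`, `pending_run`, `bins_processed`. Plain data: it
#'   serializes and round-trips with `saveRDS()`/`readRDS()` or JSON.
#' @export
decoder_state <- function(policy = online_policy()) {
  structure(
    list(
      current_class = policy$initial_state,
      pending_class = NA_character_,
      pending_run = 0L,
      bins_processed = 0L
    ),
    class = "decoder_state"
  )
}

#' One debounced decoder step
#'
#' Feeds one bin's class probabilities through the stability policy. The
#' candidate is the arg-max (ties to the lowest class index); it counts
#' toward the pending run only if its probability exceeds the threshold and
#' it differs from the current class. When the pending run reaches
#' `stability_count`, the decoded class switches and the run resets.
#'
#' @param state A [decoder_state()].
#' @param proba Named probability vector for one bin (sums to 1).
#' @param policy The [online_policy()].
#' @return A list with `state` (updated) and `emitted` (the decoded class
#'   after this bin).
#' @export
decoder_step <- function(state, proba, policy = online_policy()) {
  if (is.null(names(proba)) || any(!is.finite(proba)) ||
      abs(sum(proba) - 1) > 1e-6) {
    abort("`proba` must be a named probability vector summing to 1.")
  }
  candidate <- names(proba)[which.max(proba)]
  p <- unname(proba[[candidate]])
  qualifies <- p > policy$prob_threshold && candidate != state$current_class
  if (qualifies) {
    if (identical(candidate, state$pending_class)) {
      state$pending_run <- state$pending_run + 1L
    } else {
      state$pending_class <- candidate
      state$pending_run <- 1L
    }
    if (state$pending_run >= policy$stability_count) {
      state$current_class <- candidate
      state$pending_class <- NA_character_
      state$pending_run <- 0L
    }
  } else {
    state$pending_class <- NA_character_
    state$pending_run <- 0L
  }
  state$bins_processed <- state$bins_processed + 1L
  list(state = state, emitted = state$current_class)
}

#' Replay a recording through the causal online pipeline
#'
#' Streams a recording frame by frame (100 ms) through the exact causal
#' pipeline an online decoder runs: filter continuation with carried state,
#' RMS of the frame, normalization with the *training* statistics, 4-bin
#' history stacking, model probabilities, and the debounced policy step.
#' Because the filter state is carried across frames, the decoded stream is
#' bit-identical to batch preprocessing followed by sequential policy steps.
#' Bins with incomplete history emit the current decoded state without
#' stepping the policy.
#'
#' @param recording A raw (unfiltered) [emg_recording][simulate_emg].
#' @param model A trained `emg_model`.
#' @param norm_stats Training [fit_normalizer()] statistics.
#' @param policy An [online_policy()].
#' @param filter Filter specification (default [filter_spec()]).
#' @param k History bins per prediction (default 4).
#' @param bin_width_s Frame width (default 0.1 s).
#' @return A tibble with one row per frame: `bin`, `time_s`, `class` (the
#'   debounced output), `raw_class` (arg-max before debouncing), `prob`
#'   (its probability).
#' @export
replay <- function(recording, model, norm_stats, policy = online_policy(),
                   filter = filter_spec(), k = 4L, bin_width_s = 0.1) {
  stopifnot(inherits(recording, "emg_recording"))
  n_ch <- nrow(recording$samples)
  expected_dim <- n_ch * k
  model_dim <- if (!is.null(model$pca)) length(model$pca$mean) else model$spec$input_dim
  if (model_dim != expected_dim) {
    abort(sprintf(
      "Model expects %d features but the stream provides %d channels x %d bins.",
      model_dim, n_ch, k
    ))
  }
  fs <- recording$sampling_rate
  width <- as.integer(round(bin_width_s * fs))
  n_bins <- ncol(recording$samples) %/% width
  sos <- design_sos(filter, fs)
  zi <- lapply(seq_len(n_ch), function(i) matrix(0, nrow(sos), 2))

  history <- matrix(NA_real_, k, n_ch)
  state <- decoder_state(policy)
  out <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    span <- ((b - 1L) * width + 1L):(b * width)
    frame_rms <- numeric(n_ch)
    for (ch in seq_len(n_ch)) {
      f <- sosfilt_cpp(sos, recording$samples[ch, span], zi[[ch]])
      zi[[ch]] <- f$zi
      frame_rms[ch] <- sqrt(mean(f$y^2))
    }
    normed <- (frame_rms - norm_stats$mean) / norm_stats$sd
    history <- rbind(history[-1, , drop = FALSE], normed)
    if (b < k) {
      out[[b]] <- tibble::tibble(
        bin = b, time_s = (b - 1) * bin_width_s,
        class = state$current_class, raw_class = NA_character_, prob = NA_real_
      )
      next
    }
    feat <- matrix(as.vector(t(history)), 1L) # oldest bin first, channel blocks
    proba <- predict_proba(model, feat)[1, ]
    st <- decoder_step(state, proba, policy)
    state <- st$state
    out[[b]] <- tibble::tibble(
      bin = b, time_s = (b - 1) * bin_width_s,
      class = st$emitted,
      raw_class = names(proba)[which.max(proba)],
      prob = max(proba)
    )
  }
  dplyr::bind_rows(out)
}
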