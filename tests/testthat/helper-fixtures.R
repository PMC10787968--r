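# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (loops, exhaustive search) and independent
# of the implementation paths they check.

# A grid-aligned toy schedule (all boundaries multiples of 0.1 s).
toy_schedule <- function(labels, durations) {
  offs <- cumsum(durations)
  hdemg:::new_cue_schedule(
    tibble::tibble(
      segment = seq_along(labels),
      label = labels,
      onset_s = c(0, offs[-length(offs)]),
      offset_s = offs
    ),
    profile = "stroke", lead_in_s = durations[1]
  )
}

# Loop-based RMS oracle.
rms_oracle <- function(samples, fs, bin_width_s = 0.1) {
  width <- round(bin_width_s * fs)
  nb <- floor(ncol(samples) / width)
  out <- matrix(0, nb, nrow(samples))
  for (b in seq_len(nb)) {
    for (ch in seq_len(nrow(samples))) {
      acc <- 0
      for (i in seq_len(width)) {
        v <- samples[ch, (b - 1) * width + i]
        acc <- acc + v * v
      }
      out[b, ch] <- sqrt(acc / width)
    }
  }
  out
}

# Segment-mean SSR of a series under boundary positions (starts of segments
# 2..S, 1-based bins), computed naively.
ssr_oracle <- function(x, starts, n_bins) {
  starts <- c(1L, starts)
  ends <- c(starts[-1] - 1L, n_bins)
  total <- 0
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:ends[k]]
    total <- total + sum((seg - mean(seg))^2)
  }
  total
}

# Exhaustive joint search over both boundaries of a 3-segment instance.
exhaustive_shift_oracle <- function(x, schedule, max_shift_s = 2, bw = 0.1) {
  n_bins <- length(x)
  orig <- round(schedule$onset_s / bw) + 1L
  cap <- round(max_shift_s / bw)
  best <- list(ssr = Inf, b = NULL)
  for (b1 in max(2L, orig[2] - cap):min(n_bins - 1L, orig[2] + cap)) {
    for (b2 in max(b1 + 1L, orig[3] - cap):min(n_bins, orig[3] + cap)) {
      s <- ssr_oracle(x, c(b1, b2), n_bins)
      if (s < best$ssr - 1e-12) best <- list(ssr = s, b = c(b1, b2))
    }
  }
  best
}

# Small simulated block shared by several expensive tests (built once per
# test run).
cached_block <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- make_cue_schedule(c("Hand Close", "Hand Open", "Wrist Flexion"),
        2, "stroke",
        seed = 42
      )
      lay <- make_sleeve_layout("small")
      rec <- simulate_emg(sched, lay, sim_params(seed = 43, latency_range = c(0, 0)))
      ft <- rms_bins(bandpass_notch(rec))
      ns <- fit_normalizer(ft)
      ftn <- stack_history(apply_normalizer(ft, ns))
      ds <- extract_center_windows(ftn, sched, 2.5)
      cache <<- list(
        schedule = sched, layout = lay, recording = rec,
        features = ftn, norm_stats = ns, dataset = ds
      )
    }
    cache
  }
})

# Deterministic softmax/linear forward pass of an MLP in eval mode,
# re-implemented independently of mlp_forward for cross-checking.
mlp_forward_oracle <- function(par, x, spec) {
  a <- x
  for (i in seq_along(spec$hidden)) {
    z <- a %*% par$layers[[i]]$W
    z <- z + matrix(par$layers[[i]]$b, nrow(z), ncol(z), byrow = TRUE)
    bn <- par$bn[[i]]
    for (j in seq_len(ncol(z))) {
      z[, j] <- (z[, j] - bn$run_mean[j]) / sqrt(bn$run_var[j] + 1e-5) *
        bn$gamma[j] + bn$beta[j]
    }
    a <- ifelse(z > 0, z, 0)
  }
  out <- a %*% par$layers[[length(spec$hidden) + 1]]$W
  out <- out + matrix(
    par$layers[[length(spec$hidden) + 1]]$b,
    nrow(out), ncol(out),
    byrow = TRUE
  )
  p <- matrix(0, nrow(out), ncol(out))
  for (r in seq_len(nrow(out))) {
    e <- exp(out[r, ] - max(out[r, ]))
    p[r, ] <- e / sum(e)
  }
  p
}
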