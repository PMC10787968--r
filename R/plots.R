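#' Plot a few channels of a recording
#'
#' @param object An [emg_recording][simulate_emg].
#' @param channels Channel indices to draw (default first 3).
#' @param ... Unused.
#' @return A ggplot: time traces with cue segments shaded.
#' @export
autoplot.emg_recording <- function(object, channels = 1:3, ...) {
  fs <- object$sampling_rate
  df <- purrr::map(channels, function(ch) {
    tibble::tibble(
      channel = factor(ch),
      time_s = (seq_len(ncol(object$samples)) - 1) / fs,
      uV = object$samples[ch, ]
    )
  })
  df <- dplyr::bind_rows(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$uV)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "EMG (µV)")
  if (!is.null(object$schedule)) {
    cues <- dplyr::filter(tibble::as_tibble(object$schedule), .data$label != "Rest")
    p <- p + ggplot2::geom_rect(
      data = cues, inherit.aes = FALSE,
      ggplot2::aes(
        xmin = .data$onset_s, xmax = .data$offset_s,
        ymin = -Inf, ymax = Inf, fill = .data$label
      ),
      alpha = 0.15
    )
  }
  p
}

#' Heatmap of binned RMS activity
#'
#' @param object An `emg_features` object.
#' @param ... Unused.
#' @return A ggplot: channels x time heatmap of (normalized) RMS.
#' @export
autoplot.emg_features <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(.data$time_s, .data$channel, fill = .data$rms)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (isTRUE(object$normalized)) "z-RMS" else "RMS") +
    ggplot2::labs(x = "time (s)", y = "channel")
}

#' Confusion-matrix plot for an evaluation report
#'
#' @param object An `emg_eval` report.
#' @param ... Unused.
#' @return A ggplot tile plot of row-normalized confusion fractions.
#' @export
autoplot.emg_eval <- function(object, ...) {
  cm <- sweep(object$confusion, 1, pmax(rowSums(object$confusion), 1), `/`)
  df <- tibble::as_tibble(as.table(cm))
  names(df) <- c("truth", "predicted", "fraction")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$fraction)), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Summary signal with original and shifted cue boundaries
#'
#' @param object A `shift_result` from [dynamic_shift()].
#' @param summary The summary signal the shift was computed on.
#' @param original The original cue schedule.
#' @param ... Unused.
#' @return A ggplot of the summary with boundary positions before/after.
#' @export
autoplot.shift_result <- function(object, summary, original, ...) {
  bw <- 0.1
  df <- tibble::tibble(
    time_s = (seq_along(summary) - 1) * bw,
    activity = summary
  )
  bounds <- tibble::tibble(
    time_s = c(original$onset_s[-1], object$shifted_schedule$onset_s[-1]),
    which = rep(c("cue", "aligned"), each = nrow(original) - 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = bounds,
      ggplot2::aes(xintercept = .data$time_s, color = .data$which),
      linetype = "dashed", alpha = 0.7
    ) +
    ggplot2::labs(x = "time (s)", y = "mean normalized RMS", color = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
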