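#' Save / load a recording
#'
#' The native on-disk form is RDS (lossless, keeps layout, schedule and
#' ground truth). For language-neutral interchange use [write_edf()].
#'
#' @param recording An [emg_recording][simulate_emg].
#' @param path File path.
#' @return `read_recording()` returns the recording; writers return `path`
#'   invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "emg_recording")) abort("File does not contain an emg_recording.")
  rec
}

#' EDF interchange for recordings
#'
#' Writes a recording as EDF (European Data Format): fixed-width ASCII
#' header plus 16-bit little-endian samples in 0.1 s data records. Samples
#' are scaled to the per-channel physical range, so re-import agrees with
#' the original within one 16-bit quantization step; a trailing partial
#' record is dropped. Schedules and ground truth do not travel in EDF --
#' serialize them separately with [write_schedule()].
#'
#' @param recording An [emg_recording][simulate_emg].
#' @param path Output path.
#' @return `read_edf()` returns an `emg_recording` (no schedule);
#'   `write_edf()` returns `path` invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  x <- recording$samples
  fs <- recording$sampling_rate
  rec_dur <- 0.1
  spr <- as.integer(round(fs * rec_dur)) # samples per signal per record
  n_rec <- ncol(x) %/% spr
  n_sig <- nrow(x)
  if (n_rec < 1L) abort("Recording shorter than one EDF record.")

  pad <- function(s, width) {
    s <- substr(as.character(s), 1, width)
    sprintf("%-*s", width, s)
  }
  phys_max <- pmax(apply(abs(x), 1, max), 1e-6)
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    pad("0", 8), pad("synthetic sleeve subject", 80), pad("hdemg recording", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (1 + n_sig), 8), pad("", 44),
    pad(n_rec, 8), pad(format(rec_dur), 8), pad(n_sig, 4)
  )
  writeChar(header, con, eos = NULL)
  field <- function(f, width) writeChar(paste0(vapply(f, pad, "", width = width), collapse = ""), con, eos = NULL)
  field(sprintf("EMG ch%d", seq_len(n_sig)), 16) # label
  field(rep("HD-EMG sleeve", n_sig), 80) # transducer
  field(rep("uV", n_sig), 8) # physical dimension
  field(sprintf("%.6g", -phys_max), 8) # physical minimum
  field(sprintf("%.6g", phys_max), 8) # physical maximum
  field(rep(-dig_max - 1L, n_sig), 8) # digital minimum
  field(rep(dig_max, n_sig), 8) # digital maximum
  field(rep("BP 20-400 Hz, notch 60 Hz", n_sig), 80) # prefiltering
  field(rep(spr, n_sig), 8) # samples per record
  field(rep("", n_sig), 32) # reserved

  # inverse of the standard EDF decode map phys = (dig - dmin) * span + pmin
  for (r in seq_len(n_rec)) {
    span <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(n_sig)) {
      gain <- (2 * phys_max[s]) / (2 * dig_max + 1)
      dig <- round((x[s, span] + phys_max[s]) / gain) - dig_max - 1
      dig <- as.integer(pmin(pmax(dig, -dig_max - 1), dig_max))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(n_sig), function(i) rd(width), "")
  rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8))
  dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)

  x <- matrix(0, n_sig, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      dig <- readBin(con, integer(), n = spr[s], size = 2, endian = "little")
      phys <- pmin_[s] + (dig - dmin_[s]) * (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
      x[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  structure(
    list(
      samples = x,
      sampling_rate = spr[1] / rec_dur,
      layout = NULL, schedule = NULL, filtered = NA, ground_truth = NULL
    ),
    class = "emg_recording"
  )
}

#' Persist binned features as CSV
#'
#' Columns: `bin_index`, `label`, then one column per channel (`ch0`...).
#'
#' @param features An `emg_features` object.
#' @param path Output path.
#' @return `read_features_csv()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "emg_features"))
  df <- as.data.frame(features$rms)
  names(df) <- paste0("ch", seq_len(ncol(df)) - 1L)
  df <- cbind(
    bin_index = seq_len(nrow(df)) - 1L,
    label = features$labels %||% NA_character_,
    df
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Write an evaluation report as JSON
#'
#' @param report An `emg_eval` object.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "emg_eval"))
  obj <- list(
    bin_accuracy = report$bin_accuracy,
    chance_level = report$chance_level,
    per_class_accuracy = as.list(report$per_class_accuracy),
    confusion = list(
      classes = rownames(report$confusion),
      counts = unname(apply(report$confusion, 1, as.list))
    ),
    success = if (!is.null(report$success)) {
      list(
        rate = report$success$rate,
        per_class = purrr::pmap(report$success$per_class, function(label, successes, attempts) {
          list(label = label, successes = successes, attempts = attempts)
        })
      )
    },
    n_bins = report$n_bins
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Save / load training normalization statistics as JSON
#'
#' @param norm_stats A [fit_normalizer()] result.
#' @param path File path.
#' @export
write_norm_stats <- function(norm_stats, path) {
  stopifnot(inherits(norm_stats, "norm_stats"))
  jsonlite::write_json(
    list(mean = norm_stats$mean, sd = norm_stats$sd),
    path, digits = NA
  )
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = obj$mean, sd = obj$sd), class = "norm_stats")
}
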