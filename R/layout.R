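#' The 13 movement classes decoded by the pipeline
#'
#' Rest plus the 12 cued hand, wrist, and forearm movements used for
#' myoelectric intention decoding. Class indices are fixed (Rest = 0) so that
#' label encodings are stable across models and serialized artifacts.
#'
#' @return A tibble with columns `label`, `index` (0-12) and `side`, the
#'   forearm aspect (flexor/extensor) where the movement's musculature
#'   predominantly lies; used by the simulator to place activation patterns.
#' @export
#' @examples
#' movement_classes()
movement_classes <- function() {
  tibble::tibble(
    label = c(
      "Rest", "Hand Close", "Hand Open", "Index Extension", "Thumb Flexion",
      "Thumb Extension", "Thumb Abduction", "Forearm Supination",
      "Forearm Pronation", "Wrist Flexion", "Wrist Extension",
      "Two Point Pinch", "Key Pinch"
    ),
    index = 0:12,
    side = c(
      NA, "flexor", "extensor", "extensor", "flexor",
      "extensor", "extensor", "extensor",
      "flexor", "flexor", "extensor",
      "flexor", "flexor"
    )
  )
}

sleeve_sizes <- c(small = 64L, medium = 71L, large = 75L)

#' Build a sleeve electrode-grid layout
#'
#' The recording sleeve wraps the forearm from elbow to wrist with a grid of
#' bipolar channels: rings along the forearm axis, angular sectors around it.
#' Three garment sizes expose 64 (small), 71 (medium) or 75 (large) bipolar
#' channels; electrodes are spaced 25 mm apart. Channels are laid out
#' ring-major; sectors 0-3 sit over the flexor aspect, 4-7 over the extensor
#' aspect.
#'
#' @param size_class One of `"small"`, `"medium"`, `"large"`.
#' @return A tibble of class `sleeve_layout` with one row per bipolar channel:
#'   `channel` (1-based), `ring` (0-based, elbow to wrist), `sector`
#'   (0-based, around the forearm), `side` (`"flexor"`/`"extensor"`),
#'   `x_mm`, `y_mm` (unrolled grid coordinates). Attributes: `size_class`,
#'   `n_channels`, `n_rings`, `n_sectors`, `electrode_spacing_mm`.
#' @export
#' @examples
#' lay <- make_sleeve_layout("large")
#' nrow(lay) # 75
make_sleeve_layout <- function(size_class = c("small", "medium", "large")) {
  if (length(size_class) != 1L || !size_class %in% names(sleeve_sizes)) {
    abort(paste0(
      "Unknown sleeve size ", deparse(substitute(size_class)),
      "; valid options are \"small\", \"medium\", \"large\"."
    ))
  }
  n_channels <- sleeve_sizes[[size_class]]
  n_sectors <- 8L
  n_rings <- as.integer(ceiling(n_channels / n_sectors))
  spacing <- 25
  channel <- seq_len(n_channels)
  ring <- (channel - 1L) %/% n_sectors
  sector <- (channel - 1L) %% n_sectors
  out <- tibble::tibble(
    channel = channel,
    ring = ring,
    sector = sector,
    side = ifelse(sector < 4L, "flexor", "extensor"),
    x_mm = ring * spacing,
    y_mm = sector * spacing
  )
  structure(
    out,
    size_class = size_class,
    n_channels = n_channels,
    n_rings = n_rings,
    n_sectors = n_sectors,
    electrode_spacing_mm = spacing,
    class = c("sleeve_layout", class(out))
  )
}

#' @export
print.sleeve_layout <- function(x, ...) {
  cat(sprintf(
    "<sleeve_layout: %s, %d bipolar channels, %d rings x %d sectors, %g mm spacing>\n",
    attr(x, "size_class"), attr(x, "n_channels"),
    attr(x, "n_rings"), attr(x, "n_sectors"), attr(x, "electrode_spacing_mm")
  ))
  NextMethod()
}
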