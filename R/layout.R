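#' Region-of-interest vocabulary for the probe montage
#'
#' The ten cortical regions covered by the montage: bilateral premotor
#' cortex (PMC), dorsolateral prefrontal cortex (DLPFC) and frontopolar
#' area (FPA), left inferior frontal gyrus (IFG), right supramarginal
#' gyrus (SMG), right primary somatosensory (SI) and right primary motor
#' (MI) cortices.
#' @export
ROI_NAMES <- c("L PMC", "R PMC", "L DLPFC", "R DLPFC", "L FPA", "R FPA",
               "L IFG", "R SMG", "R SI", "R MI")

#' Default channel-to-ROI assignment for 24 long channels
#'
#' A declarative stand-in for optode registration: each long channel is
#' assigned to one of the ten ROIs, with heavier coverage of the prefrontal
#' regions, mirroring a frontal + right sensorimotor probe.
#'
#' @return data.frame with columns `channel` (1..24) and `roi`.
#' @export
default_roi_table <- function() {
  data.frame(
    channel = 1:24,
    roi = c(
      "L PMC", "L PMC",
      "R PMC", "R PMC",
      "L DLPFC", "L DLPFC", "L DLPFC",
      "R DLPFC", "R DLPFC", "R DLPFC",
      "L FPA", "L FPA", "L FPA",
      "R FPA", "R FPA", "R FPA",
      "L IFG", "L IFG",
      "R SMG", "R SMG",
      "R SI", "R SI",
      "R MI", "R MI"
    ),
    stringsAsFactors = FALSE
  )
}

#' Build a channel layout with long/short channel pairing
#'
#' Constructs the montage description used throughout the pipeline: `n_long`
#' measurement channels, each mapped to one ROI and paired with its nearest
#' short-separation channel (the nuisance regressor sampling scalp/systemic
#' hemodynamics only). Short channels are distributed evenly over the long
#' channels.
#'
#' @param n_long Number of long (cortical) channels.
#' @param n_short Number of short-separation channels (must be >= 1).
#' @param roi_table data.frame with `channel`, `roi` covering all long
#'   channels; defaults to [default_roi_table()].
#' @param seed Unused randomness hook kept for interface stability.
#' @return An object of class `channel_layout`.
#' @export
make_layout <- function(n_long = 24, n_short = 8, roi_table = default_roi_table(),
                        seed = 1) {
  if (n_short < 1) stopf("layout requires at least one short channel (got %d)", n_short)
  if (n_long < 1) stopf("layout requires at least one long channel")
  roi_table <- as.data.frame(roi_table)
  if (!all(seq_len(n_long) %in% roi_table$channel)) {
    missing <- setdiff(seq_len(n_long), roi_table$channel)
    stopf("roi_table misses long channel(s): %s", paste(missing, collapse = ", "))
  }
  rois <- roi_table$roi[match(seq_len(n_long), roi_table$channel)]
  if (anyNA(rois) || any(!nzchar(rois))) stopf("every long channel needs an ROI")
  unknown <- setdiff(unique(rois), ROI_NAMES)
  if (length(unknown)) {
    stopf("unknown ROI name(s): %s", paste(unknown, collapse = ", "))
  }
  # short channel ids live after the long ids in the channel axis
  n_long <- as.integer(n_long)
  n_short <- as.integer(n_short)
  short_ids <- n_long + seq_len(n_short)
  nearest_short <- short_ids[ceiling(seq_len(n_long) / (n_long / n_short))]
  channels <- data.frame(
    id = c(seq_len(n_long), short_ids),
    source = c(seq_len(n_long), seq_len(n_short)),
    detector = c(seq_len(n_long), seq_len(n_short)),
    kind = c(rep("long", n_long), rep("short", n_short)),
    roi = c(rois, rep(NA_character_, n_short)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      channels = channels,
      nearest_short = stats::setNames(nearest_short, seq_len(n_long)),
      n_long = as.integer(n_long),
      n_short = as.integer(n_short),
      rois = unique(rois)
    ),
    class = "channel_layout"
  )
}

long_ids <- function(layout) layout$channels$id[layout$channels$kind == "long"]
short_ids <- function(layout) layout$channels$id[layout$channels$kind == "short"]

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf("<channel_layout> %d long + %d short channels over %d ROIs\n",
              x$n_long, x$n_short, length(x$rois)))
  invisible(x)
}
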