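#' Write a scan to a portable JSON container
#'
#' Serializes a [simulate_scan()] result (intensity, montage, protocol,
#' condition, ground-truth sidecar) to a single self-describing JSON file.
#' Numeric data are written with 17 significant digits so the write/read
#' round trip reproduces every double exactly.
#'
#' @param scan A `raw_scan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "raw_scan"))
  payload <- list(
    format = "fnirspain-scan",
    version = 1L,
    fs = scan$fs,
    condition = scan$condition,
    subject = scan$subject,
    seed = scan$seed,
    intensity = list(dim = dim(scan$intensity), data = as.numeric(scan$intensity)),
    ground_truth = list(dim = dim(scan$ground_truth),
                        data = as.numeric(scan$ground_truth)),
    events = scan$protocol$events,
    protocol = list(session_length = scan$protocol$session_length,
                    stim_dur = scan$protocol$stim_dur, rest = scan$protocol$rest,
                    seed = scan$protocol$seed),
    layout = list(channels = scan$layout$channels,
                  nearest_short = as.integer(scan$layout$nearest_short),
                  n_long = scan$layout$n_long, n_short = scan$layout$n_short)
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' Read a scan written by [write_scan()]
#'
#' @param path Path to a scan JSON file.
#' @return A `raw_scan` object equal to the one written.
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stopf("no such scan file: %s", path)
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$format, "fnirspain-scan")) {
    stopf("not an fnirspain scan file: %s", path)
  }
  for (field in c("intensity", "events", "layout", "protocol", "condition")) {
    if (is.null(p[[field]])) stopf("scan file %s is missing field '%s'", path, field)
  }
  channels <- as.data.frame(p$layout$channels, stringsAsFactors = FALSE)
  for (col in c("id", "source", "detector")) {
    channels[[col]] <- as.integer(channels[[col]])
  }
  layout <- structure(
    list(
      channels = channels,
      nearest_short = stats::setNames(as.integer(p$layout$nearest_short),
                                      seq_len(p$layout$n_long)),
      n_long = as.integer(p$layout$n_long),
      n_short = as.integer(p$layout$n_short),
      rois = unique(stats::na.omit(p$layout$channels$roi))
    ),
    class = "channel_layout"
  )
  events <- as.data.frame(p$events, stringsAsFactors = FALSE)
  protocol <- structure(
    list(events = events, session_length = p$protocol$session_length,
         stim_dur = p$protocol$stim_dur, rest = p$protocol$rest,
         seed = as.integer(p$protocol$seed)),
    class = "stimulus_protocol"
  )
  structure(
    list(
      intensity = array(p$intensity$data, dim = p$intensity$dim),
      fs = p$fs, layout = layout, protocol = protocol,
      condition = p$condition, subject = as.integer(p$subject),
      ground_truth = array(p$ground_truth$data, dim = p$ground_truth$dim),
      seed = as.integer(p$seed)
    ),
    class = "raw_scan"
  )
}

#' Write a full study to disk with a manifest
#'
#' @param study A list as returned by [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return data.frame manifest (`file`, `condition`, `subject`, `session`),
#'   also written to `manifest.csv` in `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cond in names(study)) {
    for (i in seq_along(study[[cond]])) {
      scan <- study[[cond]][[i]]
      file <- sprintf("scan_%s_s%02d_%02d.json", cond, scan$subject, i)
      write_scan(scan, file.path(dir, file))
      rows[[length(rows) + 1L]] <- data.frame(
        file = file, condition = cond, subject = scan$subject, session = i,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
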