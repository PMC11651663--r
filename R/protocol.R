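#' Build a nociceptive stimulation protocol
#'
#' Generates the event list of a block-design nociceptive session: equal
#' numbers of painful and non-painful stimuli in seeded random order, each
#' stimulus lasting `stim_dur` seconds and followed by `rest` seconds of
#' rest before the next onset. The defaults reproduce the canonical design
#' of six painful and six non-painful 5-s stimuli separated by 25-s rests.
#'
#' @param n_per_class Number of stimuli per class (pain / non-pain).
#' @param stim_dur Stimulus duration in seconds.
#' @param rest Rest period after each stimulus, seconds.
#' @param seed Integer seed controlling the label order.
#' @param lead_in Quiet baseline before the first onset, seconds.
#' @param lead_out Quiet tail after the final rest, seconds.
#' @return An object of class `stimulus_protocol`: a list with `events`
#'   (data.frame of `onset`, `duration`, `label`) and `session_length`
#'   in seconds.
#' @examples
#' p <- make_protocol(6, 5, 25, seed = 1)
#' nrow(p$events)          # 12
#' table(p$events$label)   # 6 pain, 6 non-pain
#' @export
make_protocol <- function(n_per_class = 6, stim_dur = 5, rest = 25, seed = 1,
                          lead_in = 15, lead_out = 15) {
  if (!is.numeric(n_per_class) || n_per_class < 1 || n_per_class != round(n_per_class)) {
    stopf("`n_per_class` must be a positive integer")
  }
  assert_scalar_pos(stim_dur, "stim_dur")
  assert_scalar_pos(rest, "rest")
  n_events <- 2L * as.integer(n_per_class)
  labels <- with_seed(seed, sample(rep(c("pain", "non-pain"), n_per_class)))
  onsets <- lead_in + (seq_len(n_events) - 1L) * (stim_dur + rest)
  events <- data.frame(
    onset = onsets,
    duration = rep(stim_dur, n_events),
    label = labels,
    stringsAsFactors = FALSE
  )
  out <- structure(
    list(
      events = events,
      session_length = lead_in + n_events * (stim_dur + rest) + lead_out,
      stim_dur = stim_dur,
      rest = rest,
      seed = as.integer(seed)
    ),
    class = "stimulus_protocol"
  )
  validate_protocol(out)
  out
}

validate_protocol <- function(p) {
  ev <- p$events
  if (any(diff(ev$onset) < ev$duration[-nrow(ev)] + p$rest - 1e-9)) {
    stopf("protocol events overlap or violate the rest period")
  }
  counts <- table(ev$label)
  if (length(counts) != 2L || counts[["pain"]] != counts[["non-pain"]]) {
    stopf("protocol must contain equal numbers of pain and non-pain events")
  }
  if (utils::tail(ev$onset, 1) + utils::tail(ev$duration, 1) > p$session_length) {
    stopf("events extend past the session length")
  }
  invisible(p)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> %d events (%d per class), %.0f s stim + %.0f s rest, session %.0f s\n",
    nrow(x$events), nrow(x$events) / 2L, x$stim_dur, x$rest, x$session_length
  ))
  invisible(x)
}
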