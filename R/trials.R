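#' Epoch a preprocessed scan into labelled trials
#'
#' Cuts one trial per stimulus event from the long-channel \eqn{\Delta}HbO
#' series: a 1-s pre-stimulus period plus a 30-s post-onset period,
#' down-sampled to 1 Hz by decimation (the 0.1 Hz low-pass leaves no
#' content near the new Nyquist). With the defaults each trial is a
#' 31-sample x n_long matrix. Pain trials are labelled +1, non-pain -1.
#' Events whose window falls outside the scan are dropped with a warning.
#'
#' @param hemo A `hemo_scan` (after short-channel regression).
#' @param protocol Stimulus protocol; defaults to the scan's own.
#' @param pre_s,post_s Window extent in seconds around each onset.
#' @param target_fs Target sampling rate in Hz (must divide `fs`).
#' @return A `trial_set`: list with `data` (N x T x C array), `labels`
#'   (+1/-1), `meta` (data.frame: subject, condition, onset), `T`, `C`.
#' @export
extract_trials <- function(hemo, protocol = hemo$protocol,
                           pre_s = 1, post_s = 30, target_fs = 1) {
  stopifnot(inherits(hemo, "hemo_scan"))
  dec <- hemo$fs / target_fs
  if (abs(dec - round(dec)) > 1e-9) {
    stopf("target_fs must divide the scan sampling rate")
  }
  dec <- as.integer(round(dec))
  nl <- hemo$layout$n_long
  X <- hemo$dHbO[seq(1, nrow(hemo$dHbO), by = dec), seq_len(nl), drop = FALSE]
  n_dec <- nrow(X)
  Tt <- as.integer((pre_s + post_s) * target_fs)
  ev <- protocol$events
  keep <- list()
  labels <- integer(0)
  onsets <- numeric(0)
  for (k in seq_len(nrow(ev))) {
    t0 <- ev$onset[k] - pre_s
    idx <- round(t0 * target_fs) + seq_len(Tt)
    if (idx[1] < 1 || idx[Tt] > n_dec) {
      warning(sprintf("dropping trial at onset %.1f s: window outside scan",
                      ev$onset[k]), call. = FALSE)
      next
    }
    keep[[length(keep) + 1L]] <- X[idx, , drop = FALSE]
    labels <- c(labels, if (ev$label[k] == "pain") 1L else -1L)
    onsets <- c(onsets, ev$onset[k])
  }
  data <- array(0, c(length(keep), Tt, nl))
  for (i in seq_along(keep)) data[i, , ] <- keep[[i]]
  structure(
    list(
      data = data, labels = labels,
      meta = data.frame(subject = rep(hemo$subject %||% NA_integer_, length(keep)),
                        condition = rep(hemo$condition %||% NA_character_, length(keep)),
                        onset = onsets, stringsAsFactors = FALSE),
      T = Tt, C = nl
    ),
    class = "trial_set"
  )
}

#' Pool trial sets across sessions and subjects
#'
#' @param sets Non-empty list of `trial_set`s with identical `T` and `C`.
#' @return One concatenated `trial_set` with metadata preserved.
#' @export
pool_sessions <- function(sets) {
  if (!length(sets)) stopf("cannot pool an empty list of trial sets")
  Tt <- sets[[1]]$T
  C <- sets[[1]]$C
  for (s in sets) {
    if (s$T != Tt || s$C != C) stopf("trial sets have mismatched shapes")
  }
  n <- sum(vapply(sets, function(s) dim(s$data)[1], integer(1)))
  data <- array(0, c(n, Tt, C))
  labels <- integer(n)
  meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  at <- 0L
  for (s in sets) {
    k <- dim(s$data)[1]
    if (k > 0) {
      data[at + seq_len(k), , ] <- s$data
      labels[at + seq_len(k)] <- s$labels
    }
    at <- at + k
  }
  structure(list(data = data, labels = labels, meta = meta, T = Tt, C = C),
            class = "trial_set")
}

subset_trials <- function(ts, idx, role = NULL) {
  out <- ts
  out$data <- ts$data[idx, , , drop = FALSE]
  out$labels <- ts$labels[idx]
  out$meta <- ts$meta[idx, , drop = FALSE]
  out$role <- role
  out
}

#' Split pooled trials 60/20/20
#'
#' Seeded shuffle followed by a floor-rounded partition: validation and
#' test each receive `floor(frac * N)` trials and the remainder goes to
#' training (336 trials give 202/67/67, 168 give 102/33/33). The shuffle
#' is redrawn (bounded retries) until every partition contains both
#' classes.
#'
#' @param ts A `trial_set`.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed for the shuffle.
#' @param max_retry Bound on reshuffles for class presence.
#' @return A `data_split`: list with `train`, `validation`, `test`
#'   (`trial_set`s carrying a `role`), `fractions`, `seed`.
#' @export
split_trials <- function(ts, fractions = c(0.6, 0.2, 0.2), seed = 1,
                         max_retry = 100) {
  stopifnot(inherits(ts, "trial_set"))
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  n <- dim(ts$data)[1]
  if (n < 5) stopf("need at least 5 trials to split")
  if (length(unique(ts$labels)) < 2) stopf("cannot stratify a single-class set")
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  for (attempt in seq_len(max_retry)) {
    ord <- with_seed(derive_seed(seed, "split", attempt), sample.int(n))
    i_train <- ord[seq_len(n_train)]
    i_val <- ord[n_train + seq_len(n_val)]
    i_test <- ord[n_train + n_val + seq_len(n_test)]
    ok <- all(vapply(list(i_train, i_val, i_test),
                     function(i) length(unique(ts$labels[i])) == 2, logical(1)))
    if (ok) {
      return(structure(
        list(
          train = subset_trials(ts, i_train, "train"),
          validation = subset_trials(ts, i_val, "validation"),
          test = subset_trials(ts, i_test, "test"),
          fractions = fractions, seed = as.integer(seed),
          indices = list(train = i_train, validation = i_val, test = i_test)
        ),
        class = "data_split"
      ))
    }
  }
  stopf("could not produce a split with both classes in every partition")
}

#' Augmentation configuration
#'
#' @param factor Number of augmented copies per training trial (the
#'   originals are always retained).
#' @param slopes Candidate linear-trend slopes (units per second at 1 Hz).
#' @param variances Candidate Gaussian noise variances.
#' @param seed Integer seed.
#' @return An `augmentation_config`.
#' @export
augmentation_config <- function(factor = 25,
                                slopes = c(0.01, 0.05, 0.1),
                                variances = c(0.01, 0.05, 0.1),
                                seed = 1) {
  if (factor < 0) stopf("`factor` must be >= 0")
  if (!length(slopes) || !length(variances)) {
    stopf("slope and variance sets must be non-empty")
  }
  structure(list(factor = as.integer(factor), slopes = slopes,
                 variances = variances, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Augment the training portion of a split
#'
#' Each augmented copy of a trial applies exactly one time-domain
#' procedure, chosen at random: addition of a linear trend
#' `slope * (0, 1, ..., T-1)` to every channel, with the slope drawn from
#' the configured set, or addition of zero-mean Gaussian noise with a
#' variance drawn from the configured set, independently per sample and
#' channel. Labels are copied. Only the training partition may be
#' augmented; validation and test partitions are refused.
#'
#' @param ts A `trial_set` with role `"train"` (or no role).
#' @param config An [augmentation_config()].
#' @return A `trial_set` with `N * (1 + factor)` trials.
#' @export
augment_trials <- function(ts, config = augmentation_config()) {
  stopifnot(inherits(ts, "trial_set"))
  if (!is.null(ts$role) && ts$role != "train") {
    stopf("augmentation is restricted to the training partition (got '%s')", ts$role)
  }
  n <- dim(ts$data)[1]
  Tt <- ts$T
  C <- ts$C
  f <- config$factor
  if (f == 0 || n == 0) return(ts)
  out <- array(0, c(n * (1L + f), Tt, C))
  out[seq_len(n), , ] <- ts$data
  labels <- c(ts$labels, rep(ts$labels, f))
  trend_base <- seq_len(Tt) - 1
  with_seed(config$seed, {
    at <- n
    for (copy in seq_len(f)) {
      use_trend <- stats::runif(n) < 0.5
      slopes <- sample(config$slopes, n, replace = TRUE)
      vars <- sample(config$variances, n, replace = TRUE)
      for (i in seq_len(n)) {
        x <- ts$data[i, , ]
        if (use_trend[i]) {
          x <- x + slopes[i] * trend_base
        } else {
          x <- x + matrix(stats::rnorm(Tt * C, 0, sqrt(vars[i])), Tt, C)
        }
        out[at + i, , ] <- x
      }
      at <- at + n
    }
  })
  meta <- ts$meta[rep(seq_len(n), 1L + f), , drop = FALSE]
  structure(list(data = out, labels = labels, meta = meta, T = Tt, C = C,
                 role = ts$role, augmented = TRUE),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> N=%d trials x T=%d x C=%d (%d pain / %d non-pain)%s\n",
              dim(x$data)[1], x$T, x$C, sum(x$labels == 1), sum(x$labels == -1),
              if (!is.null(x$role)) paste0(" [", x$role, "]") else ""))
  invisible(x)
}
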