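#' Convert raw light intensity to optical density
#'
#' Per channel and wavelength, `OD(t) = -ln(I(t) / mean_t I)`, i.e. optical
#' density relative to the whole-scan mean intensity baseline.
#'
#' @param scan A `raw_scan`.
#' @return An `od_scan`: list with `od` (time x channel x wavelength),
#'   `fs`, `layout` and the scan's protocol/condition metadata.
#' @export
intensity_to_od <- function(scan) {
  stopifnot(inherits(scan, "raw_scan"))
  I <- scan$intensity
  bad <- which(I <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("non-positive intensity at sample %d, channel %d, wavelength %d",
          bad[1, 1], bad[1, 2], bad[1, 3])
  }
  od <- I
  for (j in seq_len(dim(I)[2])) {
    for (w in 1:2) {
      od[, j, w] <- -log(I[, j, w] / mean(I[, j, w]))
    }
  }
  structure(
    list(od = od, fs = scan$fs, layout = scan$layout, protocol = scan$protocol,
         condition = scan$condition, subject = scan$subject),
    class = "od_scan"
  )
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (`signal::filtfilt`, zero phase) to every channel and wavelength.
#' The default 0.01-0.1 Hz band isolates evoked hemodynamics and rejects
#' cardiac pulsation (>1 Hz), respiration (0.15-0.4 Hz) and attenuates
#' Mayer waves (~0.1 Hz).
#'
#' @param od An `od_scan`.
#' @param low,high Cutoff frequencies in Hz, `0 < low < high < fs/2`.
#' @param order Filter order per pass.
#' @return The filtered `od_scan`.
#' @export
bandpass <- function(od, low = 0.01, high = 0.1, order = 3) {
  stopifnot(inherits(od, "od_scan"))
  nyq <- od$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stopf("cutoffs must satisfy 0 < low < high < fs/2 = %g", nyq)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  x <- od$od
  for (j in seq_len(dim(x)[2])) {
    for (w in 1:2) {
      x[, j, w] <- signal::filtfilt(bf, x[, j, w])
    }
  }
  od$od <- x
  od$filtered <- TRUE
  od
}

#' Invert the modified Beer-Lambert law
#'
#' Per channel, solves the 2x2 system
#' `OD_w = (eps_w,HbO * dHbO + eps_w,HbR * dHbR) * d * DPF_w` for the
#' hemoglobin concentration changes, using the channel's source-detector
#' separation (long or short) and the configured differential pathlength
#' factors. Concentrations are returned in micromolar.
#'
#' @param od An `od_scan`.
#' @param optics Optical constants as from [default_optics()].
#' @return A `hemo_scan`: `dHbO`, `dHbR` (time x channel, microM), `fs`,
#'   `layout`, provenance flags.
#' @export
od_to_hemoglobin <- function(od, optics = default_optics()) {
  stopifnot(inherits(od, "od_scan"))
  E <- optics$extinction
  if (abs(det(E)) < 1e-12) stopf("singular extinction matrix")
  nl <- od$layout$n_long
  nc <- dim(od$od)[2]
  dist <- ifelse(seq_len(nc) <= nl, optics$dist_long, optics$dist_short)
  if (any(dist <= 0)) stopf("source-detector distances must be positive")
  Einv <- solve(E)
  n <- dim(od$od)[1]
  dHbO <- matrix(0, n, nc)
  dHbR <- matrix(0, n, nc)
  for (j in seq_len(nc)) {
    od_eff <- cbind(od$od[, j, 1] / (dist[j] * optics$dpf[1]),
                    od$od[, j, 2] / (dist[j] * optics$dpf[2]))
    conc <- od_eff %*% t(Einv)
    dHbO[, j] <- conc[, 1]
    dHbR[, j] <- conc[, 2]
  }
  structure(
    list(dHbO = dHbO, dHbR = dHbR, fs = od$fs, layout = od$layout,
         protocol = od$protocol, condition = od$condition,
         subject = od$subject,
         filtered = isTRUE(od$filtered), short_regressed = FALSE),
    class = "hemo_scan"
  )
}

#' Short-separation channel regression
#'
#' For every long channel's \eqn{\Delta}HbO series `L` and its nearest
#' short channel's series `S`, estimates the scalar systemic coupling
#' `beta = (S'S)^{-1} S'L` (ordinary least squares through the origin; the
#' band-passed series are near zero-mean so no intercept is used) and
#' returns the corrected series `L' = L - beta * S`. The residual is
#' orthogonal to the short-channel regressor by construction.
#'
#' @param hemo A `hemo_scan`.
#' @param layout Channel layout; defaults to the scan's own.
#' @return List with `scan` (the corrected `hemo_scan`, short channels
#'   retained but flagged consumed) and `record` (data.frame: `channel`,
#'   `short`, `beta`).
#' @export
short_channel_regress <- function(hemo, layout = hemo$layout) {
  stopifnot(inherits(hemo, "hemo_scan"))
  nl <- layout$n_long
  betas <- numeric(nl)
  shorts <- integer(nl)
  for (j in seq_len(nl)) {
    s_id <- layout$nearest_short[[as.character(j)]]
    S <- hemo$dHbO[, s_id]
    L <- hemo$dHbO[, j]
    ss <- sum(S * S)
    if (ss == 0) stopf("short channel %d is all zero: normal equation singular", s_id)
    beta <- sum(S * L) / ss
    hemo$dHbO[, j] <- L - beta * S
    betas[j] <- beta
    shorts[j] <- s_id
  }
  hemo$short_regressed <- TRUE
  list(
    scan = hemo,
    record = data.frame(channel = seq_len(nl), short = shorts, beta = betas)
  )
}

#' Default preprocessing parameters
#'
#' @return Named list of stage parameters consumed by [preprocess_scan()].
#' @export
preprocess_params <- function() {
  list(
    stages = c("od", "wavelet", "pca", "bandpass", "mbll", "short_regression"),
    wavelet_iqr = 1.5,
    wavelet_levels = NULL,
    pca_var = 0.8,
    band = c(0.01, 0.1),
    filter_order = 3,
    optics = default_optics(),
    verbose = FALSE
  )
}

#' Full preprocessing chain for one scan
#'
#' Fixed-order composition: intensity to optical density, wavelet then PCA
#' motion correction, zero-phase Butterworth band-pass, modified
#' Beer-Lambert inversion, short-channel regression of \eqn{\Delta}HbO.
#' The stage order is part of the method and cannot be permuted; a `stages`
#' entry that differs from the canonical order is refused.
#'
#' @param scan A `raw_scan`.
#' @param params Stage parameters, see [preprocess_params()].
#' @return A `hemo_scan` with the short-regression `record` attached as
#'   attribute `"regression"`.
#' @export
preprocess_scan <- function(scan, params = preprocess_params()) {
  defaults <- preprocess_params()
  params <- utils::modifyList(defaults, params)
  if (!identical(params$stages, defaults$stages)) {
    stopf("preprocessing stage order is fixed: %s",
          paste(defaults$stages, collapse = " -> "))
  }
  say <- function(fmt, ...) if (isTRUE(params$verbose)) message(sprintf(fmt, ...))
  say("stage od: intensity -> optical density")
  od <- intensity_to_od(scan)
  say("stage wavelet: db5 outlier suppression (iqr_factor = %g)", params$wavelet_iqr)
  od <- correct_motion_wavelet(od, params$wavelet_iqr, params$wavelet_levels)
  say("stage pca: remove shared components (var_fraction = %g)", params$pca_var)
  od <- correct_motion_pca(od, params$pca_var)
  say("stage bandpass: %g-%g Hz order %d, zero phase",
      params$band[1], params$band[2], params$filter_order)
  od <- bandpass(od, params$band[1], params$band[2], params$filter_order)
  say("stage mbll: optical density -> hemoglobin (microM)")
  hemo <- od_to_hemoglobin(od, params$optics)
  say("stage short_regression: systemic removal via nearest short channel")
  res <- short_channel_regress(hemo)
  out <- res$scan
  attr(out, "regression") <- res$record
  out
}
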