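#' Canonical double-gamma hemodynamic response function
#'
#' @param t Time grid in seconds.
#' @param peak Delay of the positive response peak, seconds.
#' @param undershoot Delay of the post-stimulus undershoot, seconds.
#' @param ratio Undershoot-to-peak amplitude ratio.
#' @param disp,disp_u Dispersion of peak and undershoot gamma kernels.
#' @return Numeric vector of the HRF sampled at `t`, scaled to unit peak.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6,
                             disp = 1, disp_u = 1) {
  h <- stats::dgamma(t, shape = peak / disp, scale = disp) -
    ratio * stats::dgamma(t, shape = undershoot / disp_u, scale = disp_u)
  h[t < 0] <- 0
  m <- max(abs(h))
  if (m > 0) h <- h / m
  h
}

#' Default pain / non-pain response amplitude table
#'
#' Peak evoked \eqn{\Delta}HbO amplitude in micromolar per ROI and class.
#' Pain responses are negative (deactivation) in the frontopolar areas and
#' positive over sensorimotor and lateral prefrontal regions; non-painful
#' stimulation evokes the same spatial pattern at a fraction of the
#' amplitude, as expected for a sub-threshold electrical stimulus.
#'
#' @return data.frame with columns `roi`, `pain`, `nonpain` (micromolar).
#' @export
default_amplitudes <- function() {
  data.frame(
    roi = ROI_NAMES,
    pain    = c(0.5, 0.5, 0.4, 0.4, -0.8, -0.8, 0.3, 0.4, 1.0, 0.8),
    nonpain = c(0.15, 0.15, 0.1, 0.1, -0.15, -0.15, 0.1, 0.1, 0.3, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Collects every knob of the session simulator: study design, sampling
#' rate, HRF shape, evoked amplitudes, physiological noise amplitudes,
#' drift, motion-artifact statistics, the optical forward model and the
#' short-channel systemic coupling.
#'
#' Noise amplitudes are expressed in micromolar of equivalent \eqn{\Delta}HbO;
#' the systemic components (cardiac ~1.1 Hz, respiration ~0.25 Hz, Mayer
#' waves ~0.1 Hz, slow drift) share one time course across channels with
#' channel-specific gains, which is what makes short-channel regression
#' effective.
#'
#' @param n_subjects Number of subjects in the study.
#' @param conditions Character vector of scan conditions; subset of
#'   `c("pre","MM30","MM60","MM90","PM30","PM60","PM90")`.
#' @param fs_raw Raw sampling rate in Hz.
#' @param amplitudes Amplitude table as from [default_amplitudes()].
#' @param class_separation Scale on the pain-minus-nonpain amplitude
#'   difference; 1 reproduces the table, 0 makes classes identical.
#' @param morphine_attenuation Multiplier applied to the pain-class FPA
#'   amplitude under morphine conditions.
#' @param attenuated_rois ROIs subject to the morphine attenuation.
#' @param noise Named list of amplitudes (micromolar): `cardiac`,
#'   `respiration`, `mayer`, `white`, `drift`.
#' @param motion Named list: `rate` (events per second per channel),
#'   `spike_amp`, `step_amp` (micromolar), `spike_tau` (s).
#' @param short_coupling Gain of the systemic time course in short channels.
#' @param optics Named list: `wavelengths` (nm), `extinction` (2x2 matrix,
#'   rows = wavelengths, cols = HbO/HbR, in 1/(cm*microM)), `dpf`,
#'   `dist_long`, `dist_short` (cm).
#' @param hrf Named list of HRF parameters for [hrf_double_gamma()].
#' @param hbr_ratio Evoked \eqn{\Delta}HbR amplitude as a (negative)
#'   fraction of \eqn{\Delta}HbO.
#' @param seed Base seed of the study.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 14,
                              conditions = c("pre", "MM30", "MM60", "MM90",
                                             "PM30", "PM60", "PM90"),
                              fs_raw = 10,
                              amplitudes = default_amplitudes(),
                              class_separation = 1,
                              morphine_attenuation = 0.4,
                              attenuated_rois = c("L FPA", "R FPA"),
                              noise = list(cardiac = 0.4, respiration = 0.3,
                                           mayer = 0.4, white = 0.3, drift = 1.0),
                              motion = list(rate = 0.01, spike_amp = 8,
                                            step_amp = 2, spike_tau = 0.4),
                              short_coupling = 1.0,
                              optics = default_optics(),
                              hrf = list(peak = 6, undershoot = 16, ratio = 1 / 6),
                              hbr_ratio = -0.3,
                              seed = 1L) {
  cond_ok <- c("pre", "MM30", "MM60", "MM90", "PM30", "PM60", "PM90")
  if (!all(conditions %in% cond_ok)) {
    stopf("unknown condition(s): %s", paste(setdiff(conditions, cond_ok), collapse = ", "))
  }
  assert_scalar_pos(fs_raw, "fs_raw")
  if (fs_raw <= 2 * 1.1) stopf("fs_raw must exceed twice the cardiac frequency")
  if (!all(is.finite(c(amplitudes$pain, amplitudes$nonpain)))) {
    stopf("amplitude table must be finite")
  }
  if (all(abs(amplitudes$pain - amplitudes$nonpain) < 1e-12) && class_separation != 0) {
    stopf("amplitude table must separate classes in at least one ROI")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), conditions = conditions,
      fs_raw = fs_raw, amplitudes = amplitudes,
      class_separation = class_separation,
      morphine_attenuation = morphine_attenuation,
      attenuated_rois = attenuated_rois,
      noise = noise, motion = motion, short_coupling = short_coupling,
      optics = optics, hrf = hrf, hbr_ratio = hbr_ratio,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Default optical forward-model constants
#'
#' Two-wavelength (760/850 nm) extinction coefficients for HbO and HbR in
#' 1/(cm*microM), a differential pathlength factor of 6 at both wavelengths
#' and source-detector separations of 3 cm (long) and 0.8 cm (short).
#' @return Named list used by the simulator and the Beer-Lambert inversion.
#' @export
default_optics <- function() {
  list(
    wavelengths = c(760, 850),
    extinction = matrix(c(1.486e-3, 3.843e-3,
                          2.526e-3, 1.798e-3),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("760", "850"), c("HbO", "HbR"))),
    dpf = c(6, 6),
    dist_long = 3,
    dist_short = 0.8
  )
}

# Per-(label, roi, condition) evoked amplitude in microM.
response_amplitude <- function(config, label, roi, condition) {
  tab <- config$amplitudes
  i <- match(roi, tab$roi)
  base_non <- tab$nonpain[i]
  base_pain <- base_non + config$class_separation * (tab$pain[i] - base_non)
  amp <- if (label == "pain") base_pain else base_non
  if (label == "pain" && grepl("^MM", condition) && roi %in% config$attenuated_rois) {
    amp <- amp * config$morphine_attenuation
  }
  amp
}

# Stimulus-locked regressor: boxcar of event durations convolved with the HRF.
hrf_regressor <- function(protocol, fs, n, hrf_pars, labels = c("pain", "non-pain")) {
  box <- numeric(n)
  ev <- protocol$events
  for (k in seq_len(nrow(ev))) {
    if (!ev$label[k] %in% labels) next
    i0 <- floor(ev$onset[k] * fs) + 1L
    i1 <- min(n, floor((ev$onset[k] + ev$duration[k]) * fs))
    if (i0 <= n) box[i0:i1] <- 1
  }
  h <- hrf_double_gamma(seq(0, 32, by = 1 / fs),
                        peak = hrf_pars$peak, undershoot = hrf_pars$undershoot,
                        ratio = hrf_pars$ratio)
  y <- stats::convolve(box, rev(h), type = "open")[seq_len(n)]
  m <- max(abs(y))
  if (m > 0) y / m else y
}

#' Simulate one raw fNIRS scan
#'
#' Produces raw two-wavelength light-intensity time series for every long
#' and short channel of `layout` under the given stimulation protocol and
#' drug condition. Long channels carry stimulus-locked HRF-convolved
#' responses whose amplitude is looked up per (class, ROI, condition),
#' plus shared systemic physiology, drift, white noise and sparse motion
#' artifacts; short channels carry the systemic components only. Hemoglobin
#' concentration changes are mapped to intensity through the modified
#' Beer-Lambert forward model, so the full measurement chain can be
#' inverted by the preprocessing module. A noiseless per-channel
#' \eqn{\Delta}HbO ground-truth sidecar is attached for recovery tests.
#'
#' @param config A [simulation_config()].
#' @param layout A [make_layout()] montage.
#' @param protocol A [make_protocol()] event list.
#' @param subject Subject identifier (integer).
#' @param condition One of the configured conditions.
#' @param seed Integer seed; identical seeds give bit-identical scans.
#' @return An object of class `raw_scan`.
#' @export
simulate_scan <- function(config, layout, protocol, subject = 1L,
                          condition = "pre", seed = 1L) {
  if (!condition %in% config$conditions) {
    stopf("condition '%s' not in config$conditions", condition)
  }
  fs <- config$fs_raw
  n <- as.integer(round(protocol$session_length * fs))
  nl <- layout$n_long
  ns <- layout$n_short
  nc <- nl + ns
  t_axis <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    # evoked ground truth per long channel (noiseless dHbO, microM)
    reg_pain <- hrf_regressor(protocol, fs, n, config$hrf, "pain")
    reg_non <- hrf_regressor(protocol, fs, n, config$hrf, "non-pain")
    truth <- matrix(0, n, nl)
    rois <- layout$channels$roi[layout$channels$kind == "long"]
    for (j in seq_len(nl)) {
      truth[, j] <-
        response_amplitude(config, "pain", rois[j], condition) * reg_pain +
        response_amplitude(config, "non-pain", rois[j], condition) * reg_non
    }

    # shared systemic physiology (one time course, channel-specific gains)
    nz <- config$noise
    phase <- stats::runif(4, 0, 2 * pi)
    systemic <- nz$cardiac * sin(2 * pi * 1.1 * t_axis + phase[1]) +
      nz$respiration * sin(2 * pi * 0.25 * t_axis + phase[2]) +
      nz$mayer * sin(2 * pi * 0.1 * t_axis + phase[3])
    drift_course <- nz$drift * scale_unit(stats::filter(
      stats::rnorm(n), rep(1 / (fs * 20), fs * 20), sides = 1
    ))
    gains <- stats::runif(nc, 0.8, 1.2)

    dHbO <- matrix(0, n, nc)
    dHbR <- matrix(0, n, nc)
    for (j in seq_len(nc)) {
      is_long <- j <= nl
      gain <- if (is_long) gains[j] else config$short_coupling * gains[j]
      sys_j <- gain * (systemic + drift_course)
      evoked <- if (is_long) truth[, j] else 0
      white <- nz$white * stats::rnorm(n)
      dHbO[, j] <- evoked + sys_j + white
      dHbR[, j] <- config$hbr_ratio * evoked + 0.3 * sys_j +
        nz$white * 0.5 * stats::rnorm(n)
    }

    # sparse motion artifacts: exponential spikes and step offsets
    mo <- config$motion
    if (mo$rate > 0) {
      for (j in seq_len(nc)) {
        k <- stats::rpois(1, mo$rate * protocol$session_length)
        if (k > 0) {
          at <- sample.int(n, k)
          for (a in at) {
            if (stats::runif(1) < 0.5) {
              idx <- a:min(n, a + ceiling(5 * mo$spike_tau * fs))
              shape <- exp(-(idx - a) / (mo$spike_tau * fs))
              amp <- mo$spike_amp * sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
              dHbO[idx, j] <- dHbO[idx, j] + amp * shape
              dHbR[idx, j] <- dHbR[idx, j] + 0.3 * amp * shape
            } else {
              amp <- mo$step_amp * sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
              dHbO[a:n, j] <- dHbO[a:n, j] + amp
              dHbR[a:n, j] <- dHbR[a:n, j] + 0.3 * amp
            }
          }
        }
      }
    }

    # modified Beer-Lambert forward model -> intensity per wavelength
    op <- config$optics
    dist <- ifelse(seq_len(nc) <= nl, op$dist_long, op$dist_short)
    intensity <- array(0, c(n, nc, 2))
    for (w in 1:2) {
      od <- (op$extinction[w, "HbO"] * dHbO + op$extinction[w, "HbR"] * dHbR) *
        rep(dist * op$dpf[w], each = n)
      intensity[, , w] <- exp(-od)   # I0 = 1 arbitrary unit
    }

    structure(
      list(
        intensity = intensity, fs = fs, layout = layout, protocol = protocol,
        condition = condition, subject = as.integer(subject),
        ground_truth = truth, seed = as.integer(seed)
      ),
      class = "raw_scan"
    )
  })
}

scale_unit <- function(x) {
  x <- as.numeric(x)
  x[is.na(x)] <- 0
  s <- stats::sd(x)
  if (s > 0) (x - mean(x)) / s else x
}

#' Simulate a complete drug study
#'
#' Convenience wrapper generating every scan of the study design: two
#' pre-drug sessions per subject (one per site visit) and one scan per
#' post-drug condition per subject.
#'
#' @param config A [simulation_config()].
#' @param layout,protocol Montage and protocol shared by all scans; the
#'   protocol's label order is re-randomized per scan from the study seed.
#' @param seed Study-level seed.
#' @return Named list of scan lists: `pre` (2 x n_subjects scans) and one
#'   entry per post-drug condition (n_subjects scans each).
#' @export
simulate_study <- function(config, layout = make_layout(),
                           protocol = make_protocol(), seed = config$seed) {
  out <- list()
  n_per_class <- nrow(protocol$events) / 2L
  make_p <- function(s) {
    make_protocol(n_per_class, protocol$stim_dur, protocol$rest, seed = s)
  }
  if ("pre" %in% config$conditions) {
    out$pre <- list()
    for (subj in seq_len(config$n_subjects)) {
      for (sess in 1:2) {
        s <- derive_seed(seed, "pre", subj, sess)
        out$pre[[length(out$pre) + 1L]] <-
          simulate_scan(config, layout, make_p(s), subj, "pre", seed = s)
      }
    }
  }
  for (cond in setdiff(config$conditions, "pre")) {
    out[[cond]] <- list()
    for (subj in seq_len(config$n_subjects)) {
      s <- derive_seed(seed, cond, subj)
      out[[cond]][[subj]] <-
        simulate_scan(config, layout, make_p(s), subj, cond, seed = s)
    }
  }
  out
}

#' @export
print.raw_scan <- function(x, ...) {
  cat(sprintf("<raw_scan> subject %d, condition %s: %d samples x %d channels x 2 wavelengths @ %g Hz\n",
              x$subject, x$condition, dim(x$intensity)[1], dim(x$intensity)[2], x$fs))
  invisible(x)
}
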