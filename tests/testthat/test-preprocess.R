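test_that("optical density conversion is exact and shape preserving", {
  l <- make_layout(2, 1, data.frame(channel = 1:2, roi = c("R SI", "R MI")))
  n <- 200
  # constant intensity -> all-zero OD
  s <- structure(list(intensity = array(2.5, c(n, 3, 2)), fs = 10, layout = l),
                 class = "raw_scan")
  od <- intensity_to_od(s)
  expect_equal(dim(od$od), c(n, 3, 2))
  expect_true(all(abs(od$od) < 1e-12))
  # I = I0 exp(-x) -> OD recovers x up to its baseline offset
  x <- sin(seq(0, 6 * pi, length.out = n)) * 0.1
  s$intensity[, 1, 1] <- 3 * exp(-x)
  od <- intensity_to_od(s)
  xc <- x - mean(x)
  odc <- od$od[, 1, 1] - mean(od$od[, 1, 1])
  expect_lt(max(abs(odc - xc)), 1e-9)
  # non-positive intensity is refused with location
  s$intensity[17, 2, 1] <- 0
  expect_error(intensity_to_od(s), "sample 17, channel 2")
})

test_that("db5 transform reconstructs perfectly", {
  set.seed(42)
  for (n in c(257, 1000, 4096)) {
    x <- rnorm(n)
    w <- fnirspain:::dwt_db5(x, 4)
    expect_lt(max(abs(fnirspain:::idwt_db5(w) - x)), 1e-9)
  }
  expect_error(fnirspain:::dwt_db5(rnorm(5), 2), "too short")
})

test_that("wavelet correction spares clean signal and crushes spikes", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  x <- sin(2 * pi * 0.05 * t)
  w <- correct_motion_wavelet(tone_od(x), 1.5)
  expect_lt(sqrt(mean((w$od[, 1, 1] - x)^2)) / sqrt(mean(x^2)), 0.01)
  # single large spike mostly removed
  xs <- x
  k <- 3000
  xs[k] <- xs[k] + 20 * sd(x)
  ws <- correct_motion_wavelet(tone_od(xs), 1.5)
  resid <- max(abs(ws$od[(k - 20):(k + 20), 1, 1] - x[(k - 20):(k + 20)]))
  expect_lt(resid, 0.2 * (20 * sd(x)))
  # infinite fence factor is the identity
  wi <- correct_motion_wavelet(tone_od(xs), Inf)
  expect_identical(wi$od[, 1, 1], xs)
})

test_that("PCA correction removes a dominating shared artifact", {
  set.seed(3)
  n <- 500
  base <- matrix(rnorm(n * 4, sd = 0.1), n, 4)
  artifact <- numeric(n)
  artifact[200:260] <- 8
  X <- base + artifact
  od <- structure(list(od = array(X, c(n, 2, 2)), fs = 10, layout = NULL),
                  class = "od_scan")
  out <- correct_motion_pca(od, 0.8)
  Y <- matrix(out$od, n, 4)
  expect_gt(out$pca_removed, 0)
  # compare mean-centred residuals: the DC offset of the pulse goes to the
  # band-pass stage, not to PCA
  ctr <- function(M) sweep(M, 2, colMeans(M))
  e_before <- sum(ctr(X - base)^2)
  e_after <- sum(ctr(Y - base)^2)
  expect_lt(e_after, 0.1 * e_before)
  # residual orthogonal to the removed component scores
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  Yc <- sweep(Y, 2, colMeans(Y))
  ip <- abs(t(sv$u[, 1]) %*% Yc)
  expect_lt(max(ip) / sqrt(sum(Yc^2)), 1e-10)
  # when no single component dominates, the stage is an identity
  od2 <- structure(list(od = array(matrix(rnorm(n * 4), n, 4), c(n, 2, 2)),
                        fs = 10, layout = NULL), class = "od_scan")
  out2 <- correct_motion_pca(od2, 0.8)
  expect_equal(out2$od, od2$od, tolerance = 1e-12)
  # degenerate constant data is refused
  odc <- structure(list(od = array(1, c(50, 2, 2)), fs = 10, layout = NULL),
                   class = "od_scan")
  expect_error(correct_motion_pca(odc, 0.8), "degenerate")
})

test_that("band-pass keeps the hemodynamic band and rejects physiology", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  mid <- 2000:4000
  tone <- function(f) sin(2 * pi * f * t)
  g <- function(f) {
    y <- bandpass(tone_od(tone(f)))$od[, 1, 1]
    sd(y[mid]) / sd(tone(f)[mid])
  }
  expect_gt(g(0.03), 0.95)   # passband
  expect_lt(g(1.0), 0.01)    # cardiac band
  # DC offset removed
  y <- bandpass(tone_od(tone(0.03) + 5))$od[, 1, 1]
  expect_lt(abs(mean(y[mid])), 0.02)
  # idempotence: filtering twice barely changes the result
  once <- bandpass(tone_od(tone(0.03)))
  twice <- bandpass(once)
  expect_lt(sqrt(mean((twice$od[mid, 1, 1] - once$od[mid, 1, 1])^2)) /
              sqrt(mean(once$od[mid, 1, 1]^2)), 0.01)
  expect_error(bandpass(tone_od(tone(0.03)), low = 0.01, high = 6), "fs/2")
})

test_that("Beer-Lambert inversion is the exact inverse of the forward model", {
  l <- make_layout(2, 1, data.frame(channel = 1:2, roi = c("R SI", "R MI")))
  op <- default_optics()
  n <- 300
  set.seed(8)
  hbo <- matrix(rnorm(n * 3), n, 3)
  hbr <- matrix(rnorm(n * 3), n, 3)
  dist <- c(op$dist_long, op$dist_long, op$dist_short)
  od <- array(0, c(n, 3, 2))
  for (w in 1:2) {
    od[, , w] <- (op$extinction[w, "HbO"] * hbo + op$extinction[w, "HbR"] * hbr) *
      rep(dist * op$dpf[w], each = n)
  }
  ods <- structure(list(od = od, fs = 10, layout = l), class = "od_scan")
  h <- od_to_hemoglobin(ods, op)
  expect_lt(max(abs(h$dHbO - hbo)), 1e-9)
  expect_lt(max(abs(h$dHbR - hbr)), 1e-9)
  # zero OD -> zero concentrations
  ods0 <- structure(list(od = array(0, c(n, 3, 2)), fs = 10, layout = l),
                    class = "od_scan")
  h0 <- od_to_hemoglobin(ods0, op)
  expect_true(all(h0$dHbO == 0) && all(h0$dHbR == 0))
  # linearity: superposition holds to machine precision
  odsA <- ods; odsA$od <- od * 0.3
  odsB <- ods; odsB$od <- od * -1.7
  odsS <- ods; odsS$od <- od * 0.3 + od * -1.7
  hs <- od_to_hemoglobin(odsS, op)
  hl <- od_to_hemoglobin(odsA, op)$dHbO + od_to_hemoglobin(odsB, op)$dHbO
  expect_lt(max(abs(hs$dHbO - hl)), 1e-12)
  # doubling distance halves concentrations
  op2 <- op
  op2$dist_long <- 2 * op$dist_long
  op2$dist_short <- 2 * op$dist_short
  h2 <- od_to_hemoglobin(ods, op2)
  expect_equal(h2$dHbO, hbo / 2, tolerance = 1e-9)
  # singular extinction matrix is refused
  opS <- op
  opS$extinction <- matrix(c(1, 2, 2, 4), 2, byrow = TRUE,
                           dimnames = dimnames(op$extinction))
  expect_error(od_to_hemoglobin(ods, opS), "singular")
})

make_hemo <- function(L, S) {
  l <- make_layout(1, 1, data.frame(channel = 1, roi = "R SI"))
  structure(list(dHbO = cbind(L, S), dHbR = cbind(L, S) * 0, fs = 1,
                 layout = l, filtered = TRUE, short_regressed = FALSE),
            class = "hemo_scan")
}

test_that("short-channel regression matches its closed-form contracts", {
  set.seed(5)
  S <- rnorm(400)
  # exact collinearity
  res <- short_channel_regress(make_hemo(2 * S, S))
  expect_equal(res$record$beta, 2, tolerance = 1e-12)
  expect_lt(max(abs(res$scan$dHbO[, 1])), 1e-10)
  # orthogonal L -> beta = 0, L unchanged
  L <- rnorm(400)
  L <- L - sum(L * S) / sum(S * S) * S
  res <- short_channel_regress(make_hemo(L, S))
  expect_lt(abs(res$record$beta), 1e-12)
  expect_equal(res$scan$dHbO[, 1], L, tolerance = 1e-12)
  # all-zero short channel is refused
  expect_error(short_channel_regress(make_hemo(L, S * 0)), "all zero")
})

test_that("the printed normal-equation estimator agrees with a generic
           least-squares oracle over many random pairs", {
  set.seed(11)
  worst_beta <- 0
  worst_orth <- 0
  for (i in 1:200) {
    S <- rnorm(100)
    L <- rnorm(100, sd = runif(1, 0.1, 10))
    res <- short_channel_regress(make_hemo(L, S))
    oracle <- unname(coef(lm(L ~ 0 + S)))
    worst_beta <- max(worst_beta, abs(res$record$beta - oracle))
    Lp <- res$scan$dHbO[, 1]
    worst_orth <- max(worst_orth,
                      abs(sum(S * Lp)) / (sqrt(sum(S^2)) * sqrt(sum(Lp^2))))
  }
  expect_lt(worst_beta, 1e-8)
  expect_lt(worst_orth, 1e-10)
})

test_that("the full chain recovers evoked hemodynamics from a clean scan", {
  l <- fix_layout()
  p <- make_protocol(6, 5, 25, seed = 2)
  cfg <- simulation_config(
    noise = list(cardiac = 0.4, respiration = 0.3, mayer = 0.4, white = 0,
                 drift = 1.0),
    motion = list(rate = 0, spike_amp = 0, step_amp = 0, spike_tau = 0.4)
  )
  s <- simulate_scan(cfg, l, p, 1, "pre", seed = 5)
  # the scan carries no motion artifacts, so the motion-PCA stage is
  # disabled: on artifact-free data it would remove the global component,
  # evoked common mode included (see the methods vignette)
  pp <- preprocess_params()
  pp$pca_var <- 0
  h <- quiet_preprocess(s, pp)
  bf <- signal::butter(3, c(0.01, 0.1) / (s$fs / 2), type = "pass")
  cors <- vapply(seq_len(l$n_long), function(j) {
    gt <- signal::filtfilt(bf, s$ground_truth[, j])
    cor(h$dHbO[, j], gt)
  }, numeric(1))
  expect_gt(min(cors), 0.95)
  expect_gt(median(cors), 0.98)
  expect_true(isTRUE(h$short_regressed))
  expect_equal(nrow(attr(h, "regression")), l$n_long)
})

test_that("preprocessing order is fixed and the chain is deterministic", {
  l <- fix_layout()
  p <- make_protocol(2, 5, 25, seed = 2)
  s <- simulate_scan(simulation_config(), l, p, 1, "pre", seed = 5)
  bad <- preprocess_params()
  bad$stages <- rev(bad$stages)
  expect_error(preprocess_scan(s, bad), "fixed")
  a <- quiet_preprocess(s)
  b <- quiet_preprocess(s)
  expect_identical(a$dHbO, b$dHbO)
})
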