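#' Shapley-style attribution of decoder outputs
#'
#' DeepSHAP-type attribution: DeepLIFT rescale-rule multipliers are
#' backpropagated from the sigmoid probability output to every input
#' feature, and contributions are averaged over a background sample drawn
#' from the training data. Elementwise nonlinearities (ReLU, sigmoid) use
#' the rescale slope `(f(x) - f(r)) / (x - r)`; max-pooling is decomposed
#' as `max(a, b) = a + relu(b - a)` so the rescale rule applies there too,
#' which makes the local-accuracy identity
#' `sum(phi) = f(x) - mean_r f(r)` hold to machine precision for every
#' attributed trial.
#'
#' @param model A `trained_decoder` (or a [linear_surrogate()] for
#'   closed-form verification).
#' @param background A `trial_set` drawn from the model's training data.
#' @param test A `trial_set` of trials to attribute.
#' @param background_size Number of background trials sampled (seeded).
#' @param seed Seed for the background draw.
#' @param ... Passed to methods.
#' @return An `attribution_set`: `phi` (n_test x T x C), `fx` (model
#'   output per test trial), `f0` (mean model output over the background),
#'   background bookkeeping and model provenance.
#' @export
shap_attribute <- function(model, background, test, background_size = 100,
                           seed = 1, ...) {
  UseMethod("shap_attribute")
}

pick_background <- function(background, background_size, seed) {
  n <- dim(background$data)[1]
  if (n == 0) stopf("empty background set")
  k <- min(background_size, n)
  idx <- with_seed(seed, sample.int(n, k))
  background$data[idx, , , drop = FALSE]
}

# Rescale slope with a derivative fallback where x ~= r.
rescale_slope <- function(fx, fr, x, r, fallback) {
  dx <- x - r
  s <- ifelse(abs(dx) > 1e-10, (fx - fr) / dx, fallback)
  s
}

#' @export
shap_attribute.trained_decoder <- function(model, background, test,
                                           background_size = 100, seed = 1, ...) {
  stopifnot(inherits(test, "trial_set"))
  B <- pick_background(background, background_size, seed)
  X <- test$data
  N <- dim(X)[1]
  phi <- array(0, dim(X))
  f0s <- numeric(dim(B)[1])
  fwx <- nn_forward(model$params, X, model$config, train = FALSE)
  for (bi in seq_len(dim(B)[1])) {
    r <- B[bi, , , drop = FALSE]
    fwr <- nn_forward(model$params, r, model$config, train = FALSE)
    f0s[bi] <- fwr$p
    phi <- phi + deeplift_multipliers(model, fwx, fwr, X, r)
  }
  phi <- phi / dim(B)[1]
  structure(
    list(phi = phi, fx = fwx$p, f0 = mean(f0s),
         background = list(size = dim(B)[1], seed = seed),
         provenance = model$provenance),
    class = "attribution_set"
  )
}

# Propagate rescale multipliers from output to input for one reference.
# Returns per-feature contributions m * (x - r), an N x T x C array.
deeplift_multipliers <- function(model, fwx, fwr, X, r) {
  params <- model$params
  cx <- fwx$cache
  cr <- fwr$cache
  N <- cx$N
  # output sigmoid
  zx <- as.numeric(cx$z)
  zr <- rep(as.numeric(cr$z), N)
  px <- as.numeric(cx$p)
  pr <- rep(as.numeric(cr$p), N)
  m <- matrix(rescale_slope(px, pr, zx, zr, px * (1 - px)), N, 1)
  # dense head (eval mode: no dropout)
  m_H <- m %*% t(params$W5)
  Z4r_b <- bc2(cr$Z4, N)
  s4 <- rescale_slope(pmax(cx$Z4, 0), pmax(Z4r_b, 0), cx$Z4, Z4r_b,
                      (cx$Z4 > 0) * 1)
  m_Z4 <- m_H * s4
  m_F <- m_Z4 %*% t(params$W4)
  m_D <- m_F
  dim(m_D) <- cx$d_last
  Ws <- list(params$W1, params$W2, params$W3)
  for (k in 3:1) {
    blx <- cx$blocks[[k]]
    blr <- cr$blocks[[k]]
    Fk <- ncol(Ws[[k]])
    Ax <- pmax(blx$Z, 0); dim(Ax) <- c(N, blx$T_in, Fk)
    Ar <- pmax(blr$Z, 0); dim(Ar) <- c(1, blr$T_in, Fk)
    P <- blx$T_in %/% 2L
    o <- seq(1L, 2L * P - 1L, 2L)
    ux <- Ax[, o + 1L, , drop = FALSE] - Ax[, o, , drop = FALSE]
    ur <- Ar[, o + 1L, , drop = FALSE] - Ar[, o, , drop = FALSE]
    ur_b <- ux; ur_b[] <- rep(ur, each = N)
    s_u <- rescale_slope(pmax(ux, 0), pmax(ur_b, 0), ux, ur_b, (ux > 0) * 1)
    m_A <- array(0, c(N, blx$T_in, Fk))
    m_A[, o, ] <- m_D * (1 - s_u)
    m_A[, o + 1L, ] <- m_D * s_u
    dim(m_A) <- c(N * blx$T_in, Fk)
    Zr_b <- matrix(rep(blr$Z, each = N), N * blx$T_in, Fk)
    s <- rescale_slope(pmax(blx$Z, 0), pmax(Zr_b, 0), blx$Z, Zr_b,
                       (blx$Z > 0) * 1)
    m_Z <- m_A * s
    m_M <- m_Z %*% t(Ws[[k]])
    m_D <- nn_col2im(m_M, N, blx$T_in, blx$C_in)
  }
  m_D * (X - array(rep(r, each = N), dim(X)))
}

# Replicate a 1-row reference cache matrix to N rows (column-major safe).
bc2 <- function(a, N) {
  matrix(rep(a, each = N), N * nrow(a), ncol(a))
}

#' Linear surrogate model for attribution verification
#'
#' A model `f(x) = sum(w * x) + b` (optionally through a sigmoid) whose
#' exact Shapley attribution against a background is the closed form
#' `phi_i = w_i * (x_i - mean_r r_i)`.
#'
#' @param w Weight array (T x C).
#' @param b Intercept.
#' @return A `linear_surrogate` model usable with [shap_attribute()].
#' @export
linear_surrogate <- function(w, b = 0) {
  structure(list(w = w, b = b), class = "linear_surrogate")
}

#' @export
shap_attribute.linear_surrogate <- function(model, background, test,
                                            background_size = 100, seed = 1, ...) {
  B <- pick_background(background, background_size, seed)
  X <- test$data
  N <- dim(X)[1]
  rbar <- apply(B, c(2, 3), mean)
  phi <- array(0, dim(X))
  fx <- numeric(N)
  for (i in seq_len(N)) {
    phi[i, , ] <- model$w * (X[i, , ] - rbar)
    fx[i] <- sum(model$w * X[i, , ]) + model$b
  }
  f0 <- mean(apply(B, 1, function(r) sum(model$w * r) + model$b))
  structure(list(phi = phi, fx = fx, f0 = f0,
                 background = list(size = dim(B)[1], seed = seed),
                 provenance = list(kind = "linear_surrogate")),
            class = "attribution_set")
}

#' Aggregate attributions into per-ROI Shapley contributions
#'
#' For each ROI, the mean of `phi` over all its channels, all time points
#' and all attributed trials: one scalar per ROI, i.e. one row of the
#' runs x ROIs Shapley matrix.
#'
#' @param attr An `attribution_set`.
#' @param layout A `channel_layout` mapping every long channel to an ROI.
#' @return Named numeric vector (one value per ROI in `layout$rois`).
#' @export
aggregate_roi <- function(attr, layout) {
  stopifnot(inherits(attr, "attribution_set"))
  rois_per_channel <- layout$channels$roi[layout$channels$kind == "long"]
  if (dim(attr$phi)[3] != length(rois_per_channel)) {
    stopf("attribution channels (%d) do not match layout long channels (%d)",
          dim(attr$phi)[3], length(rois_per_channel))
  }
  if (anyNA(rois_per_channel)) stopf("unmapped long channel in layout")
  vapply(layout$rois, function(roi) {
    mean(attr$phi[, , rois_per_channel == roi, drop = FALSE])
  }, numeric(1))
}

#' List ROIs with positive mean Shapley contribution
#'
#' @param shapley Either a runs x ROIs matrix (one model) or a named list
#'   of such matrices (one per model).
#' @return data.frame in sign-table layout: one row per model, one column
#'   per ROI, `"+"` where the mean across runs is strictly positive and
#'   `""` otherwise.
#' @export
positive_contributors <- function(shapley) {
  if (is.matrix(shapley)) shapley <- list(model = shapley)
  rois <- colnames(shapley[[1]])
  rows <- lapply(names(shapley), function(nm) {
    mu <- colMeans(shapley[[nm]])
    vals <- ifelse(mu > 0, "+", "")
    df <- as.data.frame(as.list(stats::setNames(vals, rois)),
                        check.names = FALSE, stringsAsFactors = FALSE)
    cbind(data.frame(model = nm, stringsAsFactors = FALSE), df)
  })
  do.call(rbind, rows)
}
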