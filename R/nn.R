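# Vectorized computational core of the 1D convolutional decoder.
#
# The network is small enough (31 x 24 inputs, three conv blocks) that
# batched im2col matrix products through BLAS are fast; no compiled code
# or external framework is needed. Arrays are N x T x C throughout; the
# column-major flatten (n, t) -> n + (t-1) N is used consistently by the
# forward and backward passes.

# Unfold for kernel-length-2 "same" convolution along time: one zero pad
# at the series end, output rows (N*T), columns [x_t, x_{t+1}] per channel.
nn_im2col <- function(X) {
  d <- dim(X)
  N <- d[1]; Tt <- d[2]; C <- d[3]
  Xp <- array(0, c(N, Tt + 1L, C))
  Xp[, seq_len(Tt), ] <- X
  A <- Xp[, seq_len(Tt), , drop = FALSE]
  B <- Xp[, 1L + seq_len(Tt), , drop = FALSE]
  dim(A) <- c(N * Tt, C)
  dim(B) <- c(N * Tt, C)
  cbind(A, B)
}

# Adjoint of nn_im2col.
nn_col2im <- function(dM, N, Tt, C) {
  dA <- dM[, seq_len(C), drop = FALSE]
  dB <- dM[, C + seq_len(C), drop = FALSE]
  dim(dA) <- c(N, Tt, C)
  dim(dB) <- c(N, Tt, C)
  dX <- dA
  if (Tt > 1) {
    dX[, 2:Tt, ] <- dX[, 2:Tt, ] + dB[, 1:(Tt - 1L), , drop = FALSE]
  }
  dX
}

# Max pooling, window 2, stride 2, valid padding (odd tail dropped).
nn_pool <- function(A) {
  d <- dim(A)
  P <- d[2] %/% 2L
  o <- seq(1L, 2L * P - 1L, 2L)
  Ao <- A[, o, , drop = FALSE]
  Ae <- A[, o + 1L, , drop = FALSE]
  win <- Ao >= Ae
  list(out = pmax(Ao, Ae), win = win, T_in = d[2])
}

nn_pool_back <- function(dP, pool) {
  d <- dim(dP)
  P <- d[2]
  dA <- array(0, c(d[1], pool$T_in, d[3]))
  o <- seq(1L, 2L * P - 1L, 2L)
  dA[, o, ] <- dP * pool$win
  dA[, o + 1L, ] <- dP * (1 - pool$win)
  dA
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Time-axis sizes after each conv("same")/pool(2, valid) block.
nn_shapes <- function(Tt) {
  t1 <- Tt %/% 2L
  t2 <- t1 %/% 2L
  t3 <- t2 %/% 2L
  if (t3 < 1L) stopf("input length %d too short for three pooling halvings", Tt)
  c(t1, t2, t3)
}

nn_init <- function(config) {
  f <- config$filters
  sh <- nn_shapes(config$input_T)
  with_seed(config$seed, {
    list(
      W1 = glorot(2L * config$input_C, f[1]), b1 = numeric(f[1]),
      W2 = glorot(2L * f[1], f[2]), b2 = numeric(f[2]),
      W3 = glorot(2L * f[2], f[3]), b3 = numeric(f[3]),
      W4 = glorot(sh[3] * f[3], config$dense), b4 = numeric(config$dense),
      W5 = glorot(config$dense, 1L), b5 = 0
    )
  })
}

drop_mask <- function(dm, rate) {
  if (rate <= 0) return(1)
  array((stats::runif(prod(dm)) >= rate) / (1 - rate), dm)
}

# Forward pass. train = TRUE activates dropout (caller controls RNG).
nn_forward <- function(params, X, config, train = FALSE) {
  rate <- if (train) config$dropout else 0
  N <- dim(X)[1]
  Tt <- dim(X)[2]
  blocks <- vector("list", 3)
  cur <- X
  Ws <- list(params$W1, params$W2, params$W3)
  bs <- list(params$b1, params$b2, params$b3)
  for (k in 1:3) {
    M <- nn_im2col(cur)
    Z <- sweep(M %*% Ws[[k]], 2, bs[[k]], "+")
    A <- pmax(Z, 0)
    dim(A) <- c(N, dim(cur)[2], ncol(Ws[[k]]))
    pool <- nn_pool(A)
    mask <- drop_mask(dim(pool$out), rate)
    D <- pool$out * mask
    blocks[[k]] <- list(M = M, Z = Z, pool = pool, mask = mask,
                        T_in = dim(cur)[2], C_in = dim(cur)[3])
    cur <- D
  }
  Fm <- cur
  dim(Fm) <- c(N, prod(dim(cur)[2:3]))
  Z4 <- sweep(Fm %*% params$W4, 2, params$b4, "+")
  H <- pmax(Z4, 0)
  mask4 <- drop_mask(dim(H), rate)
  Hd <- H * mask4
  z <- Hd %*% params$W5 + params$b5
  p <- 1 / (1 + exp(-z))
  list(p = as.numeric(p),
       cache = list(blocks = blocks, Fm = Fm, Z4 = Z4, H = H, mask4 = mask4,
                    Hd = Hd, z = z, p = p, N = N, d_last = dim(cur)))
}

nn_bce <- function(p, y01) {
  eps <- 1e-12
  -mean(y01 * log(p + eps) + (1 - y01) * log(1 - p + eps))
}

# Backward pass for binary cross-entropy; returns gradients of all
# parameters (conv-stack gradients set to zero when frozen).
nn_backward <- function(params, cache, y01, config, freeze_conv = FALSE) {
  N <- cache$N
  dz <- matrix((cache$p - y01) / N, N, 1)
  gW5 <- t(cache$Hd) %*% dz
  gb5 <- sum(dz)
  dHd <- dz %*% t(params$W5)
  dH <- dHd * cache$mask4
  dZ4 <- dH * (cache$Z4 > 0)
  gW4 <- t(cache$Fm) %*% dZ4
  gb4 <- colSums(dZ4)
  dF <- dZ4 %*% t(params$W4)
  dD <- dF
  dim(dD) <- cache$d_last
  grads <- list(W5 = gW5, b5 = gb5, W4 = gW4, b4 = gb4)
  Ws <- list(params$W1, params$W2, params$W3)
  for (k in 3:1) {
    bl <- cache$blocks[[k]]
    dP <- dD * bl$mask
    dA <- nn_pool_back(dP, bl$pool)
    dim(dA) <- c(N * bl$T_in, ncol(Ws[[k]]))
    dZ <- dA * (bl$Z > 0)
    if (freeze_conv) {
      grads[[paste0("W", k)]] <- 0 * Ws[[k]]
      grads[[paste0("b", k)]] <- numeric(ncol(Ws[[k]]))
    } else {
      grads[[paste0("W", k)]] <- t(bl$M) %*% dZ
      grads[[paste0("b", k)]] <- colSums(dZ)
    }
    if (k > 1 || !freeze_conv) {
      dM <- dZ %*% t(Ws[[k]])
      dD <- nn_col2im(dM, N, bl$T_in, bl$C_in)
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
                      skip = character(0)) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
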