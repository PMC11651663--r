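#' Decoder architecture configuration
#'
#' Three 1D convolutional blocks (kernel length 2, "same" padding, ReLU,
#' max-pooling of width 2, dropout 0.4) with 32/64/128 filters, followed
#' by flatten, a 256-unit ReLU dense layer with dropout and a single
#' sigmoid output. Convolution runs along the time axis with channels as
#' input features; with T = 31 the time axis shrinks 31 -> 15 -> 7 -> 3.
#'
#' @param filters Filter counts of the three conv layers.
#' @param dense Units of the dense layer.
#' @param dropout Dropout rate after each pool and after the dense layer.
#' @param input_T,input_C Input trial shape (time points, channels).
#' @param seed Weight initialization seed.
#' @return A `model_config`.
#' @export
model_config <- function(filters = c(32, 64, 128), dense = 256, dropout = 0.4,
                         input_T = 31, input_C = 24, seed = 1) {
  if (length(filters) != 3 || any(filters < 1)) {
    stopf("`filters` must be three positive counts")
  }
  nn_shapes(input_T)  # errors if too short for three pool halvings
  structure(list(filters = as.integer(filters), dense = as.integer(dense),
                 dropout = dropout, kernel = 2L, pool = 2L,
                 input_T = as.integer(input_T), input_C = as.integer(input_C),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Training schedule configuration
#'
#' Adam with learning rate 1e-4, binary cross-entropy loss, batch size 16,
#' 100 epochs, and a plateau schedule that multiplies the learning rate by
#' 0.01 when the validation loss has not improved by more than `min_delta`
#' for `patience` consecutive epochs, bounded below by `min_lr`.
#'
#' @param lr Initial learning rate.
#' @param factor Plateau reduction factor.
#' @param patience Plateau patience in epochs.
#' @param min_lr Learning-rate floor.
#' @param min_delta Minimum validation-loss improvement that resets the
#'   plateau counter.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of epochs.
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-4, factor = 0.01, patience = 10,
                         min_lr = 1e-6, min_delta = 1e-4,
                         batch_size = 16, epochs = 100) {
  if (!(min_lr > 0 && min_lr <= lr)) stopf("need 0 < min_lr <= lr")
  if (patience < 1) stopf("patience must be >= 1")
  structure(list(lr = lr, factor = factor, patience = as.integer(patience),
                 min_lr = min_lr, min_delta = min_delta,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
            class = "train_config")
}

#' Build an untrained decoder
#'
#' @param config A [model_config()].
#' @return A `trained_decoder` with freshly initialized (Glorot uniform)
#'   weights, `trained = FALSE` provenance.
#' @export
build_model <- function(config = model_config()) {
  structure(
    list(config = config, params = nn_init(config),
         provenance = list(kind = "base", trained = FALSE,
                           condition = NA_character_, seed = config$seed),
         history = NULL),
    class = "trained_decoder"
  )
}

#' Predict decoder scores for a trial set
#'
#' @param model A `trained_decoder` (sigmoid probabilities) or a
#'   [linear_surrogate()] (raw linear scores).
#' @param ts A `trial_set` (or bare N x T x C array).
#' @return Numeric score vector. Dropout is inactive; prediction is
#'   deterministic.
#' @export
predict_decoder <- function(model, ts) {
  UseMethod("predict_decoder")
}

#' @export
predict_decoder.trained_decoder <- function(model, ts) {
  X <- if (inherits(ts, "trial_set")) ts$data else ts
  nn_forward(model$params, X, model$config, train = FALSE)$p
}

#' @export
predict_decoder.linear_surrogate <- function(model, ts) {
  X <- if (inherits(ts, "trial_set")) ts$data else ts
  apply(X, 1, function(x) sum(model$w * x) + model$b)
}

labels_01 <- function(labels) as.numeric(labels > 0)

decoder_fit <- function(model, split, tc, seed, freeze_conv = FALSE) {
  Xtr <- split$train$data
  ytr <- labels_01(split$train$labels)
  Xva <- split$validation$data
  yva <- labels_01(split$validation$labels)
  n <- dim(Xtr)[1]
  params <- model$params
  state <- adam_init(params)
  lr <- tc$lr
  best <- Inf
  wait <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_loss = numeric(0), acc = numeric(0),
                     val_acc = numeric(0), lr = numeric(0))
  skip <- if (freeze_conv) c("W1", "b1", "W2", "b2", "W3", "b3") else character(0)
  with_seed(seed, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      accs <- numeric(0)
      for (start in seq(1, n, by = tc$batch_size)) {
        idx <- ord[start:min(n, start + tc$batch_size - 1L)]
        Xb <- Xtr[idx, , , drop = FALSE]
        yb <- ytr[idx]
        fw <- nn_forward(params, Xb, model$config, train = TRUE)
        if (!all(is.finite(fw$p))) stopf("NaN/Inf in forward pass: training aborted")
        loss <- nn_bce(fw$p, yb)
        if (!is.finite(loss)) stopf("NaN loss at epoch %d: training aborted", epoch)
        grads <- nn_backward(params, fw$cache, yb, model$config, freeze_conv)
        upd <- adam_step(params, grads, state, lr, skip = skip)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, loss)
        accs <- c(accs, mean((fw$p > 0.5) == yb))
      }
      pv <- nn_forward(params, Xva, model$config, train = FALSE)$p
      val_loss <- nn_bce(pv, yva)
      val_acc <- mean((pv > 0.5) == yva)
      hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                     val_loss = val_loss, acc = mean(accs),
                                     val_acc = val_acc, lr = lr))
      # reduce-on-plateau
      if (val_loss < best - tc$min_delta) {
        best <- val_loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience && lr > tc$min_lr) {
          lr <- max(lr * tc$factor, tc$min_lr)
          wait <- 0L
        }
      }
    }
  })
  model$params <- params
  model$history <- hist
  model$provenance$trained <- TRUE
  model
}

#' Train the base (pre-drug) decoder
#'
#' @param model A `trained_decoder` from [build_model()].
#' @param split A [split_trials()] result whose training partition has
#'   been augmented; validation and test stay untouched.
#' @param tc A [train_config()].
#' @param seed Seed for batch shuffling and dropout.
#' @return The trained `trained_decoder` with its per-epoch history.
#' @export
train_decoder <- function(model, split, tc = train_config(), seed = 1) {
  stopifnot(inherits(model, "trained_decoder"), inherits(split, "data_split"))
  out <- decoder_fit(model, split, tc, seed, freeze_conv = FALSE)
  out$provenance <- list(kind = "base", trained = TRUE,
                         condition = split$train$meta$condition[1] %||% NA,
                         seed = seed)
  out
}

#' Transfer the convolutional stack to a post-drug condition
#'
#' Copies the trained conv-stack weights (first convolution through last
#' max-pooling) from `base` into a fresh model, freezes them, reinitializes
#' the flatten/dense/sigmoid head and trains the head on the post-drug
#' split with the same optimizer schedule. Set `finetune_conv = TRUE` to
#' let the conv stack adapt as well.
#'
#' @param base A trained `trained_decoder`.
#' @param split The post-condition [split_trials()] (training augmented).
#' @param tc A [train_config()].
#' @param seed Seed for head init, shuffling, dropout.
#' @param finetune_conv Unfreeze the transferred conv stack.
#' @return A `trained_decoder` with provenance `kind = "transferred"`.
#' @export
transfer_decoder <- function(base, split, tc = train_config(), seed = 1,
                             finetune_conv = FALSE) {
  stopifnot(inherits(base, "trained_decoder"))
  if (!isTRUE(base$provenance$trained)) {
    warning("transferring from an untrained base model", call. = FALSE)
  }
  if (dim(split$train$data)[2] != base$config$input_T ||
      dim(split$train$data)[3] != base$config$input_C) {
    stopf("post-condition trials do not match the base input shape")
  }
  cfg <- base$config
  cfg$seed <- derive_seed(seed, "head")
  fresh <- build_model(cfg)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    fresh$params[[nm]] <- base$params[[nm]]
  }
  out <- decoder_fit(fresh, split, tc, seed, freeze_conv = !finetune_conv)
  out$provenance <- list(kind = "transferred", trained = TRUE,
                         condition = split$train$meta$condition[1] %||% NA,
                         base_seed = base$provenance$seed, seed = seed,
                         frozen_conv = !finetune_conv)
  out
}

#' Evaluate a decoder on a held-out test set
#'
#' Pain (+1) is the positive class. Accuracy, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP) at the given threshold, and AUC from the rank
#' statistic of the sigmoid scores (Mann-Whitney formulation, ties
#' averaged).
#'
#' @param model A `trained_decoder`.
#' @param test A `trial_set` containing both classes.
#' @param threshold Decision threshold on the sigmoid output.
#' @return A one-row data.frame: `accuracy`, `sensitivity`, `specificity`,
#'   `auc`.
#' @export
evaluate_decoder <- function(model, test, threshold = 0.5) {
  y <- test$labels
  if (length(unique(y)) < 2) {
    stopf("test set contains a single class: sensitivity/specificity undefined")
  }
  p <- predict_decoder(model, test)
  pred <- ifelse(p > threshold, 1L, -1L)
  tp <- sum(pred == 1 & y == 1)
  fn <- sum(pred == -1 & y == 1)
  tn <- sum(pred == -1 & y == -1)
  fp <- sum(pred == 1 & y == -1)
  n1 <- sum(y == 1)
  n0 <- sum(y == -1)
  r <- rank(p)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  data.frame(accuracy = (tp + tn) / length(y),
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             auc = auc)
}

#' Run the full multi-condition decoding experiment
#'
#' For each run: re-split and re-augment the pre-drug trials, train the
#' base decoder, evaluate it on its held-out test set, then transfer the
#' conv stack to every post-drug condition (each with its own split and
#' augmentation), evaluating each transferred model. Optionally computes
#' per-ROI Shapley contributions of every model on its test set.
#'
#' @param datasets Named list of pooled `trial_set`s; must contain `pre`,
#'   other entries are post-drug conditions.
#' @param n_runs Number of repetitions (re-randomized augmentation/splits).
#' @param seed Master seed; all per-run seeds derive from it.
#' @param mc,tc,ac Model, training and augmentation configurations.
#' @param explain Also compute ROI Shapley attributions per run.
#' @param background_size Background sample size for the explainer.
#' @param layout Channel layout (needed when `explain = TRUE`).
#' @param verbose Print one line per model.
#' @return List with `metrics` (data.frame: run, condition, accuracy,
#'   sensitivity, specificity, auc) and, when `explain = TRUE`, `shapley`
#'   (named list per condition of runs x ROIs matrices).
#' @export
run_experiment <- function(datasets, n_runs = 30, seed = 1,
                           mc = model_config(), tc = train_config(),
                           ac = augmentation_config(),
                           explain = FALSE, background_size = 100,
                           layout = NULL, verbose = FALSE) {
  if (!"pre" %in% names(datasets)) stopf("datasets must contain a 'pre' entry")
  conds <- names(datasets)
  metrics <- list()
  shap_rows <- if (explain) stats::setNames(vector("list", length(conds)), conds)
  if (explain && is.null(layout)) stopf("explain = TRUE requires a layout")
  for (r in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, "run", r)
    sp_pre <- split_trials(datasets$pre, seed = derive_seed(run_seed, "pre"))
    ac_r <- ac
    ac_r$seed <- derive_seed(run_seed, "aug", "pre")
    sp_pre$train <- augment_trials(sp_pre$train, ac_r)
    mc_r <- mc
    mc_r$seed <- derive_seed(run_seed, "init")
    base <- build_model(mc_r)
    base <- train_decoder(base, sp_pre, tc, seed = derive_seed(run_seed, "fit"))
    row <- cbind(data.frame(run = r, condition = "pre"),
                 evaluate_decoder(base, sp_pre$test))
    metrics[[length(metrics) + 1L]] <- row
    if (verbose) message(sprintf("run %d pre: acc %.3f", r, row$accuracy))
    if (explain) {
      shap_rows[["pre"]][[r]] <- run_shap_row(base, sp_pre, layout,
                                              background_size, run_seed)
    }
    for (cond in setdiff(conds, "pre")) {
      sp <- split_trials(datasets[[cond]], seed = derive_seed(run_seed, cond))
      ac_c <- ac
      ac_c$seed <- derive_seed(run_seed, "aug", cond)
      sp$train <- augment_trials(sp$train, ac_c)
      post <- transfer_decoder(base, sp, tc, seed = derive_seed(run_seed, "tl", cond))
      row <- cbind(data.frame(run = r, condition = cond),
                   evaluate_decoder(post, sp$test))
      metrics[[length(metrics) + 1L]] <- row
      if (verbose) message(sprintf("run %d %s: acc %.3f", r, cond, row$accuracy))
      if (explain) {
        shap_rows[[cond]][[r]] <- run_shap_row(post, sp, layout,
                                               background_size, run_seed)
      }
    }
  }
  out <- list(metrics = do.call(rbind, metrics))
  if (explain) {
    out$shapley <- lapply(shap_rows, function(rows) do.call(rbind, rows))
  }
  out
}

run_shap_row <- function(model, split, layout, background_size, run_seed) {
  phi <- shap_attribute(model, split$train, split$test,
                        background_size = background_size,
                        seed = derive_seed(run_seed, "shap"))
  aggregate_roi(phi, layout)
}

#' Mean and SD of metrics per condition across runs
#'
#' @param metrics The `metrics` data.frame from [run_experiment()].
#' @return data.frame with one row per condition and `mean`/`sd` columns
#'   per metric, in the usual performance-table layout.
#' @export
summarize_metrics <- function(metrics) {
  conds <- unique(metrics$condition)
  rows <- lapply(conds, function(cond) {
    m <- metrics[metrics$condition == cond, ]
    data.frame(
      condition = cond,
      accuracy_mean = mean(m$accuracy), accuracy_sd = stats::sd(m$accuracy),
      sensitivity_mean = mean(m$sensitivity), sensitivity_sd = stats::sd(m$sensitivity),
      specificity_mean = mean(m$specificity), specificity_sd = stats::sd(m$specificity),
      auc_mean = mean(m$auc), auc_sd = stats::sd(m$auc)
    )
  })
  do.call(rbind, rows)
}

#' @export
print.trained_decoder <- function(x, ...) {
  sh <- nn_shapes(x$config$input_T)
  cat(sprintf("<trained_decoder> %s%s, conv %s (time %d->%d->%d->%d), dense %d\n",
              x$provenance$kind, if (isTRUE(x$provenance$trained)) " (trained)" else " (untrained)",
              paste(x$config$filters, collapse = "/"),
              x$config$input_T, sh[1], sh[2], sh[3], x$config$dense))
  invisible(x)
}
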