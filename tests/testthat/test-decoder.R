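test_that("the network builds with the printed layer plan", {
  mc <- model_config()
  expect_equal(fnirspain:::nn_shapes(31), c(15, 7, 3))
  m <- build_model(mc)
  expect_equal(dim(m$params$W1), c(48, 32))
  expect_equal(dim(m$params$W2), c(64, 64))
  expect_equal(dim(m$params$W3), c(128, 128))
  expect_equal(dim(m$params$W4), c(3 * 128, 256))
  p <- predict_decoder(m, random_trials(3, 31, 24, seed = 1))
  expect_length(p, 3)
  expect_true(all(p > 0 & p < 1))
  # all-zero input still produces a finite probability
  z <- random_trials(1, 31, 24)
  z$data[] <- 0
  expect_true(is.finite(predict_decoder(m, z)))
  # identical init seed -> identical weights
  expect_identical(build_model(mc)$params, build_model(mc)$params)
  expect_error(model_config(input_T = 7), "three pooling halvings")
})

test_that("analytic gradients match finite differences", {
  mc <- model_config(filters = c(3, 4, 5), dense = 6, input_T = 15,
                     input_C = 3, seed = 2)
  m <- build_model(mc)
  set.seed(1)
  X <- array(rnorm(4 * 15 * 3), c(4, 15, 3))
  y <- c(1, 0, 1, 0)
  fw <- fnirspain:::nn_forward(m$params, X, mc, train = FALSE)
  gr <- fnirspain:::nn_backward(m$params, fw$cache, y, mc)
  loss_at <- function(params) {
    fnirspain:::nn_bce(fnirspain:::nn_forward(params, X, mc, train = FALSE)$p, y)
  }
  eps <- 1e-6
  worst <- 0
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(6, length(m$params[[nm]])))
    for (i in idx) {
      up <- m$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      ana <- gr[[nm]][i]
      worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("training solves a linearly separable toy problem", {
  ts <- separable_trials(120, 31, 8, delta = 0.5, noise = 0.1, seed = 3)
  sp <- split_trials(ts, seed = 1)
  mc <- model_config(filters = c(4, 8, 8), dense = 16, input_T = 31,
                     input_C = 8, seed = 1)
  m <- train_decoder(build_model(mc), sp, train_config(lr = 1e-3, epochs = 20),
                     seed = 2)
  expect_equal(tail(m$history$val_acc, 1), 1.0)
  ev <- evaluate_decoder(m, sp$test)
  expect_equal(ev$accuracy, 1.0)
  expect_true(isTRUE(m$provenance$trained))
})

test_that("label-shuffled training stays at chance on held-out data", {
  ts <- separable_trials(200, 31, 8, delta = 0.5, noise = 0.1, seed = 4)
  ts$labels <- fnirspain:::with_seed(9, sample(ts$labels))
  sp <- split_trials(ts, seed = 1)
  mc <- model_config(filters = c(4, 8, 8), dense = 16, input_T = 31,
                     input_C = 8, seed = 1)
  m <- train_decoder(build_model(mc), sp, train_config(lr = 1e-3, epochs = 15),
                     seed = 2)
  ev <- evaluate_decoder(m, sp$test)
  n_test <- length(sp$test$labels)
  se <- 0.5 / sqrt(n_test)
  expect_lt(abs(ev$accuracy - 0.5), 3 * se + 1e-9)
})

test_that("the plateau schedule lands on the learning-rate floor", {
  ts <- separable_trials(40, 31, 4, seed = 5)
  sp <- split_trials(ts, seed = 1)
  mc <- model_config(filters = c(2, 2, 2), dense = 4, input_T = 31,
                     input_C = 4, seed = 1)
  # min_delta so large that no epoch ever counts as an improvement
  tc <- train_config(lr = 1e-4, epochs = 25, min_delta = 10)
  m <- train_decoder(build_model(mc), sp, tc, seed = 2)
  lrs <- m$history$lr
  expect_equal(lrs[1], 1e-4)
  expect_equal(min(lrs), 1e-6)          # 1e-4 * 0.01, and never below
  expect_equal(lrs[12], 1e-6)           # reduction fires after 10 flat epochs
  expect_true(all(diff(lrs) <= 0))
})

test_that("evaluation metrics match a hand-computed confusion table", {
  # craft scores through a linear surrogate reading feature (1,1)
  w <- matrix(0, 2, 1)
  w[1, 1] <- 1
  m <- linear_surrogate(w, b = 0)
  ts <- random_trials(12, 2, 1, seed = 1)
  ts$labels <- c(rep(1L, 6), rep(-1L, 6))
  # TP=5, FN=1, TN=4, FP=2
  ts$data[, 1, 1] <- c(rep(0.9, 5), 0.1, rep(0.1, 4), 0.9, 0.9)
  ev <- evaluate_decoder(m, ts)
  expect_equal(ev$sensitivity, 5 / 6, tolerance = 1e-12)
  expect_equal(ev$specificity, 4 / 6, tolerance = 1e-12)
  expect_equal(ev$accuracy, 0.75, tolerance = 1e-12)
  # perfect and inverted predictors
  ts$data[, 1, 1] <- ifelse(ts$labels == 1, 0.9, 0.1)
  expect_equal(unlist(evaluate_decoder(m, ts)), c(accuracy = 1, sensitivity = 1,
                                                  specificity = 1, auc = 1))
  ts$data[, 1, 1] <- ifelse(ts$labels == 1, 0.1, 0.9)
  ev <- evaluate_decoder(m, ts)
  expect_equal(ev$accuracy, 0)
  expect_equal(ev$auc, 0)
  # single-class test set refused
  one <- ts
  one$labels <- rep(1L, 12)
  expect_error(evaluate_decoder(m, one), "single class")
})

test_that("rank AUC agrees with an independent ROC implementation and is
           invariant to monotone score transforms", {
  set.seed(7)
  ts <- random_trials(40, 2, 1, seed = 2)
  ts$data[, 1, 1] <- rnorm(40) + 0.8 * (ts$labels > 0)
  ts$data[, 2, 1] <- 0
  w <- matrix(c(1, 0), 2, 1)
  auc1 <- evaluate_decoder(linear_surrogate(w), ts)$auc
  roc <- pROC::roc(response = ts$labels, predictor = ts$data[, 1, 1],
                   quiet = TRUE, direction = "<")
  expect_equal(auc1, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  # monotone (affine) transform of the scores leaves AUC unchanged
  auc2 <- evaluate_decoder(linear_surrogate(5 * w, b = -2), ts)$auc
  expect_equal(auc1, auc2, tolerance = 1e-12)
})

test_that("transfer freezes the conv stack bit-identically", {
  base_ts <- separable_trials(80, 31, 6, delta = 0.5, seed = 6)
  sp <- split_trials(base_ts, seed = 1)
  mc <- model_config(filters = c(4, 4, 8), dense = 8, input_T = 31,
                     input_C = 6, seed = 1)
  tc <- train_config(lr = 1e-3, epochs = 8)
  base <- train_decoder(build_model(mc), sp, tc, seed = 2)
  post_ts <- separable_trials(80, 31, 6, delta = 0.4, seed = 8)
  sp2 <- split_trials(post_ts, seed = 2)
  post <- transfer_decoder(base, sp2, tc, seed = 3)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    expect_identical(post$params[[nm]], base$params[[nm]])
  }
  # the head did train
  expect_false(identical(post$params$W5, base$params$W5))
  expect_identical(post$provenance$kind, "transferred")
  # shape mismatch is refused
  sp3 <- split_trials(separable_trials(40, 31, 4, seed = 9), seed = 1)
  expect_error(transfer_decoder(base, sp3, tc), "input shape")
})

test_that("transferring trained knowledge beats an untrained conv stack", {
  mc <- model_config(filters = c(4, 4, 8), dense = 8, input_T = 31,
                     input_C = 6, seed = 1)
  tc <- train_config(lr = 1e-3, epochs = 8)
  base_ts <- separable_trials(80, 31, 6, delta = 0.5, seed = 6)
  base <- train_decoder(build_model(mc), split_trials(base_ts, seed = 1), tc,
                        seed = 2)
  naive <- build_model(mc)
  wins <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    post_ts <- separable_trials(60, 31, 6, delta = 0.25, noise = 0.3,
                                seed = 100 + s)
    sp <- split_trials(post_ts, seed = s)
    acc_t <- evaluate_decoder(transfer_decoder(base, sp, tc, seed = s),
                              sp$test)$accuracy
    acc_u <- evaluate_decoder(
      suppressWarnings(transfer_decoder(naive, sp, tc, seed = s)),
      sp$test)$accuracy
    wins <- wins + (acc_t >= acc_u)
  }
  expect_gte(wins, n_seeds / 2)
})

test_that("the experiment harness produces seeded, bounded metric tables", {
  datasets <- list(
    pre = separable_trials(60, 31, 6, delta = 0.5, seed = 21),
    MM30 = separable_trials(40, 31, 6, delta = 0.3, seed = 22)
  )
  mc <- model_config(filters = c(4, 4, 8), dense = 8, input_T = 31,
                     input_C = 6, seed = 1)
  tc <- train_config(lr = 1e-3, epochs = 5)
  ac <- augmentation_config(factor = 2)
  res <- run_experiment(datasets, n_runs = 2, seed = 5, mc = mc, tc = tc, ac = ac)
  expect_equal(nrow(res$metrics), 4)
  expect_setequal(unique(res$metrics$condition), c("pre", "MM30"))
  num <- as.matrix(res$metrics[, c("accuracy", "sensitivity", "specificity", "auc")])
  expect_true(all(num >= 0 & num <= 1))
  res2 <- run_experiment(datasets, n_runs = 2, seed = 5, mc = mc, tc = tc, ac = ac)
  expect_identical(res$metrics, res2$metrics)
  sm <- summarize_metrics(res$metrics)
  expect_equal(nrow(sm), 2)
})
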