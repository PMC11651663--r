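# Shared fixtures, memoized so expensive simulations run once per session.

.fix_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix_cache)) {
    assign(key, force(expr), envir = .fix_cache)
  }
  get(key, envir = .fix_cache)
}

fix_layout <- function() memo("layout", make_layout())

quiet_preprocess <- function(scan, params = preprocess_params()) {
  suppressWarnings(preprocess_scan(scan, params))
}

# Simulate + preprocess + pool one condition of a small study.
study_trials <- function(conditions = "pre", n_subjects = 4, seed = 7,
                         class_separation = 1) {
  key <- paste("study", paste(conditions, collapse = "+"), n_subjects, seed,
               class_separation, sep = "_")
  memo(key, {
    cfg <- simulation_config(n_subjects = n_subjects, conditions = conditions,
                             class_separation = class_separation)
    study <- simulate_study(cfg, fix_layout(), seed = seed)
    lapply(study, function(scans) {
      pool_sessions(lapply(scans, function(s) extract_trials(quiet_preprocess(s))))
    })
  })
}

# Random labelled trial set without any physiology (for unit tests).
random_trials <- function(n, Tt = 31, C = 24, seed = 1, sd = 1) {
  with_seed <- fnirspain:::with_seed
  with_seed(seed, {
    structure(
      list(data = array(stats::rnorm(n * Tt * C, sd = sd), c(n, Tt, C)),
           labels = rep(c(1L, -1L), length.out = n),
           meta = data.frame(subject = seq_len(n),
                             condition = rep("toy", n),
                             onset = as.numeric(seq_len(n))),
           T = Tt, C = C),
      class = "trial_set"
    )
  })
}

# Linearly separable toy trials: class +1 offset by +delta, class -1 by -delta.
separable_trials <- function(n, Tt = 31, C = 24, delta = 0.5, noise = 0.1,
                             seed = 1) {
  ts <- random_trials(n, Tt, C, seed = seed, sd = noise)
  for (i in seq_len(n)) {
    ts$data[i, , ] <- ts$data[i, , ] + delta * ts$labels[i]
  }
  ts
}

tiny_model_config <- function(Tt = 31, C = 24, seed = 1) {
  model_config(filters = c(8, 16, 32), dense = 64, input_T = Tt, input_C = C,
               seed = seed)
}

fast_train_config <- function(epochs = 15, lr = 1e-3) {
  train_config(lr = lr, epochs = epochs)
}

fast_augmentation <- function(seed = 1) augmentation_config(factor = 5, seed = seed)

# Build a 1-channel od_scan around a plain numeric series (both wavelengths).
tone_od <- function(x, fs = 10) {
  structure(list(od = array(rep(x, 2), c(length(x), 1, 2)), fs = fs,
                 layout = NULL),
            class = "od_scan")
}
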