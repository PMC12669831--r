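# The feed-forward per-timepoint estimator: splitting, gradients, training,
# purity of prediction, determinism and serialization.

test_that("chronological 80/20 split, per trial", {
  tr <- structure(list(data = data.frame(
    t = (0:999) / 100, emg_raw = 0, activation = runif(1000),
    lce = runif(1000, 0.9, 1.1), vce = rnorm(1000), force = runif(1000)
  ), meta = list(f_max = 10, fs = 100)), class = "trial")
  sp <- split_train_validation(tr)
  expect_equal(nrow(sp$train[[1]]$data), 800)
  expect_equal(nrow(sp$validation[[1]]$data), 200)
  expect_lt(max(sp$train[[1]]$data$t), min(sp$validation[[1]]$data$t))
  # multi-trial: boundaries are per trial
  tr2 <- tr; tr2$data <- tr2$data[1:500, ]
  sp2 <- split_train_validation(list(tr, tr2))
  expect_equal(sapply(sp2$train, function(x) nrow(x$data)), c(800, 400))
  expect_equal(sapply(sp2$validation, function(x) nrow(x$data)), c(200, 100))
  for (i in 1:2) {
    expect_lt(max(sp2$train[[i]]$data$t), min(sp2$validation[[i]]$data$t))
  }
  short <- tr; short$data <- short$data[1:3, ]
  expect_error(split_train_validation(short), "too short")
})

test_that("backpropagation gradients match numerical differentiation", {
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3)
  y <- matrix(rnorm(20), ncol = 1)
  for (act in c("relu", "tanh", "sigmoid")) {
    wb <- mlp_init(3, c(4, 3), act, seed = 5)
    g <- mlp_grad(wb, X, y, act)
    flat <- function(wb) c(unlist(wb$W), unlist(wb$b))
    unflat <- function(v) {
      out <- wb; k <- 0
      for (i in seq_along(wb$W)) {
        n <- length(wb$W[[i]])
        out$W[[i]] <- matrix(v[k + 1:n], nrow(wb$W[[i]])); k <- k + n
      }
      for (i in seq_along(wb$b)) {
        n <- length(wb$b[[i]])
        out$b[[i]] <- v[k + 1:n]; k <- k + n
      }
      out
    }
    fn <- function(v) mse_of(unflat(v), X, y, act)
    if (act == "relu") {
      # small forward-difference steps avoid stepping across relu kinks,
      # which Richardson extrapolation's larger steps would do
      num <- numDeriv::grad(fn, flat(wb), method = "simple",
                            method.args = list(eps = 1e-7))
      expect_equal(c(unlist(g$gW), unlist(g$gb)), num, tolerance = 1e-4)
    } else {
      num <- numDeriv::grad(fn, flat(wb))
      expect_equal(c(unlist(g$gW), unlist(g$gb)), num, tolerance = 1e-6)
    }
  }
})

test_that("training on an analytic Hill trial converges and is deterministic", {
  truth <- hill_params(0.12, 6.5, 0.22, 1.5, 4, 0.95)
  trial <- dense_hill_trial(truth, n = 3000, seed = 2)
  cfg <- nn_config(n_repeats = 1, epochs = 150, patience = 30, seed = 4)
  arch <- list(hidden = c(24, 24), activation_fn = "tanh")
  m1 <- search_and_train(trial, cfg, arch = arch)[[1]]
  expect_lt(m1$best_val, 5e-3)
  # identical seeds give identical weights and traces
  m2 <- search_and_train(trial, cfg, arch = arch)[[1]]
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$val_trace, m2$val_trace)
  # training loss replay: stored trace is consistent with definitions
  sp <- split_train_validation(trial)
  va <- build_design(sp$validation, m1$norm_stats)
  replay <- mean((predict(m1, va$X[, 1], sp$validation[[1]]$data$lce[1:nrow(va$X)],
                          sp$validation[[1]]$data$vce[1:nrow(va$X)]) - va$y)^2)
  expect_equal(replay, m1$best_val, tolerance = 1e-9)
})

test_that("random architecture search stays in bounds and selects by validation loss", {
  truth <- hill_params(0.12, 6.5, 0.22, 1.5, 4, 0.95)
  trial <- dense_hill_trial(truth, n = 1200, seed = 3)
  cfg <- nn_config(n_repeats = 2, max_search_evals = 3, epochs = 40,
                   patience = 10, hidden_range = c(5, 40), seed = 8)
  mods <- search_and_train(trial, cfg)
  expect_length(mods, 2)
  for (m in mods) {
    expect_true(length(m$hidden) >= 1 && length(m$hidden) <= 3)
    expect_true(all(m$hidden >= 5 & m$hidden <= 40))
    expect_true(m$activation_fn %in% c("relu", "tanh", "sigmoid"))
    expect_true(is.finite(m$best_val))
  }
})

test_that("prediction is a pure pointwise map", {
  truth <- hill_params(0.12, 6.5, 0.22, 1.5, 4, 0.95)
  trial <- dense_hill_trial(truth, n = 1500, seed = 5)
  m <- search_and_train(trial, nn_config(n_repeats = 1, epochs = 30, seed = 1),
                        arch = list(hidden = 8, activation_fn = "relu"))[[1]]
  set.seed(30)
  a <- runif(50); l <- runif(50, 0.8, 1.2); v <- rnorm(50)
  base <- predict(m, a, l, v)
  perm <- sample(50)
  # tolerance only for BLAS accumulation-order noise; no hidden state
  expect_equal(predict(m, a[perm], l[perm], v[perm]), base[perm],
               tolerance = 1e-12)
  expect_equal(predict(m, rep(0.5, 9), rep(1, 9), rep(0, 9)),
               rep(predict(m, 0.5, 1, 0), 9))
  expect_error(predict(m, a, l[1:10], v), "length mismatch")
})

test_that("models serialize to JSON and back without changing predictions", {
  truth <- hill_params(0.12, 6.5, 0.22, 1.5, 4, 0.95)
  trial <- dense_hill_trial(truth, n = 1000, seed = 6)
  m <- search_and_train(trial, nn_config(n_repeats = 1, epochs = 20, seed = 2),
                        arch = list(hidden = c(7, 5), activation_fn = "tanh"))[[1]]
  path <- withr::local_tempfile(fileext = ".json")
  write_nn_model(m, path)
  m2 <- read_nn_model(path)
  a <- runif(20); l <- runif(20, 0.7, 1.3); v <- rnorm(20)
  expect_equal(predict(m2, a, l, v), predict(m, a, l, v), tolerance = 1e-12)
})
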