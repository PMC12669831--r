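# Per-timepoint feed-forward force estimator: a small fully connected
# regression network mapping (activation, z-scored CE length, z-scored CE
# velocity) at one time point to normalized tendon force at the same time
# point. Training uses mini-batch Adam on the mean squared error with early
# stopping on a validation-loss plateau; hyperparameters (1-3 hidden layers,
# 5-300 nodes each, relu/tanh/sigmoid) are chosen by a seeded random search
# selecting on validation MSE.

act_funs <- list(
  relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
  tanh = list(f = function(z) tanh(z), df = function(z, a) 1 - a^2),
  sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                 df = function(z, a) a * (1 - a))
)

#' Neural network training configuration
#'
#' @param hidden_range node-count bounds per hidden layer.
#' @param max_layers maximum number of hidden layers (1 to 3).
#' @param activations candidate activation functions.
#' @param max_search_evals architecture evaluations per repeat of the
#'   hyperparameter search.
#' @param n_repeats independent repeats of the search (10 for single-trial
#'   training, 5 for large datasets).
#' @param epochs maximum training epochs per candidate.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed master seed.
#' @return object of class `nn_config`.
#' @export
nn_config <- function(hidden_range = c(5, 300), max_layers = 3,
                      activations = c("relu", "tanh", "sigmoid"),
                      max_search_evals = 30, n_repeats = 10,
                      epochs = 200, batch_size = 256, lr = 5e-3,
                      patience = 20, seed = 1L) {
  stopifnot(max_layers >= 1, max_layers <= 3, n_repeats >= 1,
            hidden_range[1] >= 1, hidden_range[2] >= hidden_range[1],
            all(activations %in% names(act_funs)))
  structure(list(hidden_range = hidden_range, max_layers = max_layers,
                 activations = activations,
                 max_search_evals = max_search_evals, n_repeats = n_repeats,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 patience = patience, seed = as.integer(seed)),
            class = "nn_config")
}

mlp_init <- function(n_in, hidden, activation_fn, seed) {
  set.seed(as.integer(seed))
  sizes <- c(n_in, hidden, 1L)
  W <- list(); b <- list()
  for (i in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[i]
    sc <- if (activation_fn == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[i]] <- matrix(stats::rnorm(fan_in * sizes[i + 1]) * sc, fan_in, sizes[i + 1])
    # small random biases avoid exactly-zero pre-activations (relu kink)
    b[[i]] <- 0.01 * stats::rnorm(sizes[i + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(wb, X, activation_fn, keep = FALSE) {
  af <- act_funs[[activation_fn]]
  L <- length(wb$W)
  Zs <- As <- vector("list", L)
  A <- X
  for (i in seq_len(L)) {
    Z <- A %*% wb$W[[i]]
    Z <- Z + rep(wb$b[[i]], each = nrow(Z))
    if (i < L) A <- af$f(Z) else A <- Z  # linear output
    if (keep) { Zs[[i]] <- Z; As[[i]] <- A }
  }
  if (keep) list(out = A, Zs = Zs, As = As) else A
}

mlp_grad <- function(wb, X, y, activation_fn) {
  af <- act_funs[[activation_fn]]
  L <- length(wb$W)
  fw <- mlp_forward(wb, X, activation_fn, keep = TRUE)
  n <- nrow(X)
  delta <- 2 * (fw$out - y) / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (i in L:1) {
    Aprev <- if (i == 1) X else fw$As[[i - 1]]
    gW[[i]] <- crossprod(Aprev, delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      delta <- (delta %*% t(wb$W[[i]])) * af$df(fw$Zs[[i - 1]], fw$As[[i - 1]])
    }
  }
  list(gW = gW, gb = gb, loss = mean((fw$out - y)^2))
}

mse_of <- function(wb, X, y, activation_fn) {
  mean((mlp_forward(wb, X, activation_fn) - y)^2)
}

# Mini-batch Adam with early stopping on validation loss.
mlp_train <- function(X, y, hidden, activation_fn, seed,
                      X_val = NULL, y_val = NULL,
                      epochs = 200, batch_size = 256, lr = 5e-3,
                      patience = 20) {
  y <- matrix(y, ncol = 1)
  if (!is.null(y_val)) y_val <- matrix(y_val, ncol = 1)
  wb <- mlp_init(ncol(X), hidden, activation_fn, seed)
  L <- length(wb$W)
  mW <- vW <- lapply(wb$W, function(w) w * 0)
  mb <- vb <- lapply(wb$b, function(b) b * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  batch_size <- min(batch_size, n)
  steps_per_epoch <- ceiling(n / batch_size)
  t_step <- 0
  best_val <- Inf; best_wb <- wb; stale <- 0
  train_trace <- val_trace <- numeric(0)
  have_val <- !is.null(X_val) && nrow(X_val) > 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1) * batch_size + 1):min(s * batch_size, n)]
      g <- mlp_grad(wb, X[idx, , drop = FALSE], y[idx, , drop = FALSE],
                    activation_fn)
      ep_loss <- ep_loss + g$loss * length(idx)
      t_step <- t_step + 1
      corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
      for (i in seq_len(L)) {
        mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * g$gW[[i]]
        vW[[i]] <- beta2 * vW[[i]] + (1 - beta2) * g$gW[[i]]^2
        wb$W[[i]] <- wb$W[[i]] - lr * (mW[[i]] / corr1) /
          (sqrt(vW[[i]] / corr2) + eps)
        mb[[i]] <- beta1 * mb[[i]] + (1 - beta1) * g$gb[[i]]
        vb[[i]] <- beta2 * vb[[i]] + (1 - beta2) * g$gb[[i]]^2
        wb$b[[i]] <- wb$b[[i]] - lr * (mb[[i]] / corr1) /
          (sqrt(vb[[i]] / corr2) + eps)
      }
    }
    train_trace <- c(train_trace, ep_loss / n)
    if (have_val) {
      vl <- mse_of(wb, X_val, y_val, activation_fn)
      val_trace <- c(val_trace, vl)
      if (vl < best_val - 1e-12) {
        best_val <- vl; best_wb <- wb; stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= patience) break
      }
    } else {
      best_wb <- wb; best_val <- ep_loss / n
    }
  }
  list(wb = best_wb, best_val = best_val,
       train_trace = train_trace, val_trace = val_trace,
       epochs_run = length(train_trace))
}

#' Chronological train/validation split
#'
#' Within each trial the first 80 percent of samples become training data
#' and the last 20 percent validation data, so no training sample is later
#' in time than any validation sample of the same trial. Multi-trial sets
#' are split per trial and pooled.
#'
#' @param trials a trial, list of trials, or `trial_dataset`.
#' @param train_frac training fraction (default 0.8).
#' @return list with `train` and `validation`, each a list of trials whose
#'   `data` is the corresponding chronological slice.
#' @export
split_train_validation <- function(trials, train_frac = 0.8) {
  if (inherits(trials, "trial")) trials <- list(trials)
  if (length(trials) == 0) stop("no trials supplied")
  tr <- lapply(trials, function(x) {
    n <- nrow(x$data)
    if (n < 5) stop("trial too short to split (need >= 5 samples)")
    k <- floor(train_frac * n)
    structure(list(data = x$data[seq_len(k), , drop = FALSE], meta = x$meta),
              class = "trial")
  })
  va <- lapply(trials, function(x) {
    n <- nrow(x$data)
    k <- floor(train_frac * n)
    structure(list(data = x$data[(k + 1):n, , drop = FALSE], meta = x$meta),
              class = "trial")
  })
  list(train = tr, validation = va)
}

# Assemble the (a, z_l, z_v) design matrix and normalized-force target.
# Each trial's force is normalized by its own f_max (from trial meta unless
# overridden).
build_design <- function(trials, stats, f_max = NULL) {
  if (inherits(trials, "trial")) trials <- list(trials)
  st <- stack_trials(trials)
  fm <- if (is.null(f_max)) {
    unlist(lapply(trials, function(tr) rep(tr$meta$f_max, nrow(tr$data))))
  } else rep(f_max, length(st$force))
  z <- apply_norm(st$lce, st$vce, stats)
  list(X = cbind(a = st$a, z_l = z$z_l, z_v = z$z_v),
       y = st$force / fm)
}

sample_architecture <- function(config) {
  n_layers <- sample.int(config$max_layers, 1)
  nodes <- round(exp(stats::runif(n_layers, log(config$hidden_range[1]),
                                  log(config$hidden_range[2]))))
  act <- sample(config$activations, 1)
  list(hidden = nodes, activation_fn = act)
}

#' Hyperparameter search and training
#'
#' For each repeat, runs a seeded random search over architectures
#' (layers, nodes, activation), trains each candidate, selects by
#' validation MSE, and returns the selected trained model. Repeats differ
#' only by their derived seeds. Input normalization statistics are fitted on
#' the training split only and stored with each model.
#'
#' @param trials training material (split 80/20 chronologically per trial).
#' @param config an [nn_config()].
#' @param f_max optional common maximal isometric force; by default each
#'   trial's own `meta$f_max` is used.
#' @param arch optional fixed architecture
#'   `list(hidden =, activation_fn =)`; the search then degenerates to
#'   plain (repeated) training.
#' @return list of `nn_model` objects, one per repeat.
#' @export
search_and_train <- function(trials, config = nn_config(), f_max = NULL,
                             arch = NULL) {
  sp <- split_train_validation(trials)
  st_tr <- stack_trials(sp$train)
  stats <- fit_norm_stats(st_tr$lce, st_tr$vce)
  tr <- build_design(sp$train, stats, f_max)
  va <- build_design(sp$validation, stats, f_max)
  seeds <- derive_seeds(config$seed, config$n_repeats * (config$max_search_evals + 1))
  models <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    base <- (r - 1) * (config$max_search_evals + 1)
    n_eval <- if (is.null(arch)) config$max_search_evals else 1L
    best <- NULL
    for (e in seq_len(n_eval)) {
      s <- seeds[base + e]
      cand <- if (is.null(arch)) {
        set.seed(s)
        sample_architecture(config)
      } else arch
      fit <- mlp_train(tr$X, tr$y, cand$hidden, cand$activation_fn, seed = s,
                       X_val = va$X, y_val = va$y,
                       epochs = config$epochs, batch_size = config$batch_size,
                       lr = config$lr, patience = config$patience)
      if (is.finite(fit$best_val) && (is.null(best) || fit$best_val < best$fit$best_val)) {
        best <- list(cand = cand, fit = fit, seed = s)
      }
    }
    if (is.null(best)) stop("hyperparameter search found no finite-loss model")
    models[[r]] <- structure(list(
      weights = best$fit$wb,
      hidden = best$cand$hidden,
      activation_fn = best$cand$activation_fn,
      norm_stats = stats,
      f_max = f_max,
      train_trace = best$fit$train_trace,
      val_trace = best$fit$val_trace,
      best_val = best$fit$best_val,
      epochs_run = best$fit$epochs_run,
      seed = best$seed
    ), class = "nn_model")
  }
  models
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("Feed-forward force estimator: [%s] %s, validation MSE %.4g (%d epochs)\n",
              paste(x$hidden, collapse = ", "), x$activation_fn,
              x$best_val, x$epochs_run))
  invisible(x)
}

#' Predict normalized force with a trained network
#'
#' Applies the stored training-set normalization statistics to length and
#' velocity and maps each time point independently. Output is the force
#' normalized to F_max, unclipped (negative values are possible and are
#' scored as-is by the metrics).
#'
#' @param object an `nn_model`.
#' @param a activation series.
#' @param lce,vce CE length (L0) and velocity (L0/s) series.
#' @param ... unused.
#' @return normalized force series.
#' @export
predict.nn_model <- function(object, a, lce, vce, ...) {
  n <- length(a)
  if (length(lce) != n || length(vce) != n) stop("input series length mismatch")
  z <- apply_norm(lce, vce, object$norm_stats)
  X <- cbind(a, z$z_l, z$z_v)
  as.numeric(mlp_forward(object$weights, X, object$activation_fn))
}

#' Save / load a trained network (JSON, text only)
#'
#' @param model an `nn_model`.
#' @param path file path.
#' @return `read_nn_model` returns an `nn_model`.
#' @export
write_nn_model <- function(model, path) {
  stopifnot(inherits(model, "nn_model"))
  obj <- list(
    hidden = model$hidden, activation_fn = model$activation_fn,
    norm_stats = unclass(model$norm_stats), f_max = model$f_max,
    best_val = model$best_val, seed = model$seed,
    W = lapply(model$weights$W, function(w) list(dim = dim(w), x = as.numeric(w))),
    b = model$weights$b
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nn_model
#' @export
read_nn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(seq_len(nrow(obj$W)), function(i) {
    matrix(obj$W$x[[i]], obj$W$dim[[i]][1], obj$W$dim[[i]][2])
  })
  b <- if (is.list(obj$b)) obj$b else list(obj$b)
  structure(list(
    weights = list(W = W, b = b),
    hidden = obj$hidden, activation_fn = obj$activation_fn,
    norm_stats = structure(as.list(obj$norm_stats), class = "norm_stats"),
    f_max = obj$f_max, best_val = obj$best_val, seed = obj$seed
  ), class = "nn_model")
}
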