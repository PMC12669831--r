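# Fitting the six Hill model parameters (W, v_max, A_rel, g_max, k_pee,
# l_slack_pee) to recorded trials by CMA-ES, minimizing the mean squared
# error between modeled and measured force on the F_max-normalized scale.
# Scale-disparate positive parameters (W, v_max, A_rel, k_pee) are searched
# in log-space; g_max and l_slack_pee in linear space.

default_hill_init <- function() {
  hill_params(W = 0.2, v_max = 7, A_rel = 0.27, g_max = 1.5,
              k_pee = 3, l_slack_pee = 1.0)
}

default_hill_bounds <- function() {
  list(
    lower = c(W = 0.02, v_max = 1, A_rel = 0.01, g_max = 0.8,
              k_pee = 1e-4, l_slack_pee = 0.7),
    upper = c(W = 0.6, v_max = 20, A_rel = 1, g_max = 2.5,
              k_pee = 50, l_slack_pee = 1.3)
  )
}

# parameter vector <-> search space encoding
.log_idx <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)  # W, v_max, A_rel, g_max, k_pee, l_slack
.par_names <- c("W", "v_max", "A_rel", "g_max", "k_pee", "l_slack_pee")

encode_hill <- function(p) {
  v <- c(p$W, p$v_max, p$A_rel, p$g_max, p$k_pee, p$l_slack_pee)
  ifelse(.log_idx, log(pmax(v, 1e-12)), v)
}

decode_hill <- function(theta) {
  v <- ifelse(.log_idx, exp(theta), theta)
  hill_params(v[1], v[2], v[3], v[4], v[5], v[6])
}

# Stack the relevant columns of a list of trials into plain vectors.
stack_trials <- function(trials) {
  if (inherits(trials, "trial")) trials <- list(trials)
  list(
    a = unlist(lapply(trials, function(tr) tr$data$activation)),
    lce = unlist(lapply(trials, function(tr) tr$data$lce)),
    vce = unlist(lapply(trials, function(tr) tr$data$vce)),
    force = unlist(lapply(trials, function(tr) tr$data$force))
  )
}

#' Mean squared force error of a Hill parameter set
#'
#' Mean over all samples of all trials of
#' `(F_Hill / f_max - F_meas / f_max)^2`.
#'
#' @param params a [hill_params()] object.
#' @param trials a trial, list of trials, or `trial_dataset`.
#' @param f_max maximal isometric force in N.
#' @return scalar MSE on the normalized force scale.
#' @export
mse_objective <- function(params, trials, f_max) {
  st <- stack_trials(trials)
  if (length(st$force) == 0) stop("no trial data supplied")
  pred <- hill_force(st$a, st$lce, st$vce, params, f_max)
  mean(((pred - st$force) / f_max)^2)
}

#' Fit Hill parameters by CMA-ES
#'
#' Minimizes [mse_objective()] over the six parameters. "Iterations" are
#' CMA-ES generations at the default population size
#' `4 + floor(3 log n) = 9`.
#'
#' @param trials trial(s) to fit.
#' @param f_max maximal isometric force in N.
#' @param init initial [hill_params()] (default mid-literature values).
#' @param bounds list with `lower` and `upper` named vectors over the six
#'   parameters (defaults span all values reported for fitted guinea fowl
#'   muscles).
#' @param n_iter CMA-ES generations (default 100).
#' @param seed integer seed.
#' @param sigma0 initial step size in the (partly log-transformed) search
#'   space.
#' @param ftol early-stop objective threshold (default 0 = run all
#'   generations).
#' @return object of class `hill_fit`: `params`, `objective`,
#'   `n_iterations`, `seed`, `trace` (best-so-far objective),
#'   `n_evals`, `converged`.
#' @export
fit_cmaes <- function(trials, f_max, init = default_hill_init(),
                      bounds = default_hill_bounds(), n_iter = 100,
                      seed = 1L, sigma0 = 0.3, ftol = 0) {
  theta0 <- encode_hill(init)
  lo <- ifelse(.log_idx, log(pmax(bounds$lower[.par_names], 1e-12)),
               bounds$lower[.par_names])
  hi <- ifelse(.log_idx, log(bounds$upper[.par_names]),
               bounds$upper[.par_names])
  if (any(theta0 < lo | theta0 > hi)) stop("`init` must lie within `bounds`")
  st <- stack_trials(trials)
  if (length(st$force) == 0) stop("no trial data supplied")
  obj <- function(theta) {
    p <- decode_hill(theta)
    pred <- hill_force(st$a, st$lce, st$vce, p, f_max)
    mean(((pred - st$force) / f_max)^2)
  }
  f0 <- obj(theta0)
  if (n_iter == 0) {
    return(structure(list(params = init, objective = f0, n_iterations = 0L,
                          seed = seed, trace = numeric(0), n_evals = 1L,
                          converged = is.finite(f0)),
                     class = "hill_fit"))
  }
  res <- cma_es(obj, theta0, sigma0 = sigma0, lower = lo, upper = hi,
                n_iter = n_iter, seed = seed, ftol = ftol)
  value <- min(res$value, f0)
  par <- if (res$value <= f0) decode_hill(res$par) else init
  structure(list(params = par, objective = value,
                 n_iterations = length(res$trace), seed = seed,
                 trace = res$trace, n_evals = res$n_evals,
                 converged = is.finite(value)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: objective (normalized-force MSE) = %.3g after %d generations\n",
              x$objective, x$n_iterations))
  print(x$params)
  invisible(x)
}

#' Re-optimize only the force-length width for a second muscle
#'
#' The width of the force-length relationship is muscle specific; starting
#' from a fitted parameter set, only `W` is optimized (one-dimensional
#' CMA-ES in log-space) against the other muscle's trials. All other
#' parameters are provably unchanged.
#'
#' @param base fitted [hill_params()] to start from.
#' @param trials trials of the other muscle.
#' @param f_max maximal isometric force of the other muscle, in N.
#' @param n_iter,seed,sigma0 as in [fit_cmaes()].
#' @param bounds two-element range for W.
#' @return `hill_fit` object.
#' @export
refit_width_only <- function(base, trials, f_max, n_iter = 100, seed = 1L,
                             sigma0 = 0.3, bounds = c(0.02, 0.6)) {
  stopifnot(inherits(base, "hill_params"))
  st <- stack_trials(trials)
  if (length(st$force) == 0) stop("no trial data supplied")
  make_p <- function(W) hill_params(W, base$v_max, base$A_rel, base$g_max,
                                    base$k_pee, base$l_slack_pee)
  obj <- function(theta) {
    pred <- hill_force(st$a, st$lce, st$vce, make_p(exp(theta)), f_max)
    mean(((pred - st$force) / f_max)^2)
  }
  theta0 <- log(min(max(base$W, bounds[1]), bounds[2]))
  f0 <- obj(theta0)
  res <- cma_es(obj, theta0, sigma0 = sigma0, lower = log(bounds[1]),
                upper = log(bounds[2]), n_iter = n_iter, seed = seed,
                lambda = 6L)
  if (f0 <= res$value) {
    W <- exp(theta0); value <- f0
  } else {
    W <- exp(res$par); value <- res$value
  }
  structure(list(params = make_p(W), objective = value,
                 n_iterations = length(res$trace), seed = seed,
                 trace = res$trace, n_evals = res$n_evals,
                 converged = is.finite(value)),
            class = "hill_fit")
}
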