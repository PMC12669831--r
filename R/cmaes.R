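# Covariance matrix adaptation evolution strategy (CMA-ES), the standard
# (mu/mu_w, lambda) formulation with rank-one and rank-mu covariance
# updates, cumulative step-size adaptation, and box constraints handled by
# projection of candidate points onto the feasible box.

#' CMA-ES minimizer
#'
#' @param fn objective function of a numeric vector; must return a finite
#'   scalar (non-finite values are treated as very bad candidates).
#' @param x0 initial mean.
#' @param sigma0 initial global step size.
#' @param lower,upper box bounds (recycled); candidates are projected onto
#'   the box before evaluation.
#' @param lambda population size; default `4 + floor(3 * log(n))`.
#' @param n_iter number of generations.
#' @param seed integer seed; the run is fully reproducible.
#' @param ftol stop early when the best objective falls below this value
#'   (default 0 = never).
#' @return list with `par` (best-seen point), `value`, `trace`
#'   (best-so-far objective per generation), `n_evals`, `lambda`, `seed`.
#' @export
cma_es <- function(fn, x0, sigma0 = 0.3, lower = -Inf, upper = Inf,
                   lambda = NULL, n_iter = 100, seed = 1L, ftol = 0) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  stopifnot(all(lower <= x0), all(x0 <= upper), sigma0 > 0, n_iter >= 0)
  set.seed(as.integer(seed))
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n)
  eig <- eigen(C, symmetric = TRUE)
  B <- eig$vectors; D <- sqrt(pmax(eig$values, 1e-20))
  invsqrtC <- B %*% diag(1 / D, n) %*% t(B)

  best_x <- pmin(pmax(x0, lower), upper)
  best_f <- fn(best_x)
  if (!is.finite(best_f)) best_f <- Inf
  trace <- numeric(0)
  n_evals <- 1L

  for (g in seq_len(n_iter)) {
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                      # ~ N(0, C)
    X <- xmean + sigma * Y
    Xf <- pmin(pmax(X, lower), upper)       # projection onto the box
    f <- apply(Xf, 2, function(x) {
      v <- fn(x); if (is.finite(v)) v else Inf
    })
    n_evals <- n_evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- Xf[, ord[1]]
    }
    sel <- ord[seq_len(mu)]
    # recombination uses the projected (evaluated) points
    xold <- xmean
    xmean <- as.numeric(Xf[, sel, drop = FALSE] %*% w)
    xmean <- pmin(pmax(xmean, lower), upper)
    ydiff <- (xmean - xold) / sigma
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.numeric(invsqrtC %*% ydiff)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ydiff
    artmp <- (Xf[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    B <- eig$vectors; D <- sqrt(pmax(eig$values, 1e-20))
    invsqrtC <- B %*% diag(1 / D, n) %*% t(B)
    trace <- c(trace, best_f)
    if (best_f <= ftol) break
    if (!all(is.finite(C)) || !is.finite(sigma)) break
  }
  list(par = best_x, value = best_f, trace = trace,
       n_evals = n_evals, lambda = lambda, seed = seed)
}
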