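# Two-element Hill-type muscle model: an active contractile element (CE)
# with a parabolic force-length relationship and a hyperbolic force-velocity
# relationship (C1-continuous across v = 0), plus a quadratic parallel
# elastic element (PEE). Lengths and velocities are normalized to optimal
# fiber length L0; forces are scaled by the maximal isometric force F_max.

#' Construct a validated set of Hill model parameters
#'
#' The six free parameters of the model, with the derived continuity factor
#' `c3` that joins the concentric and eccentric branches of the
#' force-velocity curve with matching value and slope at zero velocity.
#'
#' @param W width of the force-length parabola (L0 units); the active force
#'   vanishes at lengths `1 +/- W`.
#' @param v_max maximum shortening velocity (L0/s); the concentric branch
#'   reaches zero force at `v = -v_max`.
#' @param A_rel curvature of the concentric force-velocity hyperbola
#'   (dimensionless; classical values 0.25-0.3).
#' @param g_max asymptotic force amplification during lengthening
#'   (dimensionless; classical values 1.5-1.8).
#' @param k_pee PEE stiffness (F_max per L0^2).
#' @param l_slack_pee PEE slack length (L0 units).
#' @return an object of class `hill_params`.
#' @examples
#' p <- hill_params(W = 0.12, v_max = 6, A_rel = 0.2, g_max = 1.5,
#'                  k_pee = 4, l_slack_pee = 0.95)
#' @export
hill_params <- function(W, v_max, A_rel, g_max, k_pee, l_slack_pee) {
  stopifnot(
    is.numeric(W), W > 0,
    is.numeric(v_max), v_max > 0,
    is.numeric(A_rel), A_rel > 0,
    is.numeric(g_max), g_max > 0,
    is.numeric(k_pee), k_pee >= 0,
    is.numeric(l_slack_pee), l_slack_pee > 0
  )
  p <- list(
    W = W, v_max = v_max, A_rel = A_rel, g_max = g_max,
    k_pee = k_pee, l_slack_pee = l_slack_pee,
    c3 = hill_c3(v_max, A_rel, g_max)
  )
  class(p) <- "hill_params"
  p
}

#' @export
print.hill_params <- function(x, ...) {
  cat("Hill-type muscle model parameters\n")
  cat(sprintf("  W           = %.4g (force-length width, L0)\n", x$W))
  cat(sprintf("  v_max       = %.4g (max shortening velocity, L0/s)\n", x$v_max))
  cat(sprintf("  A_rel       = %.4g (force-velocity curvature)\n", x$A_rel))
  cat(sprintf("  g_max       = %.4g (eccentric force asymptote)\n", x$g_max))
  cat(sprintf("  k_pee       = %.4g (PEE stiffness, F_max/L0^2)\n", x$k_pee))
  cat(sprintf("  l_slack_pee = %.4g (PEE slack length, L0)\n", x$l_slack_pee))
  cat(sprintf("  c3          = %.4g (derived continuity factor)\n", x$c3))
  invisible(x)
}

# Continuity factor: the eccentric branch g(v) = g_max - (g_max - 1)*c3/(v + c3)
# matches the concentric branch in value (g(0) = 1, automatic) and slope.
# Concentric slope at 0-: (1 + 1/A_rel)/v_max; eccentric slope at 0+:
# (g_max - 1)/c3. Equating gives c3 below.
hill_c3 <- function(v_max, A_rel, g_max) {
  (g_max - 1) * A_rel * v_max / (1 + A_rel)
}

#' Active force-length relationship
#'
#' Parabola centred on the optimal fiber length: `f(l) = 1 - ((l - 1)/W)^2`,
#' floored at zero outside `1 +/- W`.
#'
#' @param l CE length in L0 units (vectorized).
#' @param W width of the parabola.
#' @return normalized active force scaling in `[0, 1]`.
#' @export
force_length <- function(l, W) {
  stopifnot(W > 0)
  pmax(0, 1 - ((l - 1) / W)^2)
}

#' Force-velocity relationship
#'
#' Concentric branch (`v <= 0`): the Hill hyperbola
#' `g(v) = (v_max + v) / (v_max - v/A_rel)`, clipped at zero for
#' `v < -v_max`. Eccentric branch (`v > 0`): a hyperbola with asymptote
#' `g_max`, with the derived factor `c3` enforcing continuity of value and
#' slope at `v = 0`.
#'
#' @param v CE velocity in L0/s (vectorized; positive = lengthening).
#' @param v_max,A_rel,g_max see [hill_params()].
#' @return normalized force scaling, `g(0) = 1`.
#' @export
force_velocity <- function(v, v_max, A_rel, g_max) {
  if (v_max <= 0 || A_rel <= 0) stop("`v_max` and `A_rel` must be positive")
  c3 <- hill_c3(v_max, A_rel, g_max)
  g <- numeric(length(v))
  con <- v <= 0
  g[con] <- pmax(0, (v_max + v[con]) / (v_max - v[con] / A_rel))
  if (any(!con)) {
    ve <- v[!con]
    if (g_max > 1) {
      ge <- g_max - (g_max - 1) * c3 / (ve + c3)
    } else {
      # With g_max <= 1 no monotone hyperbola can match the positive
      # concentric slope at v = 0, so slope continuity is unattainable;
      # use a pole-free, value-continuous decay towards g_max instead
      # (fitted eccentric asymptotes slightly below 1 do occur when trials
      # contain little active lengthening).
      c3p <- max(1 - g_max, 1e-6) * A_rel * v_max / (1 + A_rel)
      ge <- g_max + (1 - g_max) * c3p / (ve + c3p)
    }
    g[!con] <- pmax(0, ge)
  }
  g
}

#' Parallel elastic element force
#'
#' Quadratic spring engaging above the slack length:
#' `F_PEE(l) = k_pee * (l - l_slack_pee)^2` for `l > l_slack_pee`, else 0.
#' Continuous and once-differentiable at the slack length.
#'
#' @param l CE length in L0 units (vectorized).
#' @param k_pee,l_slack_pee see [hill_params()].
#' @return PEE force normalized to F_max.
#' @export
pee_force <- function(l, k_pee, l_slack_pee) {
  stopifnot(k_pee >= 0, l_slack_pee > 0)
  k_pee * pmax(0, l - l_slack_pee)^2
}

#' Hill-type tendon force
#'
#' `F = F_max * (a * f(l) * g(v) + F_PEE(l))`, the sum of the contractile
#' element force and the parallel elastic force. Activation values above 1
#' are passed through unclamped (mean-peak activation scaling can exceed 1).
#'
#' @param a activation (unitless, `>= 0`; vectorized).
#' @param l CE length (L0 units).
#' @param v CE velocity (L0/s, positive = lengthening).
#' @param params a [hill_params()] object.
#' @param f_max maximal isometric force in N.
#' @return tendon force in N (non-negative).
#' @examples
#' p <- hill_params(0.09, 6, 0.25, 1.5, 0, 1.0)
#' hill_force(1, 1, 0, p, f_max = 10)  # 10 N
#' @export
hill_force <- function(a, l, v, params, f_max) {
  stopifnot(inherits(params, "hill_params"), f_max > 0)
  n <- max(length(a), length(l), length(v))
  a <- rep_len(a, n); l <- rep_len(l, n); v <- rep_len(v, n)
  if (!all(is.finite(a), is.finite(l), is.finite(v))) {
    stop("non-finite inputs to hill_force")
  }
  if (any(a < 0)) stop("activation must be non-negative")
  fce <- a * force_length(l, params$W) *
    force_velocity(v, params$v_max, params$A_rel, params$g_max)
  pmax(0, f_max * (fce + pee_force(l, params$k_pee, params$l_slack_pee)))
}

#' Serialize / deserialize Hill parameters as JSON
#'
#' @param params a [hill_params()] object.
#' @param path file path.
#' @return `read_hill_params` returns a [hill_params()] object.
#' @export
write_hill_params <- function(params, path) {
  stopifnot(inherits(params, "hill_params"))
  jsonlite::write_json(unclass(params)[c("W", "v_max", "A_rel", "g_max",
                                         "k_pee", "l_slack_pee")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hill_params
#' @export
read_hill_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hill_params(x$W, x$v_max, x$A_rel, x$g_max, x$k_pee, x$l_slack_pee)
}
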