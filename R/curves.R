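# Probing a force estimator for its emergent force-length (FL) and
# force-velocity (FV) relationships: evaluate normalized force on a length
# grid at zero velocity (FL, includes the PEE since a network cannot
# separate it) and on a velocity grid at optimal fiber length (FV), at
# activation levels 0.2-1.0.

#' Normalized force prediction generic
#'
#' Uniform interface used by the curve-probing machinery: returns force
#' normalized to F_max given activation, CE length and CE velocity. Methods
#' exist for the analytic Hill model ([hill_params()], exact closed form)
#' and trained networks (`nn_model`).
#'
#' @param model a `hill_params` or `nn_model` object.
#' @param a,l,v activation, CE length (L0), CE velocity (L0/s); vectorized.
#' @return normalized force series.
#' @export
predict_force <- function(model, a, l, v) UseMethod("predict_force")

#' @export
predict_force.hill_params <- function(model, a, l, v) {
  hill_force(a, l, v, model, f_max = 1)
}

#' @export
predict_force.nn_model <- function(model, a, l, v) {
  n <- max(length(a), length(l), length(v))
  stats::predict(model, rep_len(a, n), rep_len(l, n), rep_len(v, n))
}

default_fl_grid <- function() seq(0.6, 1.4, by = 0.01)
default_fv_grid <- function() seq(-10, 10, by = 0.1)
default_activation_levels <- function() c(0.2, 0.4, 0.6, 0.8, 1.0)

extract_curve <- function(model, kind, grid, levels) {
  force <- matrix(NA_real_, length(levels), length(grid),
                  dimnames = list(paste0("a=", levels), NULL))
  for (i in seq_along(levels)) {
    if (kind == "FL") {
      force[i, ] <- predict_force(model, rep(levels[i], length(grid)), grid,
                                  rep(0, length(grid)))
    } else {
      force[i, ] <- predict_force(model, rep(levels[i], length(grid)),
                                  rep(1, length(grid)), grid)
    }
  }
  extrap <- rep(FALSE, length(grid))
  if (inherits(model, "nn_model")) {
    ns <- model$norm_stats
    if (kind == "FL") {
      extrap <- abs((grid - ns$mean_l) / ns$sd_l) > 3
    } else {
      extrap <- abs((grid - ns$mean_v) / ns$sd_v) > 3
    }
  }
  structure(list(kind = kind, grid = grid, levels = levels, force = force,
                 extrapolated = extrap),
            class = "curve_set")
}

#' Force-length curve extraction
#'
#' Evaluates the estimator over a fiber-length grid (default 60 to 140
#' percent of optimal length, step 0.01) at zero velocity (isometric) for
#' each activation level. For networks, grid points whose z-scored input
#' lies more than 3 SD from the training mean are flagged as extrapolation.
#'
#' @param model `hill_params` or `nn_model`.
#' @param grid length grid in L0 units.
#' @param levels activation levels.
#' @return object of class `curve_set`.
#' @export
extract_fl <- function(model, grid = default_fl_grid(),
                       levels = default_activation_levels()) {
  if (inherits(model, "nn_model") && !inherits(model$norm_stats, "norm_stats")) {
    stop("model carries no input normalization statistics")
  }
  extract_curve(model, "FL", grid, levels)
}

#' Force-velocity curve extraction
#'
#' As [extract_fl()] but over a velocity grid (default -10 to 10 L0/s, step
#' 0.1) at optimal fiber length.
#'
#' @inheritParams extract_fl
#' @param grid velocity grid in L0/s.
#' @return object of class `curve_set`.
#' @export
extract_fv <- function(model, grid = default_fv_grid(),
                       levels = default_activation_levels()) {
  if (inherits(model, "nn_model") && !inherits(model$norm_stats, "norm_stats")) {
    stop("model carries no input normalization statistics")
  }
  extract_curve(model, "FV", grid, levels)
}

#' Per-level curve maxima
#'
#' Location (grid value) and height of the maximum normalized force at each
#' activation level; ties resolve to the first grid point.
#'
#' @param curves a `curve_set`.
#' @return data.frame with `level`, `argmax`, `max_force`.
#' @export
curve_summary <- function(curves) {
  stopifnot(inherits(curves, "curve_set"))
  idx <- apply(curves$force, 1, which.max)
  data.frame(level = curves$levels,
             argmax = curves$grid[idx],
             max_force = curves$force[cbind(seq_along(idx), idx)])
}

#' Long-format curve table
#'
#' @param curves a `curve_set`.
#' @return data.frame with columns kind, activation, x, force,
#'   extrapolated.
#' @export
curve_table <- function(curves) {
  stopifnot(inherits(curves, "curve_set"))
  data.frame(
    kind = curves$kind,
    activation = rep(curves$levels, each = length(curves$grid)),
    x = rep(curves$grid, times = length(curves$levels)),
    force = as.numeric(t(curves$force)),
    extrapolated = rep(curves$extrapolated, times = length(curves$levels))
  )
}
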