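# Evaluation metrics for force estimates: normalized-force RMSE, relative
# RMSE (percent of the trial's maximum measured force), coefficient of
# determination, missed/extra force-peak percentages from a bespoke peak
# matching rule, and rise/fall-time RMSE over matched peaks.

#' Detect force peaks
#'
#' Removes a baseline offset (the 1st percentile of the series, a robust
#' minimum), then keeps local maxima whose debaselined height is at least
#' `mean + 1.5 * sd` of the debaselined series. Plateaus report their first
#' sample. Invariant to additive constants.
#'
#' @param force force series (any consistent scale).
#' @return object of class `peak_set`: `indices`, `heights` (debaselined),
#'   `threshold`, `n` (series length).
#' @export
detect_peaks <- function(force) {
  n <- length(force)
  if (n < 3) stop("series too short for peak detection")
  d <- force - stats::quantile(force, 0.01, names = FALSE)
  s <- stats::sd(d)
  thr <- mean(d) + 1.5 * (if (is.finite(s)) s else 0)
  idx <- find_local_peaks(d, threshold = thr)
  structure(list(indices = idx, heights = d[idx], threshold = thr, n = n),
            class = "peak_set")
}

#' Match measured and estimated peaks
#'
#' Peaks are aligned when their locations differ by less than 45 percent of
#' the 25th percentile of the intervals between consecutive measured peaks
#' (a stride-period proxy). Candidate pairs are resolved globally by
#' distance: the closest measured-estimated pair is matched first, each
#' peak at most once. Unmatched measured peaks are "missed"; unmatched
#' estimated peaks are "extra". With fewer than two measured peaks the
#' window falls back to `0.45 * n / max(1, n_measured)` samples, with a
#' warning.
#'
#' @param measured,estimated `peak_set` objects from same-length series.
#' @param fs optional sampling rate; if given, distances in the result are
#'   also reported in seconds.
#' @return list: `pairs` (two-column matrix of measured/estimated indices),
#'   `missed` (measured indices), `extra` (estimated indices), `window`
#'   (samples).
#' @export
match_peaks <- function(measured, estimated, fs = NULL) {
  stopifnot(inherits(measured, "peak_set"), inherits(estimated, "peak_set"))
  if (measured$n != estimated$n) stop("peak sets from different-length series")
  m <- measured$indices; e <- estimated$indices
  if (length(m) >= 2) {
    window <- 0.45 * stats::quantile(diff(m), 0.25, names = FALSE)
  } else {
    window <- 0.45 * measured$n / max(1, length(m))
    warning("fewer than 2 measured peaks; using fallback matching window")
  }
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("measured", "estimated")))
  if (length(m) && length(e)) {
    dmat <- abs(outer(m, e, "-"))
    cand <- which(dmat < window, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dmat[cand], cand[, 1], cand[, 2])
      used_m <- logical(length(m)); used_e <- logical(length(e))
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_m[i] && !used_e[j]) {
          used_m[i] <- TRUE; used_e[j] <- TRUE
          pairs <- rbind(pairs, c(m[i], e[j]))
        }
      }
    }
  }
  list(pairs = pairs,
       missed = setdiff(m, pairs[, 1]),
       extra = setdiff(e, pairs[, 2]),
       window = window,
       window_s = if (!is.null(fs)) window / fs else NULL)
}

#' Rise and fall time of a force peak
#'
#' Rise time is the interval from the last upward crossing of 50 percent of
#' the (debaselined) peak height before the peak to the peak itself; fall
#' time runs from the peak to the first downward crossing after it.
#' Crossing times are linearly interpolated between samples. `NA` is
#' returned when the half-height level is never crossed on that side.
#'
#' @param force force series.
#' @param peak_idx index of a detected peak.
#' @param fs sampling rate in Hz.
#' @return list with `rise` and `fall` in seconds (possibly `NA`).
#' @export
rise_fall_times <- function(force, peak_idx, fs) {
  n <- length(force)
  stopifnot(peak_idx >= 1, peak_idx <= n, fs > 0)
  d <- force - stats::quantile(force, 0.01, names = FALSE)
  half <- 0.5 * d[peak_idx]
  rise <- NA_real_
  if (peak_idx > 1) {
    below <- which(d[seq_len(peak_idx - 1)] < half)
    if (length(below)) {
      j <- max(below)  # last sample below half before the peak
      frac <- (half - d[j]) / (d[j + 1] - d[j])
      rise <- (peak_idx - (j + frac)) / fs
    }
  }
  fall <- NA_real_
  if (peak_idx < n) {
    below <- which(d[(peak_idx + 1):n] < half)
    if (length(below)) {
      j <- peak_idx + min(below)  # first sample below half after the peak
      frac <- (d[j - 1] - half) / (d[j - 1] - d[j])
      fall <- ((j - 1 + frac) - peak_idx) / fs
    }
  }
  list(rise = rise, fall = fall)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` about the measured mean; negative when prediction
#' errors exceed the variability of the measurements.
#'
#' @param measured,estimated same-length numeric series.
#' @return scalar R-squared (may be negative).
#' @export
r_squared <- function(measured, estimated) {
  stopifnot(length(measured) == length(estimated), length(measured) >= 2)
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot <= 0) stop("measured series has zero variance; R^2 undefined")
  1 - sum((measured - estimated)^2) / ss_tot
}

# Per-trial metric row.
evaluate_trial <- function(measured, estimated, f_max, fs) {
  stopifnot(length(measured) == length(estimated))
  rmse <- sqrt(mean((measured - estimated)^2))
  pk_m <- detect_peaks(measured)
  pk_e <- detect_peaks(estimated)
  mt <- withCallingHandlers(
    match_peaks(pk_m, pk_e, fs = fs),
    warning = function(w) invokeRestart("muffleWarning")
  )
  rf <- function(series, idx) {
    out <- vapply(idx, function(i) {
      unlist(rise_fall_times(series, i, fs))
    }, numeric(2))
    if (length(idx) == 0) matrix(numeric(0), nrow = 2) else out
  }
  rise_err <- fall_err <- NA_real_
  if (nrow(mt$pairs) > 0) {
    rfm <- rf(measured, mt$pairs[, 1])
    rfe <- rf(estimated, mt$pairs[, 2])
    dr <- rfe[1, ] - rfm[1, ]
    df <- rfe[2, ] - rfm[2, ]
    if (any(stats::complete.cases(dr))) rise_err <- sqrt(mean(dr^2, na.rm = TRUE))
    if (any(stats::complete.cases(df))) fall_err <- sqrt(mean(df^2, na.rm = TRUE))
  }
  data.frame(
    rmse_norm = rmse / f_max,
    rrmse_pct = 100 * rmse / max(measured),
    r2 = r_squared(measured, estimated),
    n_measured_peaks = length(pk_m$indices),
    n_estimated_peaks = length(pk_e$indices),
    n_matched = nrow(mt$pairs),
    missed_pct = if (length(pk_m$indices)) 100 * length(mt$missed) / length(pk_m$indices) else NA_real_,
    extra_pct = if (length(pk_e$indices)) 100 * length(mt$extra) / length(pk_e$indices) else NA_real_,
    rise_rmse = rise_err,
    fall_rmse = fall_err
  )
}

#' Build a metrics report over trials
#'
#' Computes, per trial, the RMSE of normalized force (vs F_max), the
#' relative RMSE (percent of the trial's maximum measured force), the
#' coefficient of determination, missed and extra peak percentages, and the
#' RMSE of rise and fall times over matched peaks; then aggregates with
#' mean +/- sd for RMSE-type metrics and median [min, max] for R-squared.
#'
#' @param measured_list,estimated_list lists of same-length force series
#'   (measured in N, estimated in N on the same scale).
#' @param f_max maximal isometric force per trial (scalar or vector).
#' @param fs sampling rate per trial (scalar or vector), Hz.
#' @return object of class `metrics_report`: `per_trial` data.frame and
#'   `aggregate` list.
#' @export
build_report <- function(measured_list, estimated_list, f_max, fs) {
  if (is.numeric(measured_list)) measured_list <- list(measured_list)
  if (is.numeric(estimated_list)) estimated_list <- list(estimated_list)
  k <- length(measured_list)
  if (k == 0 || length(estimated_list) != k) stop("need matching nonempty trial lists")
  f_max <- rep_len(f_max, k); fs <- rep_len(fs, k)
  rows <- do.call(rbind, lapply(seq_len(k), function(i) {
    evaluate_trial(measured_list[[i]], estimated_list[[i]], f_max[i], fs[i])
  }))
  agg <- list(
    force_mrmse = mean(rows$rmse_norm),
    force_mrmse_sd = stats::sd(rows$rmse_norm),
    rrmse_pct_mean = mean(rows$rrmse_pct),
    r2_median = stats::median(rows$r2),
    r2_min = min(rows$r2), r2_max = max(rows$r2),
    missed_pct_mean = mean(rows$missed_pct, na.rm = TRUE),
    missed_pct_min = suppressWarnings(min(rows$missed_pct, na.rm = TRUE)),
    missed_pct_max = suppressWarnings(max(rows$missed_pct, na.rm = TRUE)),
    extra_pct_mean = mean(rows$extra_pct, na.rm = TRUE),
    extra_pct_min = suppressWarnings(min(rows$extra_pct, na.rm = TRUE)),
    extra_pct_max = suppressWarnings(max(rows$extra_pct, na.rm = TRUE)),
    rise_mrmse = if (all(is.na(rows$rise_rmse))) NA_real_ else mean(rows$rise_rmse, na.rm = TRUE),
    fall_mrmse = if (all(is.na(rows$fall_rmse))) NA_real_ else mean(rows$fall_rmse, na.rm = TRUE)
  )
  structure(list(per_trial = rows, aggregate = agg), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Metrics over %d trial(s):\n", nrow(x$per_trial)))
  cat(sprintf("  force mRMSE      : %.3g +/- %.3g\n", a$force_mrmse,
              ifelse(is.na(a$force_mrmse_sd), 0, a$force_mrmse_sd)))
  cat(sprintf("  relative RMSE    : %.3g %%\n", a$rrmse_pct_mean))
  cat(sprintf("  median R^2       : %.3g [%.3g %.3g]\n", a$r2_median, a$r2_min, a$r2_max))
  cat(sprintf("  missed peaks     : %.3g %%\n", a$missed_pct_mean))
  cat(sprintf("  extra peaks      : %.3g %%\n", a$extra_pct_mean))
  cat(sprintf("  rise time mRMSE  : %.3g s\n", a$rise_mrmse))
  cat(sprintf("  fall time mRMSE  : %.3g s\n", a$fall_mrmse))
  invisible(x)
}
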