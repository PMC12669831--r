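# Signal chain from raw electromyography (EMG) and measured tendon force to
# model-ready inputs: zero-phase Butterworth high-pass (30 Hz) -> rectify ->
# zero-phase low-pass (6 Hz) envelope, scaling to the average peak activation
# of the highest-speed trials, a 23.6 ms excitation-contraction coupling
# delay, force normalization by F_max = PCSA * sigma_max, and z-scoring of
# length/velocity with training-set statistics.

#' Per bird-and-muscle physiological specification
#'
#' @param bird_id bird identifier.
#' @param muscle muscle identifier (e.g. `"LG"`, `"DF"`).
#' @param pcsa physiological cross-sectional area in mm^2.
#' @param sigma_max maximum isometric muscle stress in N/mm^2 (default 0.29).
#' @param activation_scale average peak activation of the processed EMG
#'   envelope (unitless divisor); `NA` until computed.
#' @param peak_threshold envelope threshold for peak detection when
#'   computing the activation scale (default 0.1; 0.035 was needed for one
#'   low-amplitude digital flexor channel).
#' @param l0 optimal fiber length; lengths arrive already normalized, so 1.
#' @return object of class `muscle_spec` with derived `f_max = pcsa * sigma_max`.
#' @export
muscle_spec <- function(bird_id, muscle, pcsa, sigma_max = 0.29,
                        activation_scale = NA_real_, peak_threshold = 0.1,
                        l0 = 1) {
  stopifnot(pcsa > 0, sigma_max > 0, is.na(activation_scale) || activation_scale > 0)
  structure(
    list(bird_id = bird_id, muscle = muscle, pcsa = pcsa,
         sigma_max = sigma_max, f_max = pcsa * sigma_max,
         activation_scale = activation_scale,
         peak_threshold = peak_threshold, l0 = l0),
    class = "muscle_spec"
  )
}

#' EMG envelope extraction
#'
#' Third-order Butterworth high-pass at 30 Hz applied in zero phase
#' (forward-backward), full-wave rectification, then a third-order zero-phase
#' low-pass at 6 Hz. DC offset and slow drift are removed by the high-pass
#' before rectification.
#'
#' @param emg_raw raw EMG series.
#' @param fs sampling rate in Hz (must exceed twice the 30 Hz high-pass
#'   cut-off).
#' @param hp_hz,lp_hz cut-off frequencies (defaults 30 and 6 Hz).
#' @return non-negative envelope, same length as the input.
#' @export
process_emg <- function(emg_raw, fs, hp_hz = 30, lp_hz = 6) {
  if (fs <= 2 * hp_hz) stop("sampling rate too low for the ", hp_hz, " Hz high-pass")
  hp <- butter_filtfilt(emg_raw, 3, hp_hz, fs, "high")
  rect <- abs(hp)
  env <- butter_filtfilt(rect, 3, lp_hz, fs, "low")
  pmax(env, 0)
}

# Local maxima at or above `threshold`, with a minimum separation (in
# samples) to avoid double-counting ripples on one burst. Plateaus report
# their first sample. Among maxima closer than `min_separation`, the higher
# one wins (ties: the earlier).
find_local_peaks <- function(x, threshold = -Inf, min_separation = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= threshold]
  if (length(cand) == 0 || min_separation <= 1) return(cand)
  keep <- logical(length(cand))
  ord <- order(-x[cand], cand)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= min_separation)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  sort(cand[keep])
}

#' Average peak activation for envelope scaling
#'
#' Mean height of envelope peaks at or above `peak_threshold` across the
#' supplied (highest-speed) trials. Peaks are local maxima separated by at
#' least a quarter of the median inter-peak interval, so one burst
#' contributes one peak.
#'
#' @param envelopes a list of processed envelopes (or a single numeric
#'   series).
#' @param peak_threshold detection threshold on envelope height.
#' @return the activation scale (mean peak height).
#' @export
compute_activation_scale <- function(envelopes, peak_threshold = 0.1) {
  if (is.numeric(envelopes)) envelopes <- list(envelopes)
  heights <- unlist(lapply(envelopes, function(env) {
    pk <- find_local_peaks(env, threshold = peak_threshold)
    if (length(pk) > 2) {
      sep <- max(1, round(0.25 * stats::median(diff(pk))))
      pk <- find_local_peaks(env, threshold = peak_threshold, min_separation = sep)
    }
    env[pk]
  }))
  if (length(heights) == 0) {
    stop("no peaks above threshold ", peak_threshold,
         "; consider lowering the threshold", call. = FALSE)
  }
  mean(heights)
}

#' Scale and delay the activation envelope
#'
#' Divides the envelope by the activation scale and shifts it later in time
#' by `round(fs * delay)` samples (edge-value padding at the start) to
#' account for excitation-contraction coupling. Scaled activation may exceed
#' 1 and is passed through unclamped.
#'
#' @param envelope processed EMG envelope.
#' @param activation_scale positive divisor from [compute_activation_scale()].
#' @param fs sampling rate in Hz.
#' @param delay excitation-contraction coupling delay in seconds
#'   (default 0.0236).
#' @return activation series, same length as the envelope.
#' @export
finalize_activation <- function(envelope, activation_scale, fs, delay = 0.0236) {
  stopifnot(activation_scale > 0, fs > 0, delay >= 0)
  a <- envelope / activation_scale
  k <- as.integer(round(fs * delay))
  shift_series(a, k)
}

# Shift a series k samples later (k >= 0), padding with the first value.
shift_series <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k >= n) return(rep(x[1], n))
  c(rep(x[1], k), x[1:(n - k)])
}

#' Normalize force by maximal isometric force
#'
#' @param force_N measured tendon force in N.
#' @param f_max maximal isometric force in N (PCSA times maximum stress).
#' @return dimensionless force.
#' @export
normalize_force <- function(force_N, f_max) {
  if (!is.numeric(f_max) || f_max <= 0) stop("`f_max` must be positive")
  force_N / f_max
}

#' Training-set z-scoring of CE length and velocity
#'
#' `fit_norm_stats` computes means and standard deviations on the training
#' set; `apply_norm` applies them unchanged to any data. The network inputs
#' are activation (unscaled further) plus z-scored length and velocity.
#'
#' @param lce,vce CE length (L0) and velocity (L0/s) series.
#' @return `fit_norm_stats`: object of class `norm_stats`;
#'   `apply_norm`: list with `z_l` and `z_v`.
#' @export
fit_norm_stats <- function(lce, vce) {
  stopifnot(length(lce) >= 2, length(vce) >= 2)
  s <- list(mean_l = mean(lce), sd_l = stats::sd(lce),
            mean_v = mean(vce), sd_v = stats::sd(vce))
  if (s$sd_l <= 0 || s$sd_v <= 0) stop("zero variance in length or velocity")
  structure(s, class = "norm_stats")
}

#' @rdname fit_norm_stats
#' @param stats a `norm_stats` object from the training set.
#' @export
apply_norm <- function(lce, vce, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  list(z_l = (lce - stats$mean_l) / stats$sd_l,
       z_v = (vce - stats$mean_v) / stats$sd_v)
}

#' Recompute CE velocity from length
#'
#' Central differences followed by the same 6 Hz zero-phase low-pass used on
#' the EMG envelope.
#'
#' @param lce CE length series (L0 units).
#' @param fs sampling rate in Hz.
#' @return CE velocity in L0/s.
#' @export
velocity_from_length <- function(lce, fs) {
  n <- length(lce)
  stopifnot(n >= 3)
  v <- numeric(n)
  v[2:(n - 1)] <- (lce[3:n] - lce[1:(n - 2)]) * fs / 2
  v[1] <- (lce[2] - lce[1]) * fs
  v[n] <- (lce[n] - lce[n - 1]) * fs
  butter_filtfilt(v, 3, 6, fs, "low")
}
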