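# Shared fixtures and independent oracles, all built in code at test time.

# A series of planted triangular peaks on a zero baseline.
# Returns the series plus the planted apex indices and heights.
planted_peak_series <- function(n, apex_idx, heights, half_width) {
  x <- numeric(n)
  for (k in seq_along(apex_idx)) {
    i0 <- apex_idx[k]; h <- heights[k]; w <- half_width
    for (j in max(1, i0 - w):min(n, i0 + w)) {
      x[j] <- max(x[j], h * (1 - abs(j - i0) / w))
    }
  }
  list(x = x, apex = apex_idx, heights = heights)
}

# Independent peak-matching oracle: repeatedly pick the globally closest
# unmatched (measured, estimated) pair with distance < window, using a
# plain masked distance-matrix scan (structurally different from the
# package's sorted-candidate implementation).
oracle_match <- function(m_idx, e_idx, window) {
  pairs <- matrix(integer(0), ncol = 2)
  if (length(m_idx) && length(e_idx)) {
    dmat <- abs(outer(m_idx, e_idx, "-"))
    dmat[dmat >= window] <- Inf
    repeat {
      if (!any(is.finite(dmat))) break
      k <- which(dmat == min(dmat), arr.ind = TRUE)
      # deterministic tie-break: smallest measured index, then estimated
      k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
      pairs <- rbind(pairs, c(m_idx[k[1]], e_idx[k[2]]))
      dmat[k[1], ] <- Inf
      dmat[, k[2]] <- Inf
    }
  }
  list(pairs = pairs,
       missed = setdiff(m_idx, pairs[, 1]),
       extra = setdiff(e_idx, pairs[, 2]))
}

# Rich-excitation noiseless trial driven by a known Hill parameter set:
# activation, length and velocity vary widely and partly independently,
# with near-passive stretches so the PEE is identifiable.
rich_excitation_trial <- function(truth, f_max = 25, fs = 500, dur = 6) {
  t <- seq(0, dur, by = 1 / fs)
  a <- 0.5 + 0.5 * sin(2 * pi * 0.5 * t)^2 * sin(2 * pi * 0.13 * t + 1)^2
  a <- pmax(0, pmin(1, a))
  lce <- 1 + 0.25 * sin(2 * pi * 0.5 * t) * cos(2 * pi * 0.09 * t)
  vce <- velocity_from_length(lce, fs)
  a[lce > 1.15] <- a[lce > 1.15] * 0.1
  force <- synthesize_force(a, lce, vce, truth, f_max)
  structure(list(data = data.frame(t = t, emg_raw = 0, activation = a,
                                   lce = lce, vce = vce, force = force),
                 meta = list(f_max = f_max, fs = fs, bird_id = 1L,
                             muscle = "LG", trial_id = "rich")),
            class = "trial")
}

# Dense independent coverage of the (a, l, v) input box, labelled by the
# analytic Hill model; used to train networks whose training distribution
# covers the probing grids.
dense_hill_trial <- function(truth, n = 24000, seed = 21,
                             a_range = c(0, 1.05), l_range = c(0.55, 1.45),
                             v_range = c(-11, 11), a_transform = identity) {
  set.seed(seed)
  a <- stats::runif(n, a_range[1], a_range[2])
  l <- stats::runif(n, l_range[1], l_range[2])
  v <- stats::runif(n, v_range[1], v_range[2])
  y <- predict_force(truth, a, l, v)
  structure(list(data = data.frame(t = seq_len(n), emg_raw = 0,
                                   activation = a_transform(a),
                                   lce = l, vce = v, force = y),
                 meta = list(f_max = 1, fs = 1, bird_id = 1L,
                             muscle = "LG", trial_id = "dense")),
            class = "trial")
}

# Mean matched-peak height error (estimated - measured), in input units.
matched_peak_error <- function(measured, estimated) {
  pm <- detect_peaks(measured)
  pe <- detect_peaks(estimated)
  mt <- suppressWarnings(match_peaks(pm, pe))
  if (nrow(mt$pairs) == 0) return(NA_real_)
  mean(estimated[mt$pairs[, 2]] - measured[mt$pairs[, 1]])
}
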