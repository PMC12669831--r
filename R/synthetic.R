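# Synthetic gait-trial generator emulating in vivo avian muscle recordings:
# several birds, two muscles with distinct physiological cross-sectional
# areas (PCSA) and activation scalings, cyclic stance-phase activation
# bursts with stride-to-stride jitter, fascicle length oscillating near the
# optimal length, ground-truth forces from the Hill model plus an optional
# history-dependent (stretch-enhancement) term and sensor noise, and
# obstacle strides that dissociate activation from force.

#' Synthetic dataset configuration
#'
#' Defaults describe the emulated dataset: multiple individuals, a large
#' calf muscle (LG) and a smaller toe flexor (DF) with different widths of
#' the force-length relationship and different PCSA, level and obstacle
#' trials across walking-to-running speeds, and an activation-scaling error
#' that can differ between muscles (the recorded activation channel is the
#' true neural drive divided by `activation_scale_error`, emulating
#' normalization to submaximal average peak activation).
#'
#' @param n_birds number of individuals.
#' @param muscles character vector of muscle ids.
#' @param speeds trial speeds in m/s.
#' @param obstacle_heights obstacle heights in cm (0 = level).
#' @param fs sampling rate in Hz.
#' @param n_strides strides per trial.
#' @param ground_truth named list of [hill_params()] per muscle.
#' @param pcsa named list per muscle of base PCSA in mm^2 (per-bird values
#'   get a deterministic +/- 8 percent spread).
#' @param activation_scale_error named numeric per muscle; 1 means the
#'   recorded activation is correctly scaled, 1.3 means the channel
#'   under-reports the true drive by 30 percent.
#' @param history_gain gain of the non-Hill stretch-history force term
#'   (fraction of F_max; 0 = pure Hill ground truth).
#' @param noise_sd_force force sensor noise, fraction of F_max.
#' @param noise_sd_emg additive baseline noise on the raw EMG.
#' @param seed integer seed; the full dataset is reproducible from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_birds = 3,
                             muscles = c("LG", "DF"),
                             speeds = c(1.8, 3.8, 4.5),
                             obstacle_heights = c(0, 7),
                             fs = 1000,
                             n_strides = 10,
                             ground_truth = NULL,
                             pcsa = list(LG = 100, DF = 60),
                             activation_scale_error = c(LG = 1, DF = 1),
                             history_gain = 0,
                             noise_sd_force = 0.02,
                             noise_sd_emg = 0.05,
                             seed = 1L) {
  if (is.null(ground_truth)) {
    ground_truth <- list(
      LG = hill_params(W = 0.12, v_max = 6.5, A_rel = 0.22, g_max = 1.5,
                       k_pee = 4, l_slack_pee = 0.95),
      DF = hill_params(W = 0.18, v_max = 7.5, A_rel = 0.28, g_max = 1.5,
                       k_pee = 5, l_slack_pee = 0.95)
    )
  }
  stopifnot(
    n_birds >= 1, length(muscles) >= 1, length(speeds) >= 1,
    length(obstacle_heights) >= 1, fs > 0, n_strides >= 1,
    all(muscles %in% names(ground_truth)),
    all(muscles %in% names(pcsa)), all(unlist(pcsa) > 0),
    all(muscles %in% names(activation_scale_error)),
    all(activation_scale_error > 0),
    history_gain >= 0, noise_sd_force >= 0, noise_sd_emg >= 0
  )
  structure(
    list(n_birds = n_birds, muscles = muscles, speeds = speeds,
         obstacle_heights = obstacle_heights, fs = fs, n_strides = n_strides,
         ground_truth = ground_truth, pcsa = pcsa,
         activation_scale_error = activation_scale_error,
         history_gain = history_gain, noise_sd_force = noise_sd_force,
         noise_sd_emg = noise_sd_emg, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Deterministic seed fan-out: one master seed -> n child seeds (< 2^31).
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Cyclic activation burst train
#'
#' One smooth raised-cosine burst per stride occupying `duty` of the stride,
#' with optional stride-to-stride amplitude and onset-timing jitter. Burst
#' supports are odd in sample count so the nominal peak value is exactly 1.
#'
#' @param n_strides number of strides.
#' @param stride_duration stride period in seconds.
#' @param duty burst duration as a fraction of the stride (0 < duty < 1).
#' @param fs sampling rate in Hz.
#' @param jitter relative amplitude / timing jitter (0 = deterministic).
#' @param seed integer seed.
#' @param amp_per_stride optional multiplier per stride (e.g. obstacle
#'   strides); recycled.
#' @return activation series of length `round(n_strides * stride_duration * fs)`,
#'   values in `[0, 1]` when `jitter = 0` and `amp_per_stride = 1`.
#' @export
generate_activation <- function(n_strides, stride_duration, duty = 0.35,
                                fs = 1000, jitter = 0, seed = 1L,
                                amp_per_stride = 1) {
  if (fs <= 0 || stride_duration <= 0) stop("`fs` and `stride_duration` must be positive")
  if (duty <= 0 || duty >= 1) stop("`duty` must be in (0, 1)")
  rng <- local_rng(seed)
  stride_n <- round(stride_duration * fs)
  n <- n_strides * stride_n
  a <- numeric(n)
  m <- 2L * floor(duty * stride_n / 2) + 1L  # odd support -> peak hits 1
  burst <- sin(pi * seq(0, 1, length.out = m))^2
  burst[c(1L, m)] <- 0  # exact zeros (sin(pi) is only ~1e-16)
  amp_per_stride <- rep_len(amp_per_stride, n_strides)
  for (s in seq_len(n_strides)) {
    amp <- amp_per_stride[s]
    onset <- (s - 1L) * stride_n + round(0.05 * stride_n)
    if (jitter > 0) {
      amp <- amp * max(0.2, 1 + jitter * rng$norm(1))
      onset <- onset + round(jitter * 0.3 * stride_n * rng$norm(1))
    }
    idx <- onset + seq_len(m)
    ok <- idx >= 1 & idx <= n
    a[idx[ok]] <- a[idx[ok]] + amp * burst[ok]
  }
  a
}

# Small seeded RNG scope that does not disturb the global stream.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  env$norm <- function(n) stats::rnorm(n)
  env$unif <- function(n) stats::runif(n)
  env$restore <- function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  env
}

#' Fascicle length and velocity trajectories
#'
#' Length oscillates sinusoidally about `mean_l` with a slowly varying
#' amplitude (stride-to-stride jitter shrinks the excursion, never exceeding
#' `amp`, so the series stays in `[mean_l - amp, mean_l + amp]`). Velocity is
#' the central-difference derivative of length, low-pass filtered at 6 Hz in
#' zero phase like the measured channel.
#'
#' @param n_strides,stride_duration,fs as in [generate_activation()].
#' @param amp oscillation amplitude (L0 units); must be below `mean_l`.
#' @param mean_l mean fascicle length (L0 units).
#' @param jitter relative amplitude jitter.
#' @param seed integer seed.
#' @param length_offset optional additive offset series (e.g. obstacle
#'   bumps), recycled to the series length.
#' @param phase phase of the oscillation in radians. The default places the
#'   upward crossing of `mean_l` at the centre of the activation burst of
#'   [generate_activation()], which yields one dominant force peak per
#'   stride (as in recorded gait data) rather than twin peaks.
#' @return list with `lce` and `vce`.
#' @export
generate_fascicle <- function(n_strides, stride_duration, fs = 1000,
                              amp = 0.08, mean_l = 1, jitter = 0, seed = 1L,
                              length_offset = 0, phase = -1.45) {
  if (amp >= mean_l) stop("`amp` must be smaller than `mean_l`")
  if (amp < 0) stop("`amp` must be non-negative")
  rng <- local_rng(seed)
  stride_n <- round(stride_duration * fs)
  n <- n_strides * stride_n
  t <- (seq_len(n) - 1) / fs
  if (jitter > 0 && n_strides > 1) {
    a_s <- amp * pmax(0.2, 1 - jitter * abs(rng$norm(n_strides)))
    mid <- ((seq_len(n_strides)) - 0.5) * stride_duration
    A <- stats::approx(mid, a_s, xout = t, rule = 2)$y
  } else {
    A <- rep(amp, n)
  }
  lce <- mean_l + A * sin(2 * pi * t / stride_duration + phase) +
    rep_len(length_offset, n)
  if (amp == 0 && all(length_offset == 0)) {
    return(list(lce = lce, vce = numeric(n)))
  }
  list(lce = lce, vce = velocity_from_length(lce, fs))
}

default_carrier_band <- function(fs) {
  c(max(31, 0.1 * fs), min(350, 0.45 * fs))
}

#' Synthesize a raw EMG signal from an activation trace
#'
#' Amplitude-modulates zero-mean band-limited noise with the activation
#' advanced by `delay` seconds, so that re-applying the processing chain
#' (30 Hz high-pass, rectification, 6 Hz low-pass, excitation-contraction
#' delay) approximately recovers the activation. Additive baseline noise of
#' standard deviation `noise_sd` emulates sensor noise.
#'
#' @param activation modulating activation series.
#' @param fs sampling rate in Hz.
#' @param delay electromechanical delay in seconds (activation is advanced
#'   by this much; default 0.0236).
#' @param carrier_band two-element band in Hz; must lie inside
#'   (30 Hz, fs/2).
#' @param noise_sd baseline noise standard deviation.
#' @param seed integer seed.
#' @return raw EMG series, same length as `activation`.
#' @export
generate_raw_emg <- function(activation, fs = 1000, delay = 0.0236,
                             carrier_band = default_carrier_band(fs),
                             noise_sd = 0, seed = 1L) {
  stopifnot(delay >= 0, length(carrier_band) == 2)
  if (carrier_band[1] <= 30 || carrier_band[2] >= fs / 2 ||
      carrier_band[1] >= carrier_band[2]) {
    stop("carrier band must lie within (30 Hz, fs/2)")
  }
  rng <- local_rng(seed)
  n <- length(activation)
  white <- rng$norm(n)
  carrier <- butter_filtfilt(white, 3, carrier_band[1], fs, "high")
  carrier <- butter_filtfilt(carrier, 3, carrier_band[2], fs, "low")
  s <- stats::sd(carrier)
  if (s > 0) carrier <- carrier / s
  k <- as.integer(round(fs * delay))
  adv <- if (k == 0) activation else c(activation[(k + 1):n], rep(activation[n], k))
  emg <- carrier * adv
  if (noise_sd > 0) emg <- emg + noise_sd * rng$norm(n)
  emg
}

#' Ground-truth force synthesis
#'
#' Hill-model force from the true neural drive plus an optional
#' history-dependent term emulating force enhancement after active stretch:
#' a first-order low-pass (time constant `tau`) of `max(0, vce) * a`, scaled
#' by `history_gain * f_max`. Sensor noise is additive; the total is clipped
#' at 0 N (a tendon buckle reports no compressive force).
#'
#' @param a activation (true drive).
#' @param lce,vce CE length (L0) and velocity (L0/s).
#' @param params ground-truth [hill_params()].
#' @param f_max maximal isometric force in N.
#' @param history_gain gain of the history term (fraction of F_max).
#' @param noise_sd_force noise standard deviation as a fraction of F_max.
#' @param seed integer seed (noise only).
#' @param fs sampling rate in Hz (history integrator step).
#' @param tau history time constant in seconds.
#' @return force series in N.
#' @export
synthesize_force <- function(a, lce, vce, params, f_max,
                             history_gain = 0, noise_sd_force = 0,
                             seed = 1L, fs = 1000, tau = 0.1) {
  n <- length(a)
  if (length(lce) != n || length(vce) != n) {
    stop("activation, length and velocity series must have equal length")
  }
  force <- hill_force(a, lce, vce, params, f_max)
  if (history_gain > 0) {
    u <- pmax(0, vce) * a
    alpha <- exp(-1 / (fs * tau))
    h <- numeric(n)
    acc <- 0
    for (i in seq_len(n)) {
      acc <- alpha * acc + (1 - alpha) * u[i]
      h[i] <- acc
    }
    force <- force + history_gain * f_max * h
  }
  if (noise_sd_force > 0) {
    rng <- local_rng(seed)
    noise <- rng$norm(n)
    # band-limit the sensor noise (tendon-buckle recordings are smooth;
    # broadband noise would plant spurious micro-peaks on every force
    # maximum), then rescale so noise_sd_force keeps its meaning
    if (n > 40 && fs > 24) {
      noise <- butter_filtfilt(noise, 3, min(10, fs / 4), fs, "low")
      noise <- noise / stats::sd(noise)
    }
    force <- force + noise_sd_force * f_max * noise
  }
  pmax(force, 0)
}

stride_frequency <- function(speed) 1.2 + 0.5 * speed  # Hz, walk -> run

#' Generate a full synthetic dataset
#'
#' One trial per (bird, muscle, speed, obstacle) combination. Obstacle
#' trials perturb every 4th or 5th stride (alternating): the neural drive of
#' that stride is amplified by 30 percent and the fascicle trajectory gains
#' a +0.05 L0 raised-cosine offset, dissociating activation from force.
#' Per-muscle activation scale errors divide the recorded activation
#' channel; the raw EMG is synthesized from the recorded activation. The
#' dataset is fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return object of class `trial_dataset`: a list of trials, each a list
#'   with `data` (data.frame: t, emg_raw, activation, lce, vce, force) and
#'   `meta` (bird_id, muscle, speed, obstacle, day, f_max, pcsa).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- expand.grid(bird = seq_len(config$n_birds), muscle = config$muscles,
                      speed = config$speeds, obstacle = config$obstacle_heights,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) stop("empty trial grid")
  seeds <- derive_seeds(config$seed, nrow(grid) * 6 + config$n_birds)
  # deterministic per-bird PCSA spread
  bird_fac <- 1 + 0.08 * stats::qnorm((seq_len(config$n_birds)) /
                                        (config$n_birds + 1))
  trials <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    s <- seeds[(i - 1) * 6 + 1:6]
    fs <- config$fs
    f_str <- stride_frequency(g$speed)
    stride_duration <- 1 / f_str
    n_strides <- config$n_strides
    muscle_fac <- if (g$muscle == "DF") 0.8 else 1.0
    drive_amp <- (0.5 + 0.09 * g$speed) * muscle_fac
    amp_per_stride <- rep(1, n_strides)
    length_offset <- 0
    if (g$obstacle > 0 && n_strides >= 4) {
      # every 4th-5th stride is an obstacle step
      pert <- integer(0)
      k <- 0L; step <- 4L
      while (k + step <= n_strides) {
        k <- k + step
        pert <- c(pert, k)
        step <- if (step == 4L) 5L else 4L
      }
      amp_per_stride[pert] <- 1.3
      stride_n <- round(stride_duration * fs)
      n <- n_strides * stride_n
      length_offset <- numeric(n)
      bump <- 0.05 * sin(pi * seq(0, 1, length.out = stride_n))^2
      for (p in pert) {
        idx <- (p - 1L) * stride_n + seq_len(stride_n)
        length_offset[idx] <- bump
      }
    }
    a_true <- drive_amp * generate_activation(
      n_strides, stride_duration, duty = 0.35, fs = fs,
      jitter = 0.08, seed = s[1], amp_per_stride = amp_per_stride
    )
    fas <- generate_fascicle(
      n_strides, stride_duration, fs = fs,
      amp = 0.04 + 0.015 * g$speed, mean_l = 1, jitter = 0.1, seed = s[2],
      length_offset = length_offset
    )
    pcsa <- config$pcsa[[g$muscle]] * bird_fac[g$bird]
    f_max <- pcsa * 0.29
    force <- synthesize_force(
      a_true, fas$lce, fas$vce, config$ground_truth[[g$muscle]], f_max,
      history_gain = config$history_gain,
      noise_sd_force = config$noise_sd_force, seed = s[3], fs = fs
    )
    scale_err <- config$activation_scale_error[[g$muscle]]
    a_rec <- a_true / scale_err
    emg_raw <- generate_raw_emg(a_rec, fs = fs, noise_sd = config$noise_sd_emg,
                                seed = s[4])
    n <- length(a_true)
    trials[[i]] <- structure(list(
      data = data.frame(
        t = (seq_len(n) - 1) / fs,
        emg_raw = emg_raw,
        activation = a_rec,
        lce = fas$lce,
        vce = fas$vce,
        force = force
      ),
      meta = list(bird_id = g$bird, muscle = g$muscle, speed = g$speed,
                  obstacle = g$obstacle, day = 1L,
                  f_max = f_max, pcsa = pcsa, fs = fs,
                  trial_id = sprintf("b%d_%s_v%0.1f_o%d",
                                     g$bird, g$muscle, g$speed, g$obstacle))
    ), class = "trial")
  }
  structure(trials, class = "trial_dataset", config = config)
}

#' @export
print.trial_dataset <- function(x, ...) {
  meta <- trial_meta(x)
  cat(sprintf("Synthetic trial dataset: %d trials, %d bird(s), muscles: %s\n",
              length(x), length(unique(meta$bird_id)),
              paste(unique(meta$muscle), collapse = ", ")))
  invisible(x)
}

#' Tabulate trial metadata
#'
#' @param dataset a `trial_dataset` (or plain list of trials).
#' @return data.frame with one row per trial.
#' @export
trial_meta <- function(dataset) {
  do.call(rbind, lapply(dataset, function(tr) {
    as.data.frame(tr$meta[c("bird_id", "muscle", "speed", "obstacle", "day",
                            "f_max", "pcsa", "fs", "trial_id")])
  }))
}

#' Subset a dataset by metadata
#'
#' @param dataset a `trial_dataset`.
#' @param bird_id,muscle,speed,obstacle optional filters (vectors allowed).
#' @return filtered `trial_dataset`.
#' @export
filter_trials <- function(dataset, bird_id = NULL, muscle = NULL,
                          speed = NULL, obstacle = NULL) {
  keep <- vapply(dataset, function(tr) {
    m <- tr$meta
    (is.null(bird_id) || m$bird_id %in% bird_id) &&
      (is.null(muscle) || m$muscle %in% muscle) &&
      (is.null(speed) || m$speed %in% speed) &&
      (is.null(obstacle) || m$obstacle %in% obstacle)
  }, logical(1))
  structure(dataset[keep], class = "trial_dataset",
            config = attr(dataset, "config"))
}

#' Write / read a dataset as plain-text tables plus a JSON manifest
#'
#' Each trial becomes one CSV (columns t, emg_raw, activation, lce, vce,
#' force); `manifest.json` records the per-trial metadata.
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return `read_dataset` returns a `trial_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(dataset, function(tr) {
    fname <- paste0(tr$meta$trial_id, ".csv")
    utils::write.csv(tr$data, file.path(dir, fname), row.names = FALSE)
    c(tr$meta, list(file = fname))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  trials <- lapply(manifest, function(m) {
    dat <- utils::read.csv(file.path(dir, m$file))
    structure(list(data = dat, meta = m[setdiff(names(m), "file")]),
              class = "trial")
  })
  structure(trials, class = "trial_dataset")
}
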