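# Synthetic phase-coupled EEG.
#
# Each channel is a sum of band-limited oscillations sharing, per band, one
# common phase trajectory; channels differ by a slowly-varying von Mises
# phase jitter whose concentration kappa sets the inter-channel synchrony.
# Because two independent von Mises deviates e1, e2 give
#   E[exp(i*(e1 - e2))] = (I1(k)/I0(k))^2,
# the generator has a closed-form PLV oracle (expected_plv), which every
# downstream stage can be validated against.
#
# The jitter is made slowly varying -- but with an exactly von Mises
# marginal -- by pushing a unit-variance AR(1) Gaussian process through the
# probability-integral transform and the von Mises quantile function.  Pure
# per-sample jitter would be removed by the band-pass + Hilbert stage; a
# constant offset would give PLV 1 regardless of kappa.  A sub-hertz
# jitter bandwidth (correlation time ~0.25 s) threads the needle.

# von Mises quantile function (mean 0, concentration kappa) via numerical
# CDF inversion on a fine grid; kappa = 0 is uniform, kappa = Inf degenerate.
vonmises_quantile <- function(p, kappa, grid_n = 4096L) {
  if (kappa == 0) return((p - 0.5) * 2 * pi)
  if (!is.finite(kappa)) return(rep(0, length(p)))
  if (kappa > 500) return(stats::qnorm(p, sd = 1 / sqrt(kappa)))
  theta <- seq(-pi, pi, length.out = grid_n)
  dens <- exp(kappa * (cos(theta) - 1))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[grid_n] - cdf[1])
  stats::approx(cdf, theta, xout = p, rule = 2, ties = "ordered")$y
}

# unit-variance AR(1) rows with correlation time tau (seconds)
ar1_process <- function(n_rows, n_samples, rate, tau) {
  rho <- exp(-1 / (rate * tau))
  innov <- matrix(stats::rnorm(n_rows * n_samples, sd = sqrt(1 - rho^2)),
                  n_rows, n_samples)
  innov[, 1] <- stats::rnorm(n_rows)
  ar1_filter_rows(innov, rho)
}

#' Expected PLV of the synthetic generator
#'
#' Closed-form phase-locking value between two channels whose phase jitters
#' are independent von Mises with concentrations `kappa` and `kappa2`: the
#' product of the mean resultant lengths, `(I1(k)/I0(k)) * (I1(k2)/I0(k2))`.
#' With equal concentrations this is the squared Bessel ratio
#' `(I1(kappa)/I0(kappa))^2`: 0 for uniform jitter (kappa = 0), approaching
#' 1 as the jitter vanishes (kappa -> Inf).
#'
#' @param kappa,kappa2 Non-negative concentrations (vectorized; `kappa2`
#'   defaults to `kappa`).
#' @return Expected PLV in `[0, 1]`.
#' @examples
#' expected_plv(c(0, 0.5, 2, 8, Inf))
#' @export
expected_plv <- function(kappa, kappa2 = kappa) {
  resultant <- function(k) {
    # scaled Bessel quotient up to k = 500, asymptotic expansion beyond
    r <- ifelse(is.finite(k) & k <= 500,
                besselI(pmin(k, 500), 1, expon.scaled = TRUE) /
                  besselI(pmin(k, 500), 0, expon.scaled = TRUE),
                1 - 1 / (2 * pmax(k, 1)) - 1 / (8 * pmax(k, 1)^2))
    ifelse(k == 0, 0, ifelse(is.finite(r), r, 1))
  }
  if (any(kappa < 0, kappa2 < 0)) stop("kappa must be non-negative")
  resultant(kappa) * resultant(kappa2)
}

#' Configuration of the synthetic EEG cohort
#'
#' Defaults emulate the study layout: 25 subjects, three VIMS states of 60 s
#' each, 52 channels of the BioSemi 10-20 working montage, generated at the
#' 2048 Hz acquisition rate (so the downsampling stage is exercised) and
#' analyzed at 1024 Hz.  The class signal lives in the band-wise jitter
#' concentrations: by default synchrony collapses with sickness severity in
#' the gamma band (kappa 8 -> 2 -> 0.5) and mildly in beta, while the slow
#' bands carry no state information.
#'
#' @param n_subjects Number of subjects.
#' @param montage Data frame with `label` and `region` columns; its row count
#'   sets the channel count.
#' @param native_rate Generation rate in Hz.
#' @param duration_per_state Seconds of signal per VIMS state.
#' @param bands Band definitions for the generated oscillations (default:
#'   the five physiological bands; carriers sit at band midpoints).
#' @param kappa 3 x bands matrix (rows `VIMS_0`, `VIMS_1`, `VIMS_2`) of von
#'   Mises concentrations, or `"separable"` / `"null"` for the built-in
#'   profiles (`"null"`: identical synchrony in every state).
#' @param region_multipliers Named multipliers applied to kappa per scalp
#'   region, creating regional connectivity structure.
#' @param amplitude Named per-band oscillation amplitudes (microvolt scale).
#' @param amplitude_jitter Half-width of the per-subject uniform amplitude
#'   factor (0.2 means each subject draws band amplitudes in +/-20%).
#' @param noise_sd Additive white-noise standard deviation.
#' @param jitter_tau Correlation time (s) of the phase jitter process.
#' @param freq_wander Relative SD of the slow carrier-frequency random walk.
#' @param seed Master seed; every recording derives its own stream from it.
#' @return A `synth_config` object (list).
#' @export
synth_config <- function(n_subjects = 25L,
                         montage = vims_channels,
                         native_rate = 2048,
                         duration_per_state = 60,
                         bands = eeg_bands(c("delta", "theta", "alpha",
                                             "beta", "gamma")),
                         kappa = "separable",
                         region_multipliers = c(frontal = 1.2, temporal = 0.9,
                                                central = 1.1, parietal = 1.0,
                                                occipital = 0.8),
                         amplitude = NULL,
                         amplitude_jitter = 0.2,
                         noise_sd = 0.3,
                         jitter_tau = 0.25,
                         freq_wander = 0.01,
                         seed = 1L) {
  states <- c("VIMS_0", "VIMS_1", "VIMS_2")
  if (is.character(kappa)) {
    profile <- match.arg(kappa, c("separable", "null"))
    kappa <- matrix(1.5, 3, nrow(bands),
                    dimnames = list(states, bands$name))
    if (profile == "separable") {
      if ("gamma" %in% bands$name) kappa[, "gamma"] <- c(8, 2, 0.5)
      if ("beta" %in% bands$name) kappa[, "beta"] <- c(3, 2, 1.2)
    }
  }
  kappa <- as.matrix(kappa)
  if (is.null(rownames(kappa))) rownames(kappa) <- states
  if (is.null(colnames(kappa))) colnames(kappa) <- bands$name
  if (any(kappa < 0)) stop("kappa must be non-negative")
  if (is.null(amplitude)) {
    amplitude <- stats::setNames(rep(1, nrow(bands)), bands$name)
  }
  stopifnot(nrow(kappa) == 3L, ncol(kappa) == nrow(bands),
            all(region_multipliers >= 0),
            abs(duration_per_state * native_rate -
                  round(duration_per_state * native_rate)) < 1e-9)
  structure(list(n_subjects = as.integer(n_subjects), montage = montage,
                 native_rate = native_rate,
                 duration_per_state = duration_per_state,
                 bands = bands, kappa = kappa,
                 region_multipliers = region_multipliers,
                 amplitude = amplitude, amplitude_jitter = amplitude_jitter,
                 noise_sd = noise_sd, jitter_tau = jitter_tau,
                 freq_wander = freq_wander, seed = as.integer(seed)),
            class = "synth_config")
}

synth_states <- c("VIMS_0", "VIMS_1", "VIMS_2")

# deterministic per-(subject, purpose) seed below 2^31
derive_seed <- function(seed, subject, salt) {
  (as.numeric(seed) * 7919 + subject * 104729 + salt * 65537) %% 2147483647
}

# per-subject band amplitude factors, stable across states
subject_amplitudes <- function(cfg, subject) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, subject, 1L))
  f <- stats::runif(nrow(cfg$bands), 1 - cfg$amplitude_jitter,
                    1 + cfg$amplitude_jitter)
  stats::setNames(cfg$amplitude[cfg$bands$name] * f, cfg$bands$name)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
}

# core synthesis: one continuous stretch whose kappa may switch between
# consecutive equal-length blocks (one block per state)
synth_blocks <- function(cfg, subject, states) {
  rate <- cfg$native_rate
  n_block <- as.integer(round(cfg$duration_per_state * rate))
  n <- n_block * length(states)
  nc <- nrow(cfg$montage)
  amp <- subject_amplitudes(cfg, subject)
  mult <- cfg$region_multipliers[cfg$montage$region]
  t_idx <- seq_len(n)
  x <- matrix(0, nc, n)
  for (b in seq_len(nrow(cfg$bands))) {
    band <- cfg$bands$name[b]
    f0 <- (cfg$bands$lo[b] + cfg$bands$hi[b]) / 2
    # shared oscillator: slow random-walk frequency wander around f0
    df <- ar1_process(1L, n, rate, tau = 1)[1, ] * cfg$freq_wander * f0
    phi <- 2 * pi * cumsum(f0 + df) / rate
    # fixed per-channel phase lags: PLV ignores constant offsets, but they
    # keep the cross-channel average (the re-reference signal) near zero
    mu <- stats::runif(nc, -pi, pi)
    # per-channel slowly-varying von Mises jitter, kappa per state block;
    # the Gaussian copula process is pushed through the von Mises quantile
    # function (tabulated on a uniform probability grid) inside C++
    g <- ar1_process(nc, n, rate, cfg$jitter_tau)
    p_grid <- seq(0, 1, length.out = 4096L)
    for (s in seq_along(states)) {
      cols <- ((s - 1L) * n_block + 1L):(s * n_block)
      kap <- cfg$kappa[states[s], band] * mult
      for (k in unique(kap)) {
        rows <- which(kap == k)
        qtab <- vonmises_quantile(p_grid, k)
        x[rows, cols] <- x[rows, cols] +
          vm_band_signal(g[rows, cols, drop = FALSE], qtab, phi[cols],
                         mu[rows], amp[band])
      }
    }
  }
  if (cfg$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(nc * n, sd = cfg$noise_sd), nc, n)
  }
  x
}

#' Generate one 60-s state recording
#'
#' @param cfg A [synth_config].
#' @param subject Subject index (1-based).
#' @param state One of `"VIMS_0"`, `"VIMS_1"`, `"VIMS_2"`.
#' @return An [eeg_recording] at the native rate.
#' @export
generate_recording <- function(cfg, subject, state = synth_states) {
  stopifnot(inherits(cfg, "synth_config"))
  state <- match.arg(state)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, subject, 10L + match(state, synth_states)))
  x <- synth_blocks(cfg, subject, state)
  eeg_recording(x, cfg$native_rate, cfg$montage$label,
                stats::setNames(cfg$montage$region, cfg$montage$label))
}

#' Event times of a synthetic session
#'
#' The synthetic protocol is deterministic: rest starts at 0 s, the light
#' report falls at 1.5x and the heavy report at 3x the per-state duration.
#' Exposed separately so cohort-scale pipelines can know the event layout
#' without generating (and holding) the recordings themselves.
#'
#' @param cfg A [synth_config].
#' @param subjects Subject indices.
#' @return Data frame with `subject`, `rest_start`, `t_light`, `t_heavy`.
#' @export
session_events <- function(cfg, subjects = seq_len(cfg$n_subjects)) {
  d <- cfg$duration_per_state
  data.frame(subject = subjects, rest_start = 0, t_light = 1.5 * d,
             t_heavy = 3 * d)
}

#' Generate one continuous three-state session
#'
#' Concatenates the three 60-s state stretches into one continuous
#' recording (shared oscillator phase runs through the whole session; only
#' the jitter concentration switches at state boundaries) and reports the
#' event times that place each state window exactly where
#' [extract_state_windows()] expects it: rest starts at 0 s, the light
#' report falls at 90 s and the heavy report at 180 s, where the session
#' ends.
#'
#' @param cfg A [synth_config].
#' @param subject Subject index.
#' @return List with `recording` (an [eeg_recording]) and `events` (one-row
#'   data frame: `subject`, `rest_start`, `t_light`, `t_heavy`).
#' @export
generate_session <- function(cfg, subject) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, subject, 2L))
  x <- synth_blocks(cfg, subject, synth_states)
  rec <- eeg_recording(x, cfg$native_rate, cfg$montage$label,
                       stats::setNames(cfg$montage$region, cfg$montage$label))
  list(recording = rec, events = session_events(cfg, subject))
}

#' Generate and write a full synthetic cohort
#'
#' One BDF file per subject plus a tab-separated state-timestamp sidecar
#' (`events.tsv`), so synthetic data enters the pipeline through the same
#' ingestion path as real recordings.
#'
#' @param cfg A [synth_config].
#' @param dir Output directory (created if needed).
#' @param format `"bdf"` or `"edf"`.
#' @return Invisibly, a list with the recording `paths` and the `events`
#'   data frame.
#' @export
generate_dataset <- function(cfg, dir, format = "bdf") {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(cfg$n_subjects)
  events <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    ses <- generate_session(cfg, s)
    paths[s] <- file.path(dir, sprintf("sub-%02d.%s", s, format))
    write_eeg(ses$recording, paths[s], format = format)
    events[[s]] <- ses$events
  }
  events <- do.call(rbind, events)
  write_state_events(events, file.path(dir, "events.tsv"))
  invisible(list(paths = paths, events = events))
}
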