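# Shared fixtures: tiny recordings and a small synthetic montage.

tone_recording <- function(freqs, rate = 1024, duration = 10,
                           labels = paste0("ch", seq_along(freqs))) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  data <- do.call(rbind, lapply(freqs, function(f) sin(2 * pi * f * t)))
  eeg_recording(data, rate, labels)
}

rms <- function(x) sqrt(mean(x^2))

# 64-channel recording over the full BioSemi montage (random signal)
full_montage_recording <- function(rate = 256, duration = 2) {
  n <- rate * duration
  eeg_recording(matrix(rnorm(64 * n), 64), rate, biosemi64_montage$label)
}

# small single-band generator config with flat regional multipliers
flat_cfg <- function(kappa, band = "full", nch = 12, seed = 1,
                     duration = 60, tau = NULL, noise_sd = 0.3) {
  bands <- eeg_bands(band)
  km <- matrix(kappa, 3, 1,
               dimnames = list(c("VIMS_0", "VIMS_1", "VIMS_2"), band))
  args <- list(
    n_subjects = 1L,
    montage = vims_channels[round(seq(1, 52, length.out = nch)), ],
    bands = bands, kappa = km, duration_per_state = duration,
    region_multipliers = c(frontal = 1, temporal = 1, central = 1,
                           parietal = 1, occipital = 1),
    noise_sd = noise_sd, seed = seed)
  if (!is.null(tau)) args$jitter_tau <- tau
  do.call(synth_config, args)
}

# run one recording through the standard preprocessing + band split and
# return the per-segment phase matrices of the requested band (phase is
# extracted over the whole recording, then segmented, as in session_plv)
pipeline_phases <- function(rec, band, win_len = 3) {
  rec <- preprocess_recording(rec)
  brec <- band_decompose(rec, eeg_bands(band))[[band]]
  ph <- instantaneous_phase(brec$data, rate = brec$rate)
  segment_window(ph$phase, rate = brec$rate, win_len = win_len)
}
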