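# Synthetic phase-coupled EEG generator and its synchrony oracle.

test_that("expected_plv is the squared Bessel ratio with the right limits", {
  expect_equal(expected_plv(0), 0)
  expect_equal(expected_plv(Inf), 1)
  expect_gt(expected_plv(1e4), 0.999)
  ks <- c(0.1, 0.5, 1, 2, 4, 8, 16)
  vals <- expected_plv(ks)
  expect_true(all(diff(vals) > 0))        # monotone in kappa
  expect_true(all(vals >= 0 & vals <= 1))
  # closed form at kappa = 2 against the direct Bessel quotient
  expect_equal(expected_plv(2), (besselI(2, 1) / besselI(2, 0))^2)
  # mixed concentrations multiply the resultants
  expect_equal(expected_plv(2, 8),
               sqrt(expected_plv(2)) * sqrt(expected_plv(8)))
  expect_error(expected_plv(-1), "non-negative")
})

test_that("the von Mises quantile function matches its defining distribution", {
  p <- seq(0.001, 0.999, length.out = 400)
  for (k in c(0, 0.7, 3, 40)) {
    q <- vimsnet:::vonmises_quantile(p, k)
    expect_true(all(diff(q) >= 0))
    # empirical resultant of quantile-transformed uniforms ~ I1/I0
    set.seed(50 + k)
    th <- vimsnet:::vonmises_quantile(runif(2e4), k)
    r_emp <- Mod(mean(exp(1i * th)))
    r_th <- if (k == 0) 0 else besselI(k, 1) / besselI(k, 0)
    expect_equal(r_emp, r_th, tolerance = 0.02)
  }
  expect_equal(vimsnet:::vonmises_quantile(c(0.1, 0.9), Inf), c(0, 0))
})

test_that("recordings have the configured geometry and are reproducible", {
  cfg <- flat_cfg(2, nch = 8, duration = 6, seed = 42)
  rec <- generate_recording(cfg, 1, "VIMS_0")
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec$data), c(8L, 6 * 2048))
  expect_equal(rec$rate, 2048)
  # byte-identical regeneration under the same seed
  rec2 <- generate_recording(cfg, 1, "VIMS_0")
  expect_identical(rec$data, rec2$data)
  # a different subject gets different data
  expect_false(identical(rec$data,
                         generate_recording(cfg, 2, "VIMS_0")$data))
  expect_error(synth_config(kappa = matrix(-1, 3, 5)), "non-negative")
})

test_that("kappa = Inf yields full synchrony and kappa = 0 the independence floor", {
  # jitter off: every pair phase-locked at PLV 1 (interior segments; the
  # first/last segment touch the recording boundary where the analytic
  # signal leaks)
  cfg_inf <- flat_cfg(Inf, nch = 6, duration = 15, seed = 5, noise_sd = 0)
  ph <- pipeline_phases(generate_recording(cfg_inf, 1, "VIMS_0"), "full")
  m <- average_matrices(lapply(ph[2:4], plv_matrix))
  expect_true(all(abs(m[upper.tri(m)] - 1) < 1e-3))

  # uniform jitter: per-segment PLV near the finite-N floor for N = 3072
  cfg0 <- flat_cfg(0, nch = 6, duration = 60, seed = 6)
  ph0 <- pipeline_phases(generate_recording(cfg0, 1, "VIMS_0"), "full")
  vals <- unlist(lapply(ph0, function(p) {
    m <- plv_matrix(p)
    m[upper.tri(m)]
  }))
  # the slow jitter has ~N_eff << N independent draws per segment, so the
  # floor sits above the iid value 0.016; the oracle simulation gives the
  # right scale
  set.seed(60)
  oracle <- oracle_segment_plv(0, 60)
  expect_equal(mean(vals), mean(oracle), tolerance = 0.25)
  expect_lt(mean(vals), 0.35)
})

test_that("pipeline PLV at intermediate kappa matches the Monte-Carlo oracle", {
  kappa <- 2
  cfg <- flat_cfg(kappa, nch = 10, duration = 120, seed = 8)
  ph <- pipeline_phases(generate_recording(cfg, 1, "VIMS_0"), "full")
  vals <- unlist(lapply(ph, function(p) {
    m <- plv_matrix(p)
    m[upper.tri(m)]
  }))
  set.seed(61)
  oracle <- oracle_segment_plv(kappa, 120)
  # pipeline per-segment mean within the MC oracle's confidence band
  # (plus a small allowance for filter smoothing)
  se <- sd(oracle) / sqrt(length(oracle))
  expect_lt(abs(mean(vals) - mean(oracle)), 4 * se + 0.02)
})

test_that("measured PLV increases monotonically in kappa on paired segments", {
  plv_per_seg <- function(kappa) {
    cfg <- flat_cfg(kappa, nch = 6, duration = 30, seed = 9)
    ph <- pipeline_phases(generate_recording(cfg, 1, "VIMS_0"), "full")
    vapply(ph, function(p) {
      m <- plv_matrix(p)
      mean(m[upper.tri(m)])
    }, numeric(1))
  }
  p1 <- plv_per_seg(0.5)
  p2 <- plv_per_seg(2)
  p3 <- plv_per_seg(8)
  # same seed => paired comparisons segment by segment
  expect_gte(mean(p2 > p1), 0.95)
  expect_gte(mean(p3 > p2), 0.95)
})

test_that("regional multipliers create the oracle-predicted connectivity contrast", {
  band <- "full"
  km <- matrix(3, 3, 1, dimnames = list(c("VIMS_0", "VIMS_1", "VIMS_2"),
                                        band))
  idx <- c(1:6, 24:29)                    # 6 frontal + 6 central channels
  cfg <- synth_config(n_subjects = 1, montage = vims_channels[idx, ],
                      bands = eeg_bands(band), kappa = km,
                      duration_per_state = 120,
                      region_multipliers = c(frontal = 2, temporal = 1,
                                             central = 0.5, parietal = 1,
                                             occipital = 1),
                      noise_sd = 0.3, seed = 10)
  ph <- pipeline_phases(generate_recording(cfg, 1, "VIMS_0"), band)
  avg <- average_matrices(lapply(ph, plv_matrix))
  regions <- vims_channels$region[idx]
  fr <- which(regions == "frontal")
  ce <- which(regions == "central")
  within <- function(rows) {
    sub <- avg[rows, rows]
    mean(sub[upper.tri(sub)])
  }
  observed_gap <- within(fr) - within(ce)
  predicted_gap <- expected_plv(3 * 2) - expected_plv(3 * 0.5)
  expect_gt(observed_gap, 0.5 * predicted_gap)
  # per-segment oracle of the same contrast, as the quantitative reference
  set.seed(62)
  or_hi <- mean(oracle_segment_plv(6, 40))
  or_lo <- mean(oracle_segment_plv(1.5, 40))
  expect_equal(observed_gap, or_hi - or_lo, tolerance = 0.3)
})

test_that("sessions place the three states where the window extractor expects", {
  cfg <- flat_cfg(2, nch = 6, duration = 6, seed = 11)
  ses <- generate_session(cfg, 1)
  expect_equal(ncol(ses$recording$data), 3 * 6 * 2048)
  expect_equal(ses$events$t_light, 9)
  expect_equal(ses$events$t_heavy, 18)
  w <- extract_state_windows(ses$recording, ses$events$rest_start,
                             ses$events$t_light, ses$events$t_heavy,
                             duration = 6)
  expect_equal(unname(w$VIMS_0["start"]), 1)
  expect_equal(unname(w$VIMS_2["end"]), ncol(ses$recording$data))
})

test_that("datasets write one BDF per subject plus a sidecar and reload cleanly", {
  cfg <- flat_cfg(2, nch = 4, duration = 3, seed = 12)
  cfg$n_subjects <- 2L
  dir <- withr::local_tempdir()
  out <- generate_dataset(cfg, dir)
  expect_length(out$paths, 2L)
  expect_true(all(file.exists(out$paths)))
  ev <- read_state_events(file.path(dir, "events.tsv"))
  expect_equal(nrow(ev), 2L)
  back <- read_eeg(out$paths[1])
  expect_equal(nrow(back$data), 4L)
  expect_equal(back$rate, 2048)
  # BDF quantization leaves the signal essentially intact
  orig <- generate_session(cfg, 1)$recording
  expect_lt(max(abs(back$data - orig$data)), 1e-3)
})
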