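test_that("ideal band-pass keeps exact in-band bins and kills the rest", {
  fps <- 30; t <- (0:299) / fps
  cfg <- bandpass_config()
  expect_equal(cfg$bandwidth, 2.7)

  s1 <- sin(2 * pi * 1.0 * t) + 5          # in-band exact bin + DC
  expect_equal(temporal_bandpass(s1, fps, cfg), s1 - mean(s1), tolerance = 1e-12)

  s5 <- sin(2 * pi * 5.0 * t)              # out-of-band exact bin
  expect_lt(max(abs(temporal_bandpass(s5, fps, cfg))), 1e-10)

  lo <- sin(2 * pi * 0.1 * t); mid <- sin(2 * pi * 1.0 * t)
  out <- temporal_bandpass(lo + mid, fps, cfg)
  expect_equal(out, mid - mean(mid), tolerance = 1e-10)

  # linear operator
  a <- rnorm(300); b <- rnorm(300)
  expect_equal(temporal_bandpass(2 * a - b, fps, cfg),
               2 * temporal_bandpass(a, fps, cfg) - temporal_bandpass(b, fps, cfg),
               tolerance = 1e-12)

  expect_rr_error(temporal_bandpass(a, fps, bandpass_config(0.3, 16)),
                  "rr_config_error")
  expect_rr_error(bandpass_config(0, 3), "rr_config_error")
})

# shared fixture: grating breathing at 1 Hz with 0.1-px displacement
breathing_stack <- function(amp_px = 0.1, n = 150, omega = pi / 2) {
  t <- (0:(n - 1)) / 30
  grating_clip(n, 24, 24, omega = omega, disp = amp_px * sin(2 * pi * 1.0 * t))
}

test_that("alpha = 0 stores the band-passed phase unchanged", {
  clip <- breathing_stack()
  st <- build_pyramid_stack(clip, levels = 1)
  ps0 <- amplify_phase(st, bandpass_config(), alpha = 0)
  # oracle: unwrap + band-pass the raw phase at one pixel; for a rigidly
  # translating grating every retained pixel carries the same motion term
  raw <- phase_series(st, 1, 1, c(12, 12))
  oracle <- temporal_bandpass(as.numeric(raw), 30, bandpass_config())
  expect_equal(ps0$series[["s1.o1"]][, 1], oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("amplification obeys the (1 + alpha) gain law", {
  clip <- breathing_stack(amp_px = 0.1)
  st <- build_pyramid_stack(clip, levels = 1)
  sig0 <- aggregate_signal(amplify_phase(st, bandpass_config(), alpha = 0))
  sig40 <- aggregate_signal(amplify_phase(st, bandpass_config(), alpha = 40))
  ratio <- max(abs(sig40$values)) / max(abs(sig0$values))
  expect_equal(ratio, 41, tolerance = 0.10 * 41)

  # amplified increment is exactly linear in alpha
  sig10 <- aggregate_signal(amplify_phase(st, bandpass_config(), alpha = 10))
  inc10 <- (sig10$values - sig0$values) / 10
  inc40 <- (sig40$values - sig0$values) / 40
  expect_equal(inc10, inc40, tolerance = 1e-9)

  # absolute calibration: at alpha = 0 the pooled signal is omega * delta(t)
  expect_equal(max(abs(sig0$values)), (pi / 2) * 0.1, tolerance = 0.15 * (pi / 2) * 0.1)
})

test_that("static stacks yield a null signal and empty sets are rejected", {
  static <- grating_clip(40, 24, 24, omega = pi / 2)
  st <- build_pyramid_stack(static, levels = 1)
  ps <- amplify_phase(st, bandpass_config(), alpha = 40)
  expect_lt(max(abs(aggregate_signal(ps)$values)), 1e-8)

  # all-zero frames: every pixel below the (strict) amplitude floor
  st0 <- build_pyramid_stack(video_clip(array(0, c(40, 24, 24)), 30),
                             levels = 1)
  expect_rr_error(amplify_phase(st0, bandpass_config()), "rr_empty_signal_error")
})

test_that("aggregation pools with amplitude^2 weights and sign alignment", {
  t <- (0:99) / 30
  wave <- sin(2 * pi * 1 * t)
  mk_set <- function(series_list, weights) {
    structure(list(series = list(a = do.call(cbind, series_list)),
                   weights = list(a = weights), alpha = 0,
                   cfg = bandpass_config(), fps = 30, clip_id = "x",
                   band_ids = "a", n_frames = length(t)),
              class = "phase_signal_set")
  }
  one <- aggregate_signal(mk_set(list(wave), 2))
  expect_equal(one$values, wave - mean(wave), tolerance = 1e-12)

  two <- aggregate_signal(mk_set(list(wave, wave), c(0.3, 5)))
  expect_equal(two$values, wave - mean(wave), tolerance = 1e-12)

  flipped <- aggregate_signal(mk_set(list(wave, -wave), c(1, 1)))
  expect_equal(abs(flipped$values), abs(wave - mean(wave)), tolerance = 1e-12)
  expect_gt(max(abs(flipped$values)), 0.9)   # aligned, not cancelled

  expect_rr_error(aggregate_signal(mk_set(list(wave), 0)),
                  "rr_empty_signal_error")
})

test_that("antiphase ROI arcs survive sign-aligned pooling", {
  out <- generate_clip(small_cfg(seed = 40, antiphase = TRUE, noise_sd = 0.5))
  m <- measure_rr(out$clip, out$roi)
  expect_equal(m$rr_hz, out$truth$true_rr_hz, tolerance = 0.05)
})

test_that("pooling preserves the driving frequency on the DFT grid", {
  for (f in c(0.6, 2.2)) {   # exact bins of the 150-sample, 30-fps grid
    t <- (0:149) / 30
    clip <- grating_clip(150, 24, 24, omega = pi / 2,
                         disp = 0.15 * sin(2 * pi * f * t))
    st <- build_pyramid_stack(clip, levels = 1)
    sig <- aggregate_signal(amplify_phase(st, bandpass_config(), alpha = 40))
    sp <- compute_spectrum(respiratory_signal(sig$values, 30))
    expect_equal(sp$freqs[which.max(sp$magnitude)], f)
  }
})

test_that("merging ROI signal sets pools their pixels", {
  clip <- breathing_stack()
  st <- build_pyramid_stack(clip, levels = 1)
  a <- amplify_phase(st, bandpass_config(), alpha = 0)
  merged <- merge_signal_sets(list(a, a))
  expect_equal(length(merged$band_ids), 2 * length(a$band_ids))
  # pooling duplicated content changes nothing
  expect_equal(aggregate_signal(merged)$values, aggregate_signal(a)$values,
               tolerance = 1e-12)
})
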