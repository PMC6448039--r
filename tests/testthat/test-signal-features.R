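fs <- 40000

test_that("the band-pass stage passes 1500 Hz, rejects 100 Hz, and is zero-phase", {
  t <- dcnfl:::trace_time(make_trace(numeric(4001)))
  mid <- t > 0 & t < 55  # away from filter edge transients

  tone <- make_trace(sin(2 * pi * 1.5 * t))  # 1500 Hz (t in ms)
  hf <- preprocess(tone, artifact_window = c(0, 0), seed = 1)$hf
  expect_lt(abs(max(abs(hf$samples[1, mid])) - 1), 0.05)

  slow <- make_trace(sin(2 * pi * 0.1 * t))  # 100 Hz
  hf2 <- preprocess(slow, artifact_window = c(0, 0), seed = 1)$hf
  expect_lt(20 * log10(max(abs(hf2$samples[1, mid]))), -40)

  ## an in-band burst keeps its envelope peak position
  burst <- numeric(4001)
  ctr <- 801 + round(30 * fs / 1000)
  idx <- (ctr - 60):(ctr + 60)
  burst[idx] <- sin(2 * pi * 1.6 * t[idx]) * exp(-((idx - ctr) / 20)^2)
  tr <- make_trace(burst)
  hf3 <- preprocess(tr, artifact_window = c(0, 0), seed = 1)$hf
  expect_lt(abs(which.max(abs(hf3$samples[1, ])) - which.max(abs(burst))), 2)
})

test_that("artifact replacement is local and matches baseline statistics", {
  cfg <- generator_config(n_animals = 1, rng_seed = 6)
  an <- make_cohort(cfg)[[1]]
  tr <- synthesize_trial(an, "RSN", cfg, seed = 3)
  pp <- preprocess(tr, artifact_window = c(0, 3), seed = 1)

  art <- dcnfl:::window_indices(tr, 0, 3)
  outside <- setdiff(seq_len(ncol(tr$samples)), art)
  expect_identical(pp$clean$samples[, outside], tr$samples[, outside])

  base <- dcnfl:::window_indices(tr, -15, -5)
  expect_lt(abs(stats::sd(pp$clean$samples[1, art]) -
                  stats::sd(tr$samples[1, base])),
            stats::sd(tr$samples[1, base]))

  expect_error(preprocess(tr, artifact_window = c(-12, 3)), "baseline")
})

test_that("slow-wave features follow their definitions exactly", {
  t <- dcnfl:::trace_time(make_trace(numeric(4001)))
  x <- numeric(4001)
  ## smooth bumps with extrema +50 uV at 10 ms and -150 uV at 18 ms
  x <- 50 * exp(-(t - 10)^2 / 2) - 150 * exp(-(t - 18)^2 / 2)
  lf <- lf_features(make_trace(x), 1)
  expect_equal(lf$n1_latency, 18, tolerance = 1e-6)
  expect_equal(lf$p1n1_amplitude, x[t == 18] - x[t == 10], tolerance = 1e-9)
  expect_equal(lf$p1n1_slope, lf$p1n1_amplitude / 8, tolerance = 1e-3)

  flat <- lf_features(make_trace(numeric(4001)), 1)
  expect_equal(flat$flag, "no_deflection")
  expect_true(is.na(flat$n1_latency))
})

test_that("noiseless generator extrema are recovered to machine precision", {
  cfg <- generator_config(
    n_animals = 1, noise_sd = 0, animal_variability_sd = 0,
    electrode_shift_sd = 0, rng_seed = 2,
    physiology = list(p1_latency = 12, p1_amplitude = 80,
                      n1_latency = 20, n1_amplitude = -120,
                      n1_latency_type = 0, n1_latency_side = 0,
                      n1_amplitude_type = 0, right_gain = 0,
                      p1_latency_trial_sd = 0, n1_latency_trial_sd = 0,
                      hf_rate = 0, hf_rate_type = 0))
  an <- make_cohort(cfg)[[1]]
  tr <- synthesize_trial(an, "RSN", cfg, seed = 1)
  pp <- preprocess(tr, seed = 1)
  g <- dcnfl:::channel_gains(an, "RSN")
  for (e in c(1, 4, 7)) {
    lf <- lf_features(pp$clean, e)
    expect_lt(abs(lf$p1["time"] - 12), 1000 / fs + 1e-9)
    expect_lt(abs(lf$n1["time"] - 20), 1000 / fs + 1e-9)
    expect_lt(abs(lf$p1["value"] - 80 * g[e]), 1e-6)
    expect_lt(abs(lf$n1["value"] + 120 * g[e]), 1e-6)
  }
})

test_that("burst features follow their definitions on constructed traces", {
  ## rectangular pulse: area A*w, one (leading-edge) peak
  x <- numeric(4001)
  idx <- dcnfl:::window_indices(make_trace(x), 30, 32)  # 2 ms wide
  x[idx] <- 10
  hf <- hf_features(make_trace(x), 1)
  expect_equal(hf$hf_integral, 10 * 2, tolerance = 1e-9)
  expect_equal(hf$hf_peak_count, 1)

  ## spike outside the 15-55 ms window contributes nothing
  y <- numeric(4001)
  y[dcnfl:::window_indices(make_trace(y), 60, 60.1)] <- 50
  hf2 <- hf_features(make_trace(y), 1)
  expect_equal(hf2$hf_peak_count, 0)
  expect_equal(hf2$hf_integral, 0)

  ## k spikes at 10 x baseline SD over a sinusoidal baseline -> count = k
  t <- dcnfl:::trace_time(make_trace(numeric(4001)))
  base_amp <- 2
  z <- base_amp * sin(2 * pi * 1 * t)
  sd_b <- stats::sd(z[dcnfl:::window_indices(make_trace(z), -15, -5)])
  spike_times <- c(18, 25, 33, 41, 49)
  for (st in spike_times) z[which.min(abs(t - st))] <- 10 * sd_b
  hf3 <- hf_features(make_trace(z), 1)
  expect_equal(hf3$hf_peak_count, length(spike_times))
})

test_that("peak counting agrees with a brute-force scan on random traces", {
  naive_count <- function(x, idx, thr) {
    n <- 0L
    for (i in idx) {
      if (i > 1 && i < length(x) &&
          x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] > thr) n <- n + 1L
    }
    n
  }
  set.seed(99)
  for (rep in 1:50) {
    x <- stats::rnorm(500)
    idx <- 10:490
    thr <- stats::runif(1, 0, 2)
    expect_identical(dcnfl:::count_suprathreshold_peaks(x, idx, thr),
                     naive_count(x, idx, thr))
  }
})

test_that("full extraction yields 35 deterministic values with flags", {
  cfg <- generator_config(n_animals = 1, rng_seed = 13)
  an <- make_cohort(cfg)[[1]]
  tr <- synthesize_trial(an, "LPN", cfg, seed = 17)
  fv1 <- extract_features(tr, seed = 5)
  fv2 <- extract_features(tr, seed = 5)
  expect_length(fv1, 35)
  expect_identical(fv1, fv2)
  expect_length(attr(fv1, "flags"), 7)

  ## a flat trial flags every electrode without aborting
  flat <- extract_features(make_trace(numeric(4001)), seed = 1)
  expect_true(all(attr(flat, "flags") == "no_deflection"))
  expect_equal(sum(is.na(flat)), 21)  # 3 slow-wave features x 7 electrodes
})

test_that("spectrograms localize power in time and frequency", {
  t <- dcnfl:::trace_time(make_trace(numeric(4001)))
  tone <- make_trace(sin(2 * pi * 1 * t))  # 1 kHz
  sp <- compute_spectrogram(tone, 1)
  peak_bins <- apply(sp$power, 2, which.max)
  expect_true(all(abs(sp$freq[peak_bins] - 1000) <= 100))
  expect_true(all(sp$power >= 0 & sp$power <= 1))

  zero <- compute_spectrogram(make_trace(numeric(4001)), 1)
  expect_true(all(zero$power == 0))

  ## burst confined to 15-55 ms leaks little outside 10-60 ms
  cfg <- generator_config(n_animals = 1, noise_sd = 0, rng_seed = 4,
                          physiology = list(p1_amplitude = 0, n1_amplitude = 0,
                                            n1_amplitude_type = 0))
  an <- make_cohort(cfg)[[1]]
  tr <- synthesize_trial(an, "RPN", cfg, seed = 2)
  pp <- preprocess(tr, seed = 1)
  sp2 <- compute_spectrogram(pp$hf, 4)
  band <- sp2$freq >= 550 & sp2$freq <= 3300
  outside <- sp2$time < 10 | sp2$time > 60
  expect_lt(max(sp2$power[band, outside]), 0.1)

  expect_error(compute_spectrogram(make_trace(numeric(100), t0 = 50), 1,
                                   window_ms = 10), "window")
})

test_that("feature windows are half-open with floor-based indexing", {
  tr <- make_trace(numeric(4001))
  idx <- dcnfl:::window_indices(tr, 15, 55)
  expect_equal(idx[1], tr$t0_index + 15 * 40)        # 15 ms included
  expect_equal(idx[length(idx)], tr$t0_index + 55 * 40 - 1)  # 55 ms excluded
})
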