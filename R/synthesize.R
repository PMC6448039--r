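#' Construct a raw multi-electrode trace object
#'
#' @param samples 7 x T numeric matrix of voltages (uV), channels e1..e7.
#' @param sample_rate Sampling rate (Hz).
#' @param t0_index 1-based sample index of the stimulus (t = 0).
#' @return A `raw_trace` object.
#' @export
raw_trace <- function(samples, sample_rate, t0_index) {
  stopifnot(is.matrix(samples), nrow(samples) == 7,
            t0_index >= 1, t0_index <= ncol(samples))
  structure(list(samples = samples, sample_rate = sample_rate,
                 t0_index = as.integer(t0_index),
                 channels = paste0("e", 1:7)),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> 7 x %d samples @ %g kHz, t in [%.1f, %.1f] ms\n",
              ncol(x$samples), x$sample_rate / 1000,
              -(x$t0_index - 1) / x$sample_rate * 1000,
              (ncol(x$samples) - x$t0_index) / x$sample_rate * 1000))
  invisible(x)
}

## Time axis in ms relative to the stimulus.
trace_time <- function(trace) {
  (seq_len(ncol(trace$samples)) - trace$t0_index) / trace$sample_rate * 1000
}

## Half-open window [a, b) ms -> sample indices, via floor(t * fs) offsets
## from the stimulus sample.
window_indices <- function(trace, a, b) {
  fs <- trace$sample_rate
  lo <- trace$t0_index + floor(a * fs / 1000)
  hi <- trace$t0_index + floor(b * fs / 1000) - 1
  lo <- max(1L, lo)
  hi <- min(ncol(trace$samples), hi)
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

## Seventh-order smoothstep: s(0)=0, s(1)=1 with zero 1st-3rd derivatives
## at both ends, keeping the composite slow wave smooth enough that its
## spectral leakage above 550 Hz is negligible.
smoothstep7 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^4 * (35 - 84 * u + 70 * u^2 - 20 * u^3)
}

## Biphasic slow waveform: baseline -> P1 peak -> N1 trough -> baseline.
## Extrema sit exactly at (p1_latency, p1_amplitude) and
## (n1_latency, n1_amplitude).
lf_waveform <- function(t, np, rise = 4, recovery = 12) {
  onset <- np$p1_latency - rise
  w <- numeric(length(t))
  i <- t >= onset & t < np$p1_latency
  w[i] <- np$p1_amplitude * smoothstep7((t[i] - onset) / rise)
  i <- t >= np$p1_latency & t < np$n1_latency
  w[i] <- np$p1_amplitude + (np$n1_amplitude - np$p1_amplitude) *
    smoothstep7((t[i] - np$p1_latency) / (np$n1_latency - np$p1_latency))
  i <- t >= np$n1_latency & t < np$n1_latency + recovery
  w[i] <- np$n1_amplitude *
    (1 - smoothstep7((t[i] - np$n1_latency) / recovery))
  w
}

## Unit-peak event kernel: a Gaussian-windowed cosine packet ~1 ms wide
## (one dominant positive lobe flanked by negative lobes). Its spectrum is
## a Gaussian centred at f0 with SD 1/(2*pi*sigma) ~ 455 Hz, lying almost
## entirely inside the 550-3300 Hz band, so the extraction band-pass
## leaves the shape (and its local-maxima profile) essentially unchanged.
hf_kernel <- function(fs, sigma = 0.25, f0 = 1600) {
  tt <- seq(-4 * sigma, 4 * sigma, by = 1000 / fs)  # ms
  cos(2 * pi * f0 * tt / 1000) * exp(-tt^2 / (2 * sigma^2))
}

## Poisson event times on [15, 55) ms thinned to a minimum separation
## (multiunit refractoriness); every retained event is an isolated peak.
hf_event_times <- function(rate, refractory) {
  n <- stats::rpois(1, rate * 40)
  if (n == 0) return(numeric(0))
  tt <- sort(stats::runif(n, 15, 55))
  keep <- tt[1]
  for (x in tt[-1]) if (x - keep[length(keep)] >= refractory) keep <- c(keep, x)
  keep
}

#' Synthesize one seven-channel evoked trial
#'
#' A trial is the sum of a stimulus artifact at t = 0 (common to all
#' channels), a smooth biphasic slow wave (P1 then N1), a burst of biphasic
#' high-frequency events confined to 15-55 ms post-stimulus, and white
#' noise. The slow wave and burst are scaled per channel by
#' `exp(-d / attenuation_length)` where d is the distance from the (shifted)
#' electrode to that nerve's response hotspot.
#'
#' @param animal A `dcn_animal` from [make_cohort()].
#' @param nerve One of `"RSN"`, `"LSN"`, `"RPN"`, `"LPN"`.
#' @param config The [generator_config()] used for the cohort.
#' @param seed Integer seed for this trial's noise and event times.
#' @param layout Electrode layout (see [electrode_layout()]).
#' @return A [raw_trace()].
#' @export
synthesize_trial <- function(animal, nerve, config = generator_config(),
                             seed = 1L, layout = electrode_layout()) {
  if (!nerve %in% NERVES)
    stop("unknown nerve label: ", nerve)
  p <- config$physiology
  fs <- config$sample_rate
  t0 <- as.integer(round(-config$trace_window[1] * fs / 1000)) + 1L
  nsamp <- as.integer(round(diff(config$trace_window) * fs / 1000)) + 1L
  t <- (seq_len(nsamp) - t0) / fs * 1000

  np <- animal$nerves[[nerve]]
  gains <- channel_gains(animal, nerve, layout)

  with_seed(seed, {
    ## trial-to-trial latency jitter (keeps P1 > 5 ms and N1 > P1)
    np_t <- np
    np_t$p1_latency <- max(5.2, np$p1_latency +
                             stats::rnorm(1, 0, p$p1_latency_trial_sd))
    np_t$n1_latency <- max(np_t$p1_latency + 1.5, np$n1_latency +
                             stats::rnorm(1, 0, p$n1_latency_trial_sd))
    lf <- lf_waveform(t, np_t, rise = p$p1_rise, recovery = p$n1_recovery)

    hf <- numeric(nsamp)
    if (np$hf_rate > 0) {
      times <- hf_event_times(np$hf_rate, p$hf_refractory)
      if (length(times)) {
        kern <- hf_kernel(fs, p$hf_kernel_sigma, p$hf_kernel_f0)
        half <- (length(kern) - 1L) %/% 2L
        amps <- np$hf_amplitude *
          stats::runif(length(times), 1 - p$hf_amp_jitter, 1 + p$hf_amp_jitter)
        centers <- t0 + floor(times * fs / 1000)
        for (k in seq_along(times)) {
          idx <- (centers[k] - half):(centers[k] + half)
          ok <- idx >= 1 & idx <= nsamp
          hf[idx[ok]] <- hf[idx[ok]] + amps[k] * kern[ok]
        }
      }
    }

    artifact <- numeric(nsamp)
    ia <- t >= 0 & t < 1
    artifact[ia] <- config$artifact_amplitude *
      sin(2 * pi * 3 * t[ia]) * exp(-t[ia] / 0.2)

    sig <- lf + hf
    samples <- matrix(0, 7, nsamp)
    for (e in 1:7) {
      samples[e, ] <- gains[e] * sig + artifact +
        if (config$noise_sd > 0) stats::rnorm(nsamp, 0, config$noise_sd) else 0
    }
    raw_trace(samples, fs, t0)
  })
}

#' Generate a full synthetic data set of trials
#'
#' Produces `n_animals x 4 nerves x n_sets x trials_per_set` trials, each
#' with its own deterministic seed derived from `config$rng_seed`, so the
#' same configuration always reproduces the identical data set. Trials are
#' materialized in memory; for large designs prefer
#' [simulate_feature_table()], which streams trials through feature
#' extraction without retaining the traces.
#'
#' @param config A [generator_config()].
#' @param layout Electrode layout.
#' @return A `trial_set`: list with `trials` (each a list of `trace`,
#'   `animal_id`, `nerve`, `trial`) and the generating `config` and cohort.
#' @export
generate_dataset <- function(config = generator_config(),
                             layout = electrode_layout()) {
  cohort <- make_cohort(config)
  per_nerve <- config$n_sets * config$trials_per_set
  trials <- vector("list", config$n_animals * 4L * per_nerve)
  k <- 0L
  for (a in seq_along(cohort)) {
    for (nv_i in seq_along(NERVES)) {
      for (tr in seq_len(per_nerve)) {
        k <- k + 1L
        seed <- derive_seed(config$rng_seed, a, nv_i, tr)
        trials[[k]] <- list(
          trace = synthesize_trial(cohort[[a]], NERVES[nv_i], config, seed, layout),
          animal_id = cohort[[a]]$animal_id,
          nerve = NERVES[nv_i],
          trial = tr,
          seed = seed
        )
      }
    }
  }
  structure(list(trials = trials, config = config, cohort = cohort),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d animals\n",
              length(x$trials), x$config$n_animals))
  invisible(x)
}

#' Expected per-electrode signal features for one animal and nerve
#'
#' Closed-form expectations of the five signal features under the
#' generative model, used as the oracle for parameter-recovery checks.
#' Latency, amplitude and slope follow directly from the slow-wave
#' parameters and channel gains. The expected high-frequency peak count is
#' the expected number of refractory-thinned burst events (a renewal-process
#' sum of gamma probabilities) times the probability that an event's
#' filtered peak clears the detection threshold; the expected integral is
#' the expected event count times the mean rectified area of one filtered
#' event. Noise-overlap terms are neglected, so these expectations are
#' accurate in the high signal-to-noise regime.
#'
#' @param animal A `dcn_animal`.
#' @param nerve Nerve label.
#' @param layout Electrode layout.
#' @param config The generating [generator_config()].
#' @return A data frame with one row per electrode and one column per
#'   signal feature.
#' @export
ground_truth_features <- function(animal, nerve, layout = electrode_layout(),
                                  config = generator_config()) {
  p <- config$physiology
  np <- animal$nerves[[nerve]]
  gains <- channel_gains(animal, nerve, layout)
  fs <- config$sample_rate

  kc <- kernel_constants(fs, p$hf_kernel_sigma, p$hf_kernel_f0)
  sigma_hf <- config$noise_sd * sqrt(2 * (3300 - 550) / fs)
  threshold <- max(3 * sigma_hf, 2)

  n_events <- expected_event_count(np$hf_rate, p$hf_refractory)
  amp_lo <- np$hf_amplitude * (1 - p$hf_amp_jitter)
  amp_hi <- np$hf_amplitude * (1 + p$hf_amp_jitter)

  amplitude <- gains * (np$n1_amplitude - np$p1_amplitude)
  ## Expected suprathreshold local maxima per event: the filtered kernel
  ## carries secondary maxima (band-limited ringing) beside its main peak;
  ## each maximum m_j crosses the threshold when amp * gain * m_j exceeds
  ## it, with amp uniform over the jitter range.
  p_detect <- vapply(gains, function(g) {
    if (g <= 0 || np$hf_amplitude <= 0) return(0)
    if (amp_hi > amp_lo) {
      sum(pmin(pmax((amp_hi * g * kc$maxima - threshold) /
                      (g * kc$maxima * (amp_hi - amp_lo)), 0), 1))
    } else {
      sum(amp_hi * g * kc$maxima > threshold)
    }
  }, 0)

  data.frame(
    electrode = 1:7,
    n1_latency = rep(np$n1_latency, 7),
    p1n1_slope = amplitude / (np$n1_latency - np$p1_latency),
    p1n1_amplitude = amplitude,
    hf_peak_count = n_events * p_detect,
    hf_integral = pmax(0, gains * np$hf_amplitude *
      (n_events * (kc$area - kc$edge_loss) -
         max(n_events - 1, 0) * mean_gap_cancellation(kc, np$hf_rate,
                                                      p$hf_refractory)))
  )
}

## Expected number of events retained after refractory thinning of a
## Poisson stream on a 40 ms window: renewal count with intervals
## refractory + Exp(rate), E[N] = sum_n P(Gamma(n, rate) <= 40 - (n-1)*tau).
expected_event_count <- function(rate, refractory, window = 40) {
  if (rate <= 0) return(0)
  n <- 1
  total <- 0
  repeat {
    rem <- window - (n - 1) * refractory
    if (rem <= 0) break
    pr <- stats::pgamma(rem, shape = n, rate = rate)
    total <- total + pr
    if (pr < 1e-12) break
    n <- n + 1
  }
  total
}

## Expected rectified-area loss per adjacent event pair: the deterministic
## two-event cancellation averaged over the renewal gap density
## (refractory + Exp(rate)); gaps beyond the kernel support cancel nothing.
mean_gap_cancellation <- function(kc, rate, refractory) {
  if (rate <= 0) return(0)
  g <- kc$gap_grid
  dens <- ifelse(g >= refractory, rate * exp(-rate * (g - refractory)), 0)
  dg <- g[2] - g[1]
  sum(kc$cancel * dens) * dg
}

## Filtered-kernel constants (per unit event peak): peak gain and rectified
## area (uV*ms) of one event after the 550-3300 Hz zero-phase filter.
## Cached per (fs, sigma).
kernel_constants <- local({
  cache <- list()
  function(fs, sigma, f0 = 1600) {
    key <- sprintf("%g_%g_%g", fs, sigma, f0)
    if (is.null(cache[[key]])) {
      kern <- hf_kernel(fs, sigma, f0)
      pad <- numeric(round(fs * 0.01))  # 10 ms of padding on each side
      x <- c(pad, kern, pad)
      y <- bandpass_filter(x, fs)
      im <- which(diff(sign(diff(y))) == -2) + 1
      maxima <- sort(y[im][y[im] > 0.03 * max(y)], decreasing = TRUE)
      dt <- 1000 / fs
      ay <- abs(y)
      ctr <- which.max(ay)
      offs <- abs(seq_along(ay) - ctr) * dt          # ms from kernel centre
      ## Expected area lost outside the 40 ms feature window for an event
      ## placed uniformly in it: (2/40) * integral over delta of the tail
      ## area beyond delta.
      half_support <- max(offs[ay > 1e-9 * max(ay)])
      tail_area <- function(delta) sum(ay[offs > delta]) * dt
      deltas <- seq(0, half_support, by = dt)
      edge_loss <- 2 / 40 * sum(vapply(deltas, tail_area, 0)) * dt
      ## Rectified-area cancellation of two identical events at gap g
      ## (deterministic: the waveforms interfere at a phase fixed by g).
      gap_grid <- seq(dt, 2 * half_support, by = dt)
      gap_shift <- round(gap_grid / dt)
      cancel <- vapply(gap_shift, function(s) {
        a <- c(y, numeric(s))
        b <- c(numeric(s), y)
        (sum(abs(a)) + sum(abs(b)) - sum(abs(a + b))) * dt
      }, 0)
      cache[[key]] <<- list(peak = max(y), maxima = maxima,
                            area = sum(ay) * dt,
                            edge_loss = edge_loss,
                            gap_grid = gap_grid, cancel = cancel)
    }
    cache[[key]]
  }
})
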