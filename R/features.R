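## Zero-phase band-pass 550-3300 Hz, 10th-order Butterworth (two 5th-order
## half-sections combined by the bandpass transform), applied
## forward-backward. Coefficients cached per sampling rate.
bandpass_filter <- local({
  cache <- list()
  function(x, fs, band = c(550, 3300)) {
    key <- sprintf("%g_%g_%g", fs, band[1], band[2])
    if (is.null(cache[[key]]))
      cache[[key]] <<- signal::butter(5, band / (fs / 2), type = "pass")
    signal::filtfilt(cache[[key]], x)
  }
})

#' Remove the stimulus artifact and compute the high-frequency trace
#'
#' Samples inside the artifact window are replaced with noise matching the
#' per-channel baseline mean and SD (measured over -15 to -5 ms), so the
#' sharp stimulus transient cannot ring through the subsequent band-pass
#' filter. The high-frequency trace is the cleaned signal filtered with a
#' zero-phase 10th-order Butterworth band-pass (550-3300 Hz).
#'
#' @param trace A [raw_trace()].
#' @param artifact_window `c(start, end)` in ms; half-open, default
#'   `c(0, 3)`. Must not overlap the baseline window (-15 to -5 ms).
#' @param seed Seed for the replacement noise (deterministic extraction).
#' @return A list with elements `clean` and `hf`, both `raw_trace` objects.
#' @export
preprocess <- function(trace, artifact_window = c(0, 3), seed = 0L) {
  stopifnot(inherits(trace, "raw_trace"))
  if (artifact_window[1] < -5 && artifact_window[2] > -15)
    stop("artifact window must not overlap the baseline window (-15 to -5 ms)")
  base_idx <- window_indices(trace, -15, -5)
  if (!length(base_idx)) stop("trace does not cover the baseline window")
  art_idx <- window_indices(trace, artifact_window[1], artifact_window[2])

  clean <- trace$samples
  if (length(art_idx)) {
    with_seed(seed, {
      for (e in 1:7) {
        m <- mean(clean[e, base_idx])
        s <- stats::sd(clean[e, base_idx])
        clean[e, art_idx] <- stats::rnorm(length(art_idx), m, s)
      }
    })
  }
  hf <- t(apply(clean, 1, bandpass_filter, fs = trace$sample_rate))
  list(clean = raw_trace(clean, trace$sample_rate, trace$t0_index),
       hf = raw_trace(hf, trace$sample_rate, trace$t0_index))
}

#' Low-frequency (slow-wave) features of one electrode
#'
#' P1 is the largest positive extremum inside the search window (default
#' 5-30 ms), N1 the most negative sample after P1 up to `n1_end` (55 ms).
#' Amplitude is the signed difference V(N1) - V(P1) in uV (typically
#' negative), slope is amplitude over the P1-to-N1 interval (uV/ms), and
#' latency is the time of N1 relative to the stimulus (ms). A trial whose
#' P1 does not exceed twice the baseline SD is flagged `no_deflection` and
#' its features set to `NA`.
#'
#' @param clean Cleaned `raw_trace` (from [preprocess()]).
#' @param electrode Electrode index (1-7).
#' @param p1_window P1 search window in ms.
#' @param n1_end End of the N1 search window in ms.
#' @return A list: `n1_latency`, `p1n1_slope`, `p1n1_amplitude`, `p1`, `n1`
#'   (each peak as time/value), and `flag` (`NA_character_` when valid).
#' @export
lf_features <- function(clean, electrode, p1_window = c(5, 30), n1_end = 55) {
  x <- clean$samples[electrode, ]
  t <- trace_time(clean)
  base_idx <- window_indices(clean, -15, -5)
  base_sd <- stats::sd(x[base_idx])

  p1_idx <- window_indices(clean, p1_window[1], p1_window[2])
  i_p1 <- p1_idx[which.max(x[p1_idx])]
  if (!is.finite(x[i_p1]) || x[i_p1] <= 2 * base_sd) {
    return(list(n1_latency = NA_real_, p1n1_slope = NA_real_,
                p1n1_amplitude = NA_real_, p1 = NULL, n1 = NULL,
                flag = "no_deflection"))
  }
  n1_idx <- window_indices(clean, t[i_p1], n1_end)
  n1_idx <- n1_idx[n1_idx > i_p1]
  i_n1 <- n1_idx[which.min(x[n1_idx])]

  amp <- x[i_n1] - x[i_p1]
  list(
    n1_latency = t[i_n1],
    p1n1_slope = amp / (t[i_n1] - t[i_p1]),
    p1n1_amplitude = amp,
    p1 = c(time = t[i_p1], value = x[i_p1]),
    n1 = c(time = t[i_n1], value = x[i_n1]),
    flag = NA_character_
  )
}

#' High-frequency (multiunit burst) features of one electrode
#'
#' The peak count is the number of strict local maxima of the signed
#' band-passed trace inside 15-55 ms whose value exceeds 3 x the baseline
#' SD (baseline: -15 to -5 ms), subject to a small absolute floor
#' (`min_threshold`) that guards noiseless synthetic traces against
#' counting numerical residue. The integral is the rectified area of the
#' band-passed trace over 15-55 ms, less the expected baseline-noise area
#' (mean rectified baseline x 40 ms), floored at zero.
#'
#' @param hf Band-passed `raw_trace` (from [preprocess()]).
#' @param electrode Electrode index (1-7).
#' @param window Feature window in ms (half-open).
#' @param min_threshold Absolute detection floor in uV (a minimum
#'   physically meaningful multiunit event size; also keeps band-limited
#'   ringing sidelobes of large events from being counted as events).
#' @return A list: `hf_peak_count` (integer), `hf_integral` (uV*ms),
#'   `threshold` (uV).
#' @export
hf_features <- function(hf, electrode, window = c(15, 55), min_threshold = 2) {
  x <- hf$samples[electrode, ]
  base_idx <- window_indices(hf, -15, -5)
  if (length(base_idx) < 2) stop("degenerate trace: empty baseline window")
  win_idx <- window_indices(hf, window[1], window[2])

  threshold <- max(3 * stats::sd(x[base_idx]), min_threshold)
  count <- count_suprathreshold_peaks(x, win_idx, threshold)

  dt <- 1000 / hf$sample_rate
  integral <- sum(abs(x[win_idx])) * dt -
    mean(abs(x[base_idx])) * diff(window)
  list(hf_peak_count = count, hf_integral = max(0, integral),
       threshold = threshold)
}

## Local maxima above threshold, vectorized. A peak rises strictly from
## the left and does not rise to the right, so a flat-topped pulse counts
## exactly once (at its leading edge); for generic noisy signals this
## coincides with strict local maxima. Neighbours just outside the window
## still count for the comparison.
count_suprathreshold_peaks <- function(x, idx, threshold) {
  if (!length(idx)) return(0L)
  i <- idx[idx > 1 & idx < length(x)]
  v <- x[i]
  sum(v > x[i - 1] & v >= x[i + 1] & v > threshold)
}

#' Extract the full 35-value feature vector of one trial
#'
#' Runs [preprocess()] then [lf_features()] and [hf_features()] on each of
#' the seven electrodes. Electrode-level flags are propagated (flagged
#' low-frequency features become `NA`) without aborting the trial.
#'
#' @param trial A [raw_trace()].
#' @param seed Seed for artifact-replacement noise.
#' @param artifact_window Passed to [preprocess()].
#' @return A named numeric vector of 35 values (`e1_n1_latency` ...
#'   `e7_hf_integral`) with a `flags` attribute (character, length 7).
#' @export
extract_features <- function(trial, seed = 0L, artifact_window = c(0, 3)) {
  pp <- preprocess(trial, artifact_window, seed)
  out <- numeric(0)
  flags <- character(7)
  for (e in 1:7) {
    lf <- lf_features(pp$clean, e)
    hfv <- hf_features(pp$hf, e)
    v <- c(lf$n1_latency, lf$p1n1_slope, lf$p1n1_amplitude,
           hfv$hf_peak_count, hfv$hf_integral)
    names(v) <- feature_column(e, SF_NAMES)
    out <- c(out, v)
    flags[e] <- if (is.na(lf$flag)) "" else lf$flag
  }
  attr(out, "flags") <- flags
  out
}

#' Simulate a cohort and extract its feature table in one pass
#'
#' Generates every trial of the configured design and streams it through
#' [extract_features()] without retaining the raw traces, which keeps the
#' memory footprint flat even for the full 6160-trial design. Identical
#' seeds are used as in [generate_dataset()], so the two routes agree
#' trial-for-trial.
#'
#' @param config A [generator_config()].
#' @param layout Electrode layout.
#' @param cohort Optional pre-built cohort (defaults to
#'   `make_cohort(config)`).
#' @return A feature table: data frame with `animal`, `nerve`, `trial`
#'   label columns and 35 feature columns.
#' @export
simulate_feature_table <- function(config = generator_config(),
                                   layout = electrode_layout(),
                                   cohort = NULL) {
  if (is.null(cohort)) cohort <- make_cohort(config)
  per_nerve <- config$n_sets * config$trials_per_set
  n <- length(cohort) * 4L * per_nerve
  feats <- matrix(NA_real_, n, 35,
                  dimnames = list(NULL, input_columns()))
  animal <- character(n); nerve <- character(n); trial <- integer(n)
  k <- 0L
  for (a in seq_along(cohort)) {
    for (nv_i in seq_along(NERVES)) {
      for (tr in seq_len(per_nerve)) {
        k <- k + 1L
        seed <- derive_seed(config$rng_seed, a, nv_i, tr)
        trace <- synthesize_trial(cohort[[a]], NERVES[nv_i], config, seed, layout)
        fv <- extract_features(trace, seed = derive_seed(seed, 7L))
        feats[k, names(fv)] <- fv
        animal[k] <- cohort[[a]]$animal_id
        nerve[k] <- NERVES[nv_i]
        trial[k] <- tr
      }
    }
  }
  tab <- data.frame(animal = animal,
                    nerve = factor(nerve, levels = NERVES),
                    trial = trial)
  cbind(tab, as.data.frame(feats))
}

#' Short-time power spectrogram of one channel
#'
#' 10 ms rolling windows with 5 ms overlap, min-max normalized to \[0, 1\]
#' per trace (an all-zero trace stays all-zero). Diagnostic only; the
#' classifier never sees spectrogram values.
#'
#' @param trace A [raw_trace()].
#' @param electrode Electrode index (1-7).
#' @param window_ms Window length (ms).
#' @param overlap_ms Overlap between consecutive windows (ms).
#' @return A list: `power` (frequency x time matrix in \[0, 1\]), `freq`
#'   (Hz), `time` (window-center times, ms relative to the stimulus).
#' @export
compute_spectrogram <- function(trace, electrode, window_ms = 10,
                                overlap_ms = 5) {
  x <- trace$samples[electrode, ]
  fs <- trace$sample_rate
  nwin <- round(window_ms * fs / 1000)
  if (nwin > length(x)) stop("window longer than trace")
  hop <- nwin - round(overlap_ms * fs / 1000)
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  nf <- nwin %/% 2 + 1
  pow <- matrix(0, nf, length(starts))
  han <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nwin - 1)] * han
    sp <- stats::fft(seg)[seq_len(nf)]
    pow[, j] <- Mod(sp)^2
  }
  rng <- range(pow)
  if (rng[2] > rng[1]) pow <- (pow - rng[1]) / (rng[2] - rng[1])
  list(power = pow,
       freq = (seq_len(nf) - 1) * fs / nwin,
       time = (starts + nwin / 2 - trace$t0_index) / fs * 1000)
}
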