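## Shared fixtures, built in code. Heavy tables are memoised per test run.

## Small but fully structured cohort for classifier-level tests.
small_cohort_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      cfg <- generator_config(n_animals = 3, n_sets = 3, trials_per_set = 8,
                              rng_seed = 42)
      tab <<- simulate_feature_table(cfg)
    }
    tab
  }
})

## Fast classifier spec for tests that only need qualitative behaviour.
fast_spec <- function(max_epochs = 150) classifier_spec(max_epochs = max_epochs)

## Generator configuration for ground-truth recovery checks: high SNR,
## saturated event detection (long attenuation length keeps every electrode
## well above threshold), sparse well-separated events, no amplitude or
## latency jitter -- the regime where the closed-form expectations hold.
recovery_config <- function(rate = 0.15, rate_type = 0.05, noise_sd = 0.02) {
  generator_config(
    n_animals = 1, noise_sd = noise_sd, animal_variability_sd = 0,
    electrode_shift_sd = 0, rng_seed = 3,
    physiology = list(hf_amp_jitter = 0, attenuation_length = 2,
                      hf_event_amplitude = 7,
                      hf_rate = rate, hf_rate_type = rate_type,
                      p1_latency_trial_sd = 0, n1_latency_trial_sd = 0,
                      ## symmetric trough flanks: the argmin of the flat
                      ## trough then wanders symmetrically and its median
                      ## stays unbiased
                      n1_recovery = 6))
}

## Construct a raw_trace holding given per-channel samples (all channels
## equal when a single vector is given).
make_trace <- function(x, fs = 40000, t0 = NULL, pre_ms = 20) {
  if (is.null(t0)) t0 <- round(pre_ms * fs / 1000) + 1L
  if (is.vector(x)) x <- matrix(rep(x, each = 7), nrow = 7, byrow = FALSE)
  raw_trace(x, fs, t0)
}

## Feature table with all 35 columns drawn i.i.d. normal, optionally
## overriding selected columns per nerve; used to build statistical
## oracles without the trace pipeline.
synthetic_sf_table <- function(n_per_nerve = 50, animals = "A1",
                               mean = 10, sd = 1, overrides = list()) {
  rows <- expand.grid(trial = seq_len(n_per_nerve),
                      nerve = nerve_labels(), animal = animals,
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  feats <- matrix(stats::rnorm(n * 35, mean, sd), n, 35,
                  dimnames = list(NULL, input_columns()))
  tab <- data.frame(animal = rows$animal,
                    nerve = factor(rows$nerve, levels = nerve_labels()),
                    trial = rows$trial)
  tab <- cbind(tab, as.data.frame(feats))
  for (col in names(overrides)) {
    spec <- overrides[[col]]  # named list: nerve -> c(mean, sd)
    for (nv in names(spec)) {
      i <- tab$nerve == nv
      tab[[col]][i] <- stats::rnorm(sum(i), spec[[nv]][1], spec[[nv]][2])
    }
  }
  tab
}
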