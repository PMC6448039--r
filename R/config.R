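#' Synthetic-recording generator configuration
#'
#' Collects the design and noise parameters of the synthetic evoked-potential
#' generator. The defaults reproduce the full in-vivo study design: 7 animals,
#' 20 stimulus sets of 11 trials per nerve (880 trials per animal, 6160 in
#' total), 40 kHz sampling, and a 100 ms trace window around the stimulus.
#'
#' Two dimensionless dials control the generative structure:
#' `effect_scale` scales every nerve-dependent parameter offset (0 makes all
#' four nerves statistically identical, a pure null); `asymmetry_scale`
#' scales every left/right difference (hotspot displacement toward the
#' midline, right-side magnitude gain, right-side latency shortening); at 0
#' the left and right members of each bilateral nerve pair are exact mirror
#' images.
#'
#' @param n_animals Number of animals in the cohort.
#' @param n_sets Stimulus sets per nerve.
#' @param trials_per_set Trials per stimulus set.
#' @param sample_rate Sampling rate in Hz (must exceed twice the 3300 Hz
#'   upper band edge).
#' @param trace_window `c(pre, post)` window in ms relative to the stimulus;
#'   must cover -15 to 55 ms.
#' @param noise_sd Additive white noise SD in uV.
#' @param artifact_amplitude Stimulus-artifact amplitude in uV.
#' @param effect_scale Nerve-effect dial in \[0, 1\].
#' @param asymmetry_scale Left/right asymmetry dial in \[0, 1\].
#' @param animal_variability_sd Fractional between-animal variability of
#'   amplitudes, rates and latencies.
#' @param electrode_shift_sd SD (um) of the per-animal lateral and
#'   rostro-caudal displacement of the electrode array from the midline.
#' @param rng_seed Integer seed controlling the whole cohort.
#' @param physiology Named list of cohort-mean physiological parameters; see
#'   [default_physiology()]. Entries given here override the defaults.
#' @return An object of class `dcnfl_config`.
#' @export
generator_config <- function(n_animals = 7,
                             n_sets = 20,
                             trials_per_set = 11,
                             sample_rate = 40000,
                             trace_window = c(-20, 80),
                             noise_sd = 3,
                             artifact_amplitude = 400,
                             effect_scale = 1,
                             asymmetry_scale = 1,
                             animal_variability_sd = 0.1,
                             electrode_shift_sd = 150,
                             rng_seed = 1,
                             physiology = list()) {
  cfg <- list(
    n_animals = as.integer(n_animals),
    n_sets = as.integer(n_sets),
    trials_per_set = as.integer(trials_per_set),
    sample_rate = sample_rate,
    trace_window = trace_window,
    noise_sd = noise_sd,
    artifact_amplitude = artifact_amplitude,
    effect_scale = effect_scale,
    asymmetry_scale = asymmetry_scale,
    animal_variability_sd = animal_variability_sd,
    electrode_shift_sd = electrode_shift_sd,
    rng_seed = as.integer(rng_seed),
    physiology = utils::modifyList(default_physiology(), physiology)
  )
  class(cfg) <- "dcnfl_config"
  validate_config(cfg)
  cfg
}

#' Cohort-mean physiological parameters of the generator
#'
#' Slow-wave (P1/N1), multiunit-burst and spatial parameters around which
#' per-animal models are drawn. Latencies are in ms, amplitudes in uV, the
#' burst rate in events/ms over the 15-55 ms window, and map coordinates in
#' mm. Nerve-type offsets give peroneal nerves a shorter N1 latency, a
#' larger (more negative) N1 and a higher burst rate than sural nerves;
#' side terms give right-side nerves a magnitude gain, slightly shorter
#' latencies, and a response hotspot displaced toward the midline, which
#' together emulate the right-side dominance seen at midline electrodes.
#'
#' @return A named list of parameters.
#' @export
default_physiology <- function() {
  list(
    p1_latency = 10,            # ms, cohort mean (onset rises 4 ms earlier)
    n1_latency = 18,            # ms, cohort mean
    p1_amplitude = 60,          # uV, positive lobe peak
    n1_amplitude = -110,        # uV, negative lobe peak
    p1_rise = 4,                # ms from onset to P1 peak
    n1_recovery = 12,           # ms from N1 peak back to baseline
    p1_latency_trial_sd = 0.4,  # ms trial-to-trial P1 jitter
    n1_latency_trial_sd = 1.0,  # ms trial-to-trial N1 jitter
    n1_latency_type = 2,        # ms: sural +, peroneal -
    n1_amplitude_type = 30,     # uV: sural +30 (shallower), peroneal -30
    hf_rate = 0.30,             # events/ms, cohort mean
    hf_rate_type = 0.10,        # peroneal +, sural -
    hf_event_amplitude = 8,     # uV, mean event peak
    hf_amp_jitter = 0.3,        # event peak ~ Unif(1 -/+ jitter) x mean
    hf_refractory = 0.8,        # ms minimum event separation
    hf_kernel_sigma = 0.25,     # ms envelope SD of the event wavelet
    hf_kernel_f0 = 1600,        # Hz centre frequency of the event wavelet
    right_gain = 0.15,          # fractional right-side magnitude gain
    n1_latency_side = 0.1,      # ms shorter N1 latency on the right
    hotspot_lateral = 0.55,     # mm |x| of per-nerve hotspots
    hotspot_rc = 0.35,          # mm y: peroneal +, sural -
    hotspot_asym = 0.30,        # mm medial shift of right-side hotspots
    attenuation_length = 0.9    # mm spatial decay constant
  )
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "dcnfl_config"))
  if (cfg$n_animals < 1) stop("n_animals must be >= 1")
  if (cfg$n_sets < 1 || cfg$trials_per_set < 1)
    stop("n_sets and trials_per_set must be >= 1")
  if (cfg$sample_rate <= 2 * 3300)
    stop("sample_rate must exceed twice the 3300 Hz band edge")
  if (length(cfg$trace_window) != 2 ||
      cfg$trace_window[1] > -15 || cfg$trace_window[2] < 55)
    stop("trace_window must cover [-15, 55] ms")
  for (nm in c("effect_scale", "asymmetry_scale")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(nm, " must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0 || cfg$animal_variability_sd < 0 ||
      cfg$electrode_shift_sd < 0)
    stop("noise and variability parameters must be non-negative")
  invisible(cfg)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' The file holds named [generator_config()] arguments; omitted fields keep
#' their defaults.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `dcnfl_config` object.
#' @export
read_generator_config <- function(path) {
  values <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(generator_config))
  bad <- setdiff(names(values), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(generator_config, values)
}

#' @export
print.dcnfl_config <- function(x, ...) {
  cat("Synthetic DCN recording configuration\n")
  cat(sprintf("  cohort: %d animals x %d nerves x %d sets x %d trials (%d total)\n",
              x$n_animals, 4L, x$n_sets, x$trials_per_set,
              x$n_animals * 4L * x$n_sets * x$trials_per_set))
  cat(sprintf("  sampling: %g kHz, window [%g, %g] ms\n",
              x$sample_rate / 1000, x$trace_window[1], x$trace_window[2]))
  cat(sprintf("  noise %g uV; effect %.2f; asymmetry %.2f; animal var %.2f; shift sd %g um\n",
              x$noise_sd, x$effect_scale, x$asymmetry_scale,
              x$animal_variability_sd, x$electrode_shift_sd))
  invisible(x)
}

#' Expected trial counts implied by a configuration
#'
#' Pure design arithmetic: no data are generated.
#'
#' @param config A [generator_config()].
#' @return A list with `trials_per_nerve`, `trials_per_animal`,
#'   `total_trials`, and `n_inputs` (5 signal features x 7 electrodes).
#' @export
dataset_design <- function(config = generator_config()) {
  per_nerve <- config$n_sets * config$trials_per_set
  list(
    trials_per_nerve = per_nerve,
    trials_per_animal = 4L * per_nerve,
    total_trials = config$n_animals * 4L * per_nerve,
    n_inputs = length(SF_NAMES) * 7L
  )
}
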