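# dcnfl — feature-learnability of nerve-evoked brainstem surface potentials

The dorsal column nuclei (DCN) are the first brainstem relay for ascending
tactile and proprioceptive signals. When a hindlimb nerve — the left or
right sural or peroneal (LSN, RSN, LPN, RPN) — is electrically stimulated,
a seven-electrode surface array over the DCN records a stereotyped evoked
potential: a slow biphasic wave (positive peak P1, negative peak N1) and a
burst of 550–3300 Hz multiunit activity 15–55 ms after the stimulus.

`dcnfl` is an R package for researchers in neural decoding and
somatosensory neuroprosthetics who want to quantify **where and in which
signal features the identity of the stimulated nerve is encoded**. Its core
quantity is *feature-learnability*: for a chosen set of inputs (signal
features × electrodes), a fixed feed-forward network (20 tanh hidden units,
4-way softmax, cross-entropy, gradient descent with momentum and adaptive
learning rate, early stopping) is trained repeatedly to classify the
stimulated nerve, and learnability is the mean ± SEM of the diagonal of the
repeat-averaged confusion matrix

```
FL = mean(diag(C)),   SEM across the four class accuracies,
```

a measure of the information content of the inputs rather than of
classifier tuning. Because no public recordings exist for this
preparation, the package includes a first-class synthetic-recording
generator with known ground truth (nerve-specific P1/N1 waveforms, Poisson
multiunit bursts, asymmetric spatial hotspots, inter-animal variability,
array misalignment, stimulus artifact, noise), so every stage is testable
end to end.

What the package does:

* **Simulate** cohorts of 7-channel, 40 kHz evoked recordings
  (`generator_config()`, `make_cohort()`, `generate_dataset()`,
  `simulate_feature_table()`), with dials for nerve effect size
  (`effect_scale`) and left/right asymmetry (`asymmetry_scale`) down to
  exact nulls.
* **Extract** the five signal features per electrode — N1 latency, P1N1
  slope, P1N1 amplitude, HF peak count, HF integral — with zero-phase
  band-passing and artifact replacement (`preprocess()`,
  `extract_features()`, `compute_spectrogram()`).
* **Quantify learnability** under three partitioning schemes — within
  individual animal (WIA, the benchmark), pooled population (PP), and
  leave-one-animal-out (LOO) — with ranking and near-benchmark testing
  (`run_learnability()`, `rank_results()`, `near_benchmark()`).
* **Minimize inputs** with an adapted sequential forward search in which
  rejected candidates are re-tested in later rounds, plus exhaustive
  enumeration of small subset spaces (`single_feature_grid()`,
  `adapted_sfs()`, `exhaustive_subsets()`).
* **Map** learnability over the 2 mm × 2 mm DCN surface with exact
  thin-plate-spline interpolation and shift-aligned cohort stacking
  (`tps_surface()`, `align_and_stack()`).
* **Validate statistically**: non-significant loci (nerve pairs a feature
  cannot separate) and their regression on learnability error, side
  dominance of bilateral nerve pairs at the central electrode and in the
  total response magnitude, and the dominance–error association
  (`nonsignificant_loci()`, `side_dominance()`,
  `dominance_error_association()`, `dominance_fl_correlation()`).

## Worked example

Simulate a small three-animal cohort, score the all-35-input benchmark,
and ask whether the central electrode alone is statistically as good:

```r
library(dcnfl)

cfg <- generator_config(n_animals = 3, n_sets = 5, trials_per_set = 11,
                        rng_seed = 1)
tab <- simulate_feature_table(cfg)          # 660 trials x 35 features

benchmark <- run_learnability(tab, scheme = "WIA", n_repeats = 10, seed = 1)
benchmark
#> Feature-learnability (WIA): 100.0 +/- 0.0 % (n = 660 trials, 10 repeats)
#>      predicted
#> true  RSN LSN RPN LPN
#>   RSN 100   0   0   0
#>   LSN   0 100   0   0
#>   RPN   0   0 100   0
#>   LPN   0   0   0 100

e4 <- run_learnability(tab, list(electrodes = 4, sfs = sf_names()),
                       scheme = "WIA", n_repeats = 10, seed = 1)
sprintf("e4 alone: %.1f +/- %.1f %%", e4$fl_mean, e4$fl_sem)
#> "e4 alone: 98.9 +/- 0.7 %"

nb <- near_benchmark(e4, benchmark)
sprintf("near-benchmark? %s (p = %.3f)", nb$is_near, nb$p)
#> "near-benchmark? TRUE (p = 0.285)"

head(feature_pair_correlations(tab), 3)
#>         feature_a      feature_b          r p
#> 10  hf_peak_count    hf_integral  0.8719905 0
#> 5      p1n1_slope p1n1_amplitude  0.8425447 0
#> 9  p1n1_amplitude    hf_integral -0.7928855 0
```

Every correct classification lands on the diagonal, so the benchmark
reaches 100% on this cleanly separable synthetic cohort; the central
midline electrode alone classifies at 98.9% and a paired per-animal test
cannot distinguish it from the benchmark. The two high-frequency burst
features top the pairwise correlations (r = 0.87) because both measure the
same underlying burst — redundancy the input-minimization stage exploits.

The methods vignette (`vignettes/feature-learnability.Rmd`) documents the
generative model, the parameter choices and their rationale, the
ground-truth expectations and their regime of validity, and the numerical
rules for degenerate inputs.

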