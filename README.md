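# wmpopdyn

Population-dynamics analysis of working-memory activity in prefrontal
cortex, for delayed-response tasks in which a second, behaviourally relevant
cue (the promised reward) interrupts the memory delay.

The package is aimed at systems neuroscientists analysing pooled
single-neuron recordings from tasks of this family: a 1000 ms fixation, two
500 ms cues (one spatial, one reward-predictive, order counterbalanced
across SR/RS trial types), each followed by a 1000 ms delay, then a go cue
and saccade. It implements, end to end:

- **Intrinsic timescales.** Each neuron's resting time-constant is the decay
  constant of its fixation-period spike-count autocorrelation, fitted as
  `R(kΔ) = A [exp(−kΔ/τ) + B]` over lags kΔ = 50…950 ms (20 bins of 50 ms),
  starting from the largest consecutive drop of the autocorrelogram, with
  the published exclusion rules (rate < 1 Hz, no early decline, extreme
  parameters). Populations can be split at the median τ.
- **Accuracy decoding.** Pseudopopulation linear-discriminant decoding of
  spatial location (8 collapsed targets, chance 12.5%), reward level
  (5 levels, chance 20%) or trial type: stratified split halves, 1500
  training / 100 test pseudotrials resampled per neuron within condition,
  per-timepoint PCA denoising at 90% variance, pooled-covariance LDA,
  repeated over permutations; cross-temporal (train at t, test at t′) and
  error-trial variants, epoch bootstrap comparisons, and the post-reward
  decline (slope) test.
- **Correlation decoding (PWD).** Pairwise condition differences of
  trial-averaged firing, correlated across neurons between independent data
  halves and Fisher-averaged — negative values expose tuning *reversals*
  that accuracy decoders cannot show. Cluster-based permutation tests
  (vs chance, and high-τ vs low-τ groups) correct for multiple comparisons
  over the time × time plane.
- **Population geometry.** Within-condition across-time correlation (raw
  and demeaned), mnemonic subspaces from condition-averaged epoch activity
  (PCA over conditions, k = conditions − 1), held-out trajectory
  projections, and the stimulus variance captured over time,
  `SV = Tr(S_kᵀ C_t S_k)`.
- **Single neurons.** Sliding Kruskal–Wallis selectivity with 1-D cluster
  permutation correction, ten-epoch selectivity and switching profiles, and
  two-way ANOVA classification into space / reward / linear-mixed /
  non-linear-mixed classes.
- **Synthetic sessions.** An Ornstein–Uhlenbeck-modulated inhomogeneous
  Poisson generator reproduces the task structure with known ground truth
  (per-neuron τ, tuning epochs, cue→delay reversal, space→reward
  switching), so every analysis is testable without access to recordings.

## Worked example

```r
library(wmpopdyn)

# a synthetic session: 30 neurons, mixed dynamics, known ground truth
gen <- generate_session(synth_config(n_neurons = 30, trials_per_cond = 2,
                                     seed = 1))
s <- gen$session
s
#> <wm_session> 30 neurons, 480 trials, 698930 spikes
#>   regions: VLPFC:30
#>   source: synthetic

# intrinsic timescales and a median split
fits <- fit_timescales(s)
table(fits$status)
#> excluded_extreme_params                  fitted
#>                       4                      26
split <- median_split_by_tau(fits)

# decode the remembered location through the trial (reduced permutations)
dec <- decode_timecourse(s, "space8", task_type = "SR",
                         times = seq(250, 4750, 250), n_perm = 20,
                         n_train = 600, n_test = 96, seed = 2)
glance(dec)
#> # A tibble: 1 × 6
#>   feature task_type n_perm chance mean_accuracy frac_significant
#>   <chr>   <chr>      <dbl>  <dbl>         <dbl>            <dbl>
#> 1 space8  SR            20  0.125         0.237            0.579
autoplot(dec)
```

26 of the 30 neurons receive a timescale; 4 are excluded for extreme fitted
parameters, as the published exclusion rules intend. Decoding accuracy sits
at chance (12.5%) through fixation and rises once the spatial cue appears —
23.7% averaged over the *whole* trial in this mixed-dynamics session
(untuned, transient, reversing and switching neurons all present), with 58%
of timepoints individually significant by the 2.5th-percentile rule.
`crosstemporal_discriminability()` on a reversal population instead shows a
*negative* cue × delay block (the tuning pattern inverts), which
`cluster_test_vs_chance()` localises in time.

## Acceptance script

`scripts/acceptance.R` regenerates an untuned 50-neuron synthetic session
and runs the complete pseudopopulation decoding pipeline (pseudotrials,
90%-variance PCA, pooled-covariance LDA, 100 permutations) at a mid-delay
timepoint for the 8-class spatial and 5-class reward features, writing the
mean accuracies (in percent) to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
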