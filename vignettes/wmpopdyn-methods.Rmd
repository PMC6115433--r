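---
title: "Models and methods behind wmpopdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wmpopdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the estimators
and inference procedures it implements, the assumptions they make, the
synthetic world the generator states, and the numerical choices taken where
the underlying design was genuinely open. Nothing here reports an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The task and the data model

The task family is an oculomotor delayed response with an interposed reward
cue: 1000 ms central fixation, then two 500 ms cues each followed by a
1000 ms delay, then a go cue, saccade and reward. One cue marks one of 24
spatial targets (a 5 × 5 grid around fixation, centre excluded) that must be
held in working memory; the other promises one of 5 reward magnitudes. On
SR-trials the spatial cue comes first, on RS-trials the reward cue. All
analyses work from three tables — trials, neurons, spikes — bundled in a
`wm_session`; times are milliseconds from fixation onset and every counting
window is half-open `[lo, hi)`.

The 24 targets are collapsed to 8 groups of 3 ("triangles") for decoding and
to 4 groups of 6 for the error-trial analysis. The 24→8 membership table is
not published; we fix it as eight contiguous angular sectors around
fixation (three targets each), computed once from the grid geometry and
hard-coded. Every downstream analysis depends only on this being a *fixed
partition*, not on which partition — the rectangles are the fixed
tessellating pairs (1,2), (3,4), (5,6), (7,8) of those sectors.

Firing rates are spike counts in a sliding window divided by its width:
50 ms steps with a 100 ms window for accuracy decoding, 10 ms steps with a
200 ms window for the correlation-based analyses. Bins whose window leaves
a trial's recorded span are missing values and are excluded from
correlations and fits, never zero-filled. Decoding inputs are z-scored per
neuron against the across-trial mean and SD of the rate in the final 300 ms
of fixation; a neuron with zero baseline SD would otherwise be undefined,
so its SD is replaced by the population median SD and the neuron is
flagged — dropping it silently would change the pseudopopulation size
mid-pipeline.

## Intrinsic timescales

The resting time-constant of a neuron is estimated from its fixation-period
spike-count autocorrelation: the 1000 ms fixation is cut into twenty 50 ms
bins, counts are correlated across trials for every bin pair, and the mean
correlation per lag (50…950 ms) is fitted with

\[ R(k\Delta) = A\,[\exp(-k\Delta/\tau) + B] . \]

Fitting starts "from the largest reduction between two consecutive bins
onwards", a rule whose purpose is to skip the depressed first lag produced
by refractoriness. Two details are under-determined by that phrase and we
fixed them after parameter-recovery experiments (documented in the test
suite):

- the drop search is restricted to lags ≤ 250 ms — the same horizon the
  no-decline exclusion uses — because the late lags average only 2–7 bin
  pairs and their noise otherwise selects absurd start points;
- the fit starts *at* the first bin of the maximal-drop pair, not after it.
  A dip-free curve is then fitted in full, while a curve with a depressed
  first bin starts at the peak. Starting one bin later would always discard
  the most informative lag and demonstrably breaks recovery of short
  timescales.

The optimiser is bounded multi-start least squares (L-BFGS-B from a fixed
grid of 21 deterministic starts, τ log-spaced, SSE ties broken toward the
smaller τ). Bounds are deliberately wide (τ ∈ [5, 5000] ms) so that the
published exclusion rules — applied afterwards, in order: fixation rate
< 1 Hz; no decline of the autocorrelation in the first 250 ms; extreme
parameters A > 1.2, A < 0, τ > 1000, τ < 10 — can actually observe extreme
fits. The manual visual-inspection step of the original procedure is
replaced by an optional automated flag (R² < 0.2, off by default), since
the published results were replicated without it. Per-lag means (not raw
bin pairs) are the default fitting target; the population-level fit pools
each contributing neuron's per-lag means as equally weighted points and
applies the same start rule to the pooled mean curve.

Median splits assign neurons with τ ≤ median to the low-τ half, so the
median element of an odd-sized population goes low; only successfully
fitted neurons participate.

## Accuracy decoding

Pseudopopulations are built by resampling trials independently per neuron
within condition: one permutation = a fresh stratified split of correct
trials into halves, 1500 training and 100 test pseudotrials spread
uniformly over conditions (counts differ by at most one; the test total of
100 is interpreted as 100 overall, 12–13 per spatial class, since the
source text does not say per-condition). Draws are with replacement; trial
draws are made once per permutation and reused across timepoints. At each
timepoint, principal components are fitted on the training matrix only and
both sets are projected onto the fewest axes reaching 90% of training
variance — retained scores, not reconstructed data, because the stated
purpose of this step is to keep the discriminant's pooled covariance
non-singular. The classifier is the pooled-covariance Gaussian linear
discriminant; if the pooled covariance is still numerically singular a
ridge of 10⁻⁶ × mean diagonal is added and recorded. Chance is 12.5% for 8
locations and 20% for 5 rewards; a timepoint is significant when the 2.5th
percentile of the permutation distribution exceeds chance.

Comparisons between decoders (high-τ vs low-τ populations, correct vs error
test sets) average accuracy within ten fixed 500 ms epochs per permutation
and use the published bootstrap: identify the higher-mean population, count
how often the lower exceeds the higher across random re-pairings, Bonferroni
× 10. Cross-temporal surfaces train at every t and test at every t′; the
reward-cue disruption analyses use T1 (final 500 ms of delay-one),
post-reward (250–750 ms after reward-cue onset) and T2 (final 500 ms of
delay-two), comparing block means per permutation (significant when the
2.5–97.5 percentile range of differences excludes 0) and fitting a line per
permutation to the T1-trained accuracy timecourse within each window (the
decline/slope test, same percentile rule on gradients).

## Correlation-based discriminability (PWD)

Accuracy decoders cannot represent a tuning *reversal* — anti-correlated
codes merely fall below chance weakly. The PWD decoder computes, per neuron
and timepoint, the condition means in each data half, takes all pairwise
condition differences (28 for 8 conditions, 10 for 5, 1 for 2, canonical
orientation lower-minus-higher index), correlates each difference vector
across neurons between halves, and Fisher-averages the coefficients.
Reversal appears as negative discriminability. Surfaces can be symmetrised
across the diagonal (Fisher-z average of r(t,t′) and r(t′,t)), and the
cross-task configuration trains on SR-trials and tests on RS-trials.

Inference is by cluster-based permutation. Against chance: per-pixel p from
the correlation null (t distribution, df = neurons − 2, two-tailed,
forming threshold 0.01); candidate clusters are 4-connected pixels of the
same sign inside non-overlapping 500 × 500 ms windows anchored at fixation
onset; the null of the maximum cluster size shuffles neuron order
independently within each test-set PWD. Between groups: the per-pixel
statistic is the two-correlation Fisher z,
\( z = (\mathrm{atanh}\,r_A - \mathrm{atanh}\,r_B)\,/\,
\sqrt{1/(n_A-3) + 1/(n_B-3)} \), formed one-tailed at 0.05, with the null
permuting the neuron-to-group assignment. Cluster mass is pixel count, and
p-values use the (1 + exceedances)/(1 + n_perm) convention so a cluster
larger than every null is reported as p ≤ 1/(n_perm + 1), never 0. Pixel
connectivity (4 vs 8) and the exact between-group statistic are not
published; the defaults above are recorded in the result objects, as are
reduced permutation counts.

## Population geometry

The within-condition across-time correlation correlates, per condition, the
across-neuron vector of condition means at t (training half) with the one
at t′ (test half), Fisher-averaged over the 13 conditions (8 spatial + 5
reward). Raw, it is dominated by each neuron's overall firing level —
positive everywhere; after removing the per-neuron across-condition mean at
every timepoint it isolates tuning, and a reversal population flips the
cue × delay block negative. This raw/demeaned dissociation is a core
property test of the package.

Mnemonic subspaces are principal axes over conditions of the demeaned
conditions × neurons matrix of training-half means, time-averaged over a
named epoch (fixation: the 1000 ms before cue onset; delay-one: 500–1500 ms
after cue onset) or computed per timepoint (dynamic). k defaults to
conditions − 1 (space 7, reward 4). Held-out condition means are demeaned
at each timepoint and projected; the stimulus variance a subspace captures
at t is SV = Tr(S_kᵀ C_t S_k) with C_t the across-condition covariance
(1/(c−1) scaling) of the demeaned test means. SV is reported both raw and
normalised by Tr(C_t): the normalised variant (an addition — the source
formula is unnormalised) makes timepoints comparable and gives the
full-span identity sv = 1 when k = c − 1 axes are evaluated on their own
training means. Split halves are enforced everywhere; projecting data onto
a subspace estimated from the same trials is allowed only in degenerate
consistency tests.

## Single-neuron statistics

Sliding selectivity uses a rank-based Kruskal–Wallis statistic per bin
(10 ms steps, 200 ms windows, matching the discriminability grid; the
source states only "at each timepoint"). The statistic is computed
in-package from ranks with the chi-square approximation and tie correction
— ranks are invariant under label shuffles, which makes the 1-D cluster
permutation null (shuffle the feature across trials, find the longest
sub-threshold run within each 500 ms window) hundreds of times cheaper.
`stats::kruskal.test` is the oracle the tests compare against, to machine
precision. Constant bins return statistic 0 and p = 1.

Ten-epoch profiles run the same test on epoch-mean rates across ten
consecutive 500 ms epochs, define the subset selective for the
first-presented cue's feature during the cue-one epoch, and track the
fraction of that subset that is space-only, reward-only, both or neither in
every epoch. Mixed selectivity at the second cue is classified by a two-way
fixed-effects ANOVA (type-II sums of squares, so the error-inclusive
unbalanced case is handled; balanced synthetic designs make the choice
moot): space/reward (one main effect), linear mixed (two main effects),
non-linear mixed (two main effects + interaction), non-selective, and
unclassified for combinations outside the table. F-statistics are
log-transformed only for plotting, never for statistics, and the
spatial-vs-reward F rank correlation is computed across neurons per bin
plus once over the whole cue-two epoch.

## The synthetic world

No recordings are distributed with the source study, so the generator is a
first-class module with stated parameters, not a tuning dial:

- **Rates.** Each neuron is an inhomogeneous Poisson process (sampled by
  thinning) whose rate is `baseline × (1 + gain × OU(t))` plus additive
  tuning terms, floored at 0. The Ornstein–Uhlenbeck latent (exact AR(1)
  discretisation, unit variance) gives the spike counts an exponential
  autocorrelation with the neuron's programmed τ — exactly the model the
  timescale estimator assumes. Baselines are log-normal (median 8 Hz), τ is
  log-normal (median 150 ms, σ_log 0.8, truncated to [20, 1000] ms),
  matching the published heterogeneity qualitatively.
- **Modulation depth.** `latent_gain = 0.8` (and 15 Hz baseline in the
  timescale-calibration path) was chosen once, from a 2 × 2 scan, so that
  the fixation-period spike-count autocorrelation amplitude is ~0.1–0.2 —
  the magnitude published PFC data show — and so that the documented
  recovery property (median fitted τ within 25% of each generative τ in
  {50, 100, 200, 500} ms, strictly increasing) holds. The rate floor
  truncates ~10% of the latent's mass; the resulting small bias is accepted
  and covered by the recovery tests.
- **Tuning.** Spatial tuning is cosine over the 8 sectors, reward tuning
  triangular over the 5 levels, both peaking at +depth (8 Hz default) for
  the preferred condition. `sustained` terms run from cue onset to the go
  cue, `transient` during the cue only. A `reversal` neuron expresses
  −depth from cue offset to go and, during the cue, one third of +depth
  plus a full-depth transient component with an independent preference.
  An exact sign flip would be wrong twice over: sign-flipped patterns span
  the same subspace (SV is quadratic), so the delay subspace would
  "explain" the cue period, contradicting the phenomenon being modelled.
  The 1/3 weight puts ~10% of cue-period stimulus variance in the delay
  subspace while keeping the population-level cue↔delay correlation clearly
  negative.
- **Switching.** A `switch` neuron's first-feature term ramps linearly to
  zero over 750 ms from second-cue onset (a step would complete before the
  post-reward analysis window opens and no decline could be measured), and
  the second feature's term activates with its cue.
- **Errors.** Error trials carry a corrupted remembered location (a
  neighbouring sector drives the spatial term) — the minimal mechanism that
  makes correct-trial decoding beat error-trial decoding.
- **Seeds.** One master seed; per-neuron substreams are derived as
  (seed + neuron_id × 1000003) mod 2³¹−1, so adding neurons never perturbs
  existing ones. All library randomness runs in a scoped stream that
  restores the caller's RNG state.

What a green test does *not* establish: the generator has no spike-history
refractoriness (the short-lag autocorrelation dip is absent by default), no
biophysics, no eye movements, no cross-neuron noise correlations beyond the
shared task structure, and its error model is purely spatial. Results on
real data can differ in all of these respects.

## Numerical choices and limitations

- Fisher averaging clamps |r| away from 1 by a relative 10⁻¹² before
  atanh; pairs with zero variance are dropped from the average and pixels
  with no valid pairs become missing.
- The LDA ridge (10⁻⁶ × mean diagonal) triggers only on numerically
  singular pooled covariances and is flagged in the result.
- Cluster-forming masks split by statistic sign before connected
  components; a mixed-sign "cluster" is meaningless for reversal analyses.
- Permutation counts are reduced at desk scale (and recorded in every
  result object); the published analyses used 1000–10000.
- The between-groups cluster test takes the first *sorted* group level as
  the reference group A; swapping labels negates the statistic exactly.
- Event schedules allow coincident epoch boundaries (delay-one ends exactly
  when cue two begins), so trial validation enforces non-decreasing order
  with strict increase across non-degenerate intervals.
- Timescale estimation from a 1 s window is intrinsically hard for τ well
  above ~500 ms; fits hitting τ > 1000 ms are excluded as published, which
  censors the upper tail of the estimator distribution. Recovery is
  therefore assessed on raw fitted values in the tests.
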