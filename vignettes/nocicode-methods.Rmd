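---
title: "Methods: population coding of acute pain intensity and its disruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population coding of acute pain intensity and its disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nocicode)
```

# The scientific problem

Anterior cingulate cortex (ACC) neurons respond to noxious stimulation of the
hind paw with transient increases in firing rate, and a subset of them fires
more strongly for a high-intensity noxious stimulus (HS, 250 mW laser) than
for a low-intensity one (LS, 150 mW), providing a single-neuron code for pain
intensity. `nocicode` implements the analysis chain used to quantify that
code and its degradation in a chronic inflammatory pain state (CFA injection
in the opposite paw): trial-aligned z-scored PSTHs, a two-part threshold rule
for pain-responsive units, cumulative-window population decoding with an SVM
and permutation chance levels, robust-regression tuning curves, and the
behavioral assays (conditioned place aversion, Dixon up-down von Frey,
withdrawal latency/velocity) that anchor the neural findings.

Recordings of this kind are not publicly deposited, so the package ships a
synthetic generator that produces sessions and behavioral cohorts with the
statistical structure the analysis assumes. All quantitative checks in the
test suite are parameter-recovery and calibration exercises on that
generator, anchored to the magnitudes the method is expected to reproduce.

# PSTH and z-scoring

Trials are aligned to laser onset. Spikes are counted in half-open 200 ms
bins over [−5, +5) s, giving 25 baseline and 25 post-stimulus bins; a spike
at exactly t = 0 belongs to the first post-stimulus bin. The trial-averaged
rate per bin, FR, is z-scored against the baseline:

$$Z = \frac{FR - \overline{FR_b}}{\mathrm{sd}(FR_b)}$$

**Baseline SD choice.** The baseline mean and SD are computed across the 25
baseline bins of the trial-averaged rate, not across trials. This reading
makes the baseline bins of Z standardize exactly (sample mean 0, sample
SD 1), which is what a per-bin z-scored PSTH display presumes; the
across-trials alternative is available via
`zscorePSTH(ct, baselineSdOver = "trials")`. A unit whose baseline shows no
variability at all cannot be z-scored; it is flagged *degenerate* and
excluded downstream with a warning rather than silently producing infinities.

Trials with paw withdrawal before 5 s still contribute the full post-stimulus
window: the laser turns off at withdrawal, but the recording does not, and
the analysis window is fixed at 5 s.

# Responsive-unit classification

A unit is *pain responsive* iff both hold on the post-stimulus bins:

1. at least two bins with $|Z| \ge 2.33$ (two-sided, \(p < 0.01\) each);
2. evaluated only when (1) passes: at least two bins whose lower bound
   $Z - Z_{SEM} > 1.645$ (one-sided, \(p < 0.05\)).

$Z_{SEM}$ is the standard error, across trials, of the per-trial bin rate,
divided by the baseline SD. The published definition carries an ambiguous
"(baseline / bin size)" qualifier; we implement the dimensionally consistent
form $Z_{SEM} = FR_{SEM}/\mathrm{sd}(FR_b)$ and isolate it in
`computeZSEM()` so the alternative is a one-line change. Criterion 1 uses
the absolute value (strong suppression passes it), while criterion 2 is
one-sided positive — both exactly as stated. The conjunction is deliberately
strict: on pure-noise sessions the test suite measures a false-positive rate
well under 5% across 1000 simulated units.

**Intensity-coding units.** Among responsive units recorded under both LS and
HS, the per-trial response summary is the peak z-scored bin rate in the
post-stimulus window, and HS vs LS is tested with a paired one-sided
Student's t test. LS and HS trials have no natural pairing across separate
stimulation blocks, so trials are paired by rank order of the summary within
each class (unequal counts are truncated to the common n, with a note). The
paired quantity and the pairing rule are the genuinely open design points
here; both are arguments of `identifyIntensityCoding()`.

# Population decoding

Spikes are re-binned at 100 ms from onset to 5 s (50 evaluation bins). At
bin *b* the feature vector of a trial concatenates the per-unit counts of
bins 1..b, so the dimensionality grows from C (the number of simultaneously
recorded units) to 50C. This emulates online decoding in which evidence
accumulates through the trial.

The classifier is a soft-margin SVM (libsvm via `e1071`) with a polynomial
kernel. The kernel degree is not specified by the source analysis; we default
to degree 3 with unit additive coefficient — the common polynomial-kernel
default — and expose both the degree and a linear-kernel fallback in the
configuration. Accuracy is assessed by stratified 5-fold cross-validation
(each fold is a 20% test split, which reconciles the "80/20 split" and
"5-fold CV" descriptions), repeated `mcRepeats` times with freshly shuffled
fold assignments; the per-bin mean ± SEM over repeats is reported, and the
single per-session figure is the maximum of the cumulative accuracy curve.
Feature standardization (per-dimension centering/scaling) is fit on the
training folds only, never on test trials. Class imbalance is left
unweighted, consistent with chance levels slightly above 50% on imbalanced
sessions. Constant feature columns (e.g. all-zero early bins) are dropped
before kernel evaluation; a fold with no informative column falls back to
the majority training label.

**Chance levels.** Trial labels are randomly permuted and the full CV
procedure re-run; the mean accuracy over permutations is the empirical
chance curve. With balanced classes it sits near 50%. The reference analysis
uses 500 permutations; the packaged checks use 100, which puts the Monte
Carlo SEM of the chance mean well below half a percentage point — ample for
a quantity compared at the ±2-point level.

Only sessions with at least five simultaneously recorded units enter
population summaries (`aggregateSessions(minUnits = 5)`).

# Tuning curves

For every neuron with a larger HS than LS peak z-scored response, the pair
(LS peak, HS peak) enters a robust linear regression (IRLS with bisquare
weights, tuning constant 4.685 — the default robust fit in common scientific
environments). The slope is the intensity tuning measure: steep (>1) when
HS recruits clearly more firing than LS, flatter when intensity
discrimination is degraded. Choices a reader should know:

* the intercept is fitted, not forced through the origin;
* R² of a robust fit is ambiguous; we report the squared correlation between
  fitted and observed HS peaks and document it as such;
* an exactly collinear input (zero residuals) degenerates the robust scale
  estimate, so that case returns the OLS solution the IRLS converges to.

Two slopes are compared with
$t = (b_1 - b_2)/\sqrt{SE_1^2 + SE_2^2}$, $df = n_1 + n_2 - 4$, two-sided.
The two populations are treated as independent, as that test assumes.

# Behavior

**CPA.** Each phase (baseline, conditioning, test) lasts 600 s in a
two-chamber apparatus. Animals spending <100 s or >500 s in either main
chamber at baseline are excluded (the generator's default baseline bias SD
of 156 s makes that roughly one animal in five). The CPA score is baseline
minus test time in the more-noxious-paired chamber; with occupancy conserved
the two chambers' scores are exactly antisymmetric.

**Dixon up-down von Frey.** Filaments (0.45–15.10 g, log-spaced) are applied
starting at 2.55 g, stepping down after a withdrawal and up after none,
until the first direction change plus four further stimuli. The published
protocol cites the classical up-down tables for the 50% threshold
$10^{X_f + \kappa\delta}$. Rather than shipping a transcribed table, we
compute the estimate those tables encode: the maximum-likelihood 50% point
of a normal psychometric function on the log10 force axis with SD fixed at
the mean log step δ. The likelihood is log-concave, so a bounded
one-dimensional optimization finds the unique optimum; the test suite
cross-checks it against an exhaustive grid search and verifies monotonicity
(turning any non-response into a response never raises the estimate) and
boundary clamping for monotone runs. κ is returned as an attribute for
comparison with tabulated values.

**Withdrawal.** Latency summaries are per-class means ± SEM over withdrawal
trials plus the withdrawal fraction (NS should withdraw on <5% of trials);
velocity is paw height divided by time-to-height.

# The synthetic generator

`simulateSession()` draws inhomogeneous-Poisson spike trains: a stationary
per-unit baseline rate (log-normal across units, median ≈ 2.5 Hz) over the
whole window plus, for responsive units from onset, an evoked component
$gain_t \cdot g_u \cdot A_s \cdot k(t)$ sampled by thinning. Key choices:

* **Evoked kernel** $k(t) = (1 - e^{-t/0.5})e^{-t/1.5}$, peak-normalized:
  a ~0.5 s rise and 1–2 s decay place the evoked transient well inside the
  5 s analysis window. No evoked waveform is published; the shape is a
  plausibility choice, config-exposed.
* **Per-trial gain** (log-normal, mean 1, SD 0.2) models shared
  trial-to-trial excitability.
* **Per-unit response gain** $g_u$ (log-normal, SD 0.6) models the large
  between-neuron spread of response magnitudes. It multiplies a neuron's LS
  and HS amplitudes jointly, which is precisely what makes the per-neuron
  (LS peak, HS peak) relation a correlated, fittable tuning curve rather
  than a cloud.
* **Regimes.** `pre_cfa` uses amplitudes NS/LS/HS = 0/5/9 Hz (well-separated
  intensities); `post_cfa` compresses LS toward HS (0/7.5/9 Hz), the
  saturation reading of a flattened tuning curve. The generated LS–HS
  amplitude ratios (1.8 and 1.2) bracket the tuning-slope regime the
  analysis is meant to distinguish.
* **Withdrawal latencies**: shifted gamma per class with HS faster than LS
  and NS withdrawing on ~3% of trials; exact latency distributions are not
  published as usable parameters.
* **Trial structure**: ~35 trials per single-class session, 28–30 per class
  in mixed two-class sessions, nominal 60 s inter-trial interval recorded as
  metadata.

For tuning-recovery studies, `simulateTuningCohort()` bypasses the spike
level: LS peaks are log-normal and HS = slope·LS + Gaussian noise, with the
noise SD calibrated analytically to a target population R² via
$\sigma_\epsilon = s\,\mathrm{SD}(LS)\sqrt{(1-R^2)/R^2}$.

**What the generator does not emulate.** No bursting, refractoriness, or
spike-sorting artifacts; no correlated noise between units beyond the shared
trial gain; no adaptation across trials; no anatomical structure. Passing
tests therefore show that the *analysis* behaves correctly on data with the
assumed statistical structure — not that real ACC recordings have that
structure.

# Problem sizes and numerical choices

The packaged checks use sizes chosen to estimate each quantity with adequate
Monte-Carlo precision: 200 cohorts per tuning-recovery target; 9 sessions ×
20 CV repeats for the decoding ceiling; 100 label permutations for chance
(SEM of the mean ≪ 1 point); 1000 simulated null units for the
false-positive rate; 20 seeded cohorts per regime for the pre/post decoding
direction. All randomized stages derive child seeds from one root seed
(`childSeed()`), so every stage is independently reproducible and the full
pipeline is bit-reproducible for a fixed seed.

Ties and degenerate inputs: half-open bins remove boundary ambiguity; bin
sizes must divide the window exactly; degenerate-baseline units are flagged
rather than dropped silently; singular tuning designs (constant LS peaks)
and single-class decoding inputs are errors, not NaNs.

# Limitations

* Real recordings are not available, so no quantity here is a reproduction
  of an in-vivo estimate; the checks are recovery/calibration results under
  the generator's assumptions.
* The SVM kernel degree and regularization of the original analysis are
  unknown; absolute decoding accuracies depend on them, though the
  qualitative contrasts (steep vs flattened regime, chance near 50%) do not.
* The rank-order trial pairing for the HS>LS test is a stand-in for an
  unstated pairing; its test size under the null is approximate.
* The up-down estimator is the ML form of the classical tables, not a
  transcription of them; κ values agree with the tabulated logic by
  construction of the model but were not checked digit-by-digit against the
  historical table.
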