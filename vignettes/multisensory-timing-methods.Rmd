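---
title: "Models and numerical conventions in multitact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical conventions in multitact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multitact)
```

`multitact` bundles four computational pipelines used when planning and
analysing browser-based multisensory reaction-time experiments with
smartphone vibration stimuli. This vignette is the package's account of the
models behind each pipeline, the parameters that matter, the numerical
conventions adopted where several were defensible, and what the synthetic
generators do and do not emulate.

## 1. The LATER power model

The power analysis treats each trial as a race to threshold with ergodic
rate: the decision rate is drawn per trial as $v \sim N(\mu_i, \sigma_i)$
truncated at zero, and the reaction time is $RT = 1/v$. Participant
heterogeneity enters through a two-level hierarchy,
$\mu_i \sim N(\mu_{base}, \sigma_\mu)$ and
$\sigma_i = |N(\sigma_{base}, \sigma_\sigma)|$, with defaults
$\mu_{base} = 2.5$, $\sigma_\mu = 0.3$, $\sigma_{base} = 0.4$,
$\sigma_\sigma = 0.1$ (all in 1/s; $\mu_{base} = 2.5$ corresponds to a
400 ms modal RT, typical of simple multisensory detection). An experimental
manipulation is modelled as a drift-rate decrement $\Delta\mu$, and
physical onset jitter as zero-mean Gaussian noise added to every simulated
RT in *both* conditions (jitter afflicts the apparatus, not the
manipulation). Noise is specified in ms and converted to seconds before
addition; RTs are not clipped afterwards, because for the parameter ranges
of interest the noise (≤ tens of ms) is far smaller than any simulated RT.

Numerical conventions:

* **Truncation at zero** is implemented by rejection sampling (redraw
  non-positive rates). This matches the definition exactly and leaves the
  positive tail undistorted; an inverse-CDF sampler would too, but rejection
  is cheaper here because the truncated mass is astronomically small at the
  default rates.
* **A strictly-positive-rate precondition.** If $\mu_i - \Delta\mu \le 0$
  for any participant the effect is degenerate (the experimental rate
  distribution would be mostly truncated) and the simulation errors rather
  than silently producing absurd RTs.
* **The paired test** is a two-sided Wilcoxon signed-rank on the paired
  *participant mean* RTs. The in-package implementation drops zero
  differences, uses the exact null distribution for n ≤ 25 when the
  absolute differences are untied, and otherwise the normal approximation
  with continuity and tie corrections; it agrees with
  `stats::wilcox.test(paired = TRUE)` and exists only because the Monte
  Carlo needs a vectorised p-value over tens of thousands of replicates.
* **Fresh participants every replicate.** The hierarchy is part of the
  simulated experiment, so each Monte Carlo replicate draws a new sample of
  participants; power statements therefore average over participant
  sampling as a real replication would.
* **Seed management.** A single top-level seed spawns one independent
  substream per grid point, so individual grid points are reproducible in
  isolation and under any execution order.
* **Interpolation.** The minimum detectable effect is read off the
  empirical power curve by piecewise-linear interpolation between the first
  adjacent grid pair bracketing the target; the default grid is 0 to 0.08
  in steps of 0.005. Monte Carlo standard errors are
  $\sqrt{p(1-p)/n_{reps}}$.
* **RT-space conversion.** `delta_mu_to_rt_shift` evaluates
  $|1/\mu_{base} - 1/(\mu_{base}-\Delta\mu)| \times 1000$ exactly; e.g.
  $\Delta\mu = 0.0421$ at $\mu_{base} = 2.5$ gives 6.85 ms. Shorthand
  conversions that round intermediate quantities can differ by a few tenths
  of a millisecond; the package always reports the exact formula value.

The test suite runs the calibration and recovery checks at 2,000 replicates
per grid point, and `scripts/acceptance.R` runs the full design (10,000
replicates per point, both onset-noise levels) — sizes chosen so the whole
analysis is a desk-scale computation on one CPU.

## 2. The 1-up-1-down matching staircase

The staircase adjusts a comparison intensity on a normalized [0, 1] scale
with a fixed step of 0.05 (5% of the range; there is no step-halving). A
"comparison more intense" judgment moves the comparison down, a "vibration
more intense" judgment moves it up, so the procedure converges on the 50%
point of the psychometric function — the point of subjective equality. It
terminates after 8 reversals, 50 trials, or when the maximum intensity was
presented on each of the last 10 trials, in that precedence order. The
reversal-count criterion is configurable because descriptions of this
procedure vary between eight and nine reversals; the package defaults to 8.

Conventions worth noting:

* A **reversal** is a flip of the *intended* movement direction; the
  reversal value recorded is the intensity presented on the flipping trial.
  A move clamped at a bound does not create a reversal by itself — only an
  actual direction flip on a later trial does.
* The **plateau rule applies at the ceiling only**. A floor plateau is not
  a stopping rule: sitting at minimum intensity means the comparison is
  still judged more intense, which the trial limit handles.
* The **PSE** is the mean of the final six reversal intensities. If the
  track terminated with fewer than six reversals, all available reversals
  are averaged and the result is flagged `degraded`; zero reversals raise
  an error carrying the trial count and termination reason.
* The **simulated observer** judges the comparison more intense with
  probability $\lambda + (1-2\lambda)\,\mathrm{logit}^{-1}((x - PSE)/s)$;
  $s = 0$ gives a deterministic threshold observer (0.5 exactly at the
  PSE). The symmetric lapse keeps the function's 50% crossing at the PSE,
  so staircase bias estimates are not confounded by lapses.

Because a 1-up-1-down rule targets the 50% point, the package's recovery
property is that the mean recovered PSE over replicates is within one step
of the true PSE for a symmetric observer; the suite checks this with 500
replicates.

## 3. The redundant-target analysis pipeline

Trial filtering is two-stage and order-fixed: first the range filter
(RT < 100 ms or > 1000 ms removed), then a single pass of the deviation
filter removing trials more than 2.5 sample standard deviations (n−1
denominator) from their participant × condition cell mean, computed on the
range-filtered data. The single pass and the per-cell scope are deliberate:
iterating the SD filter or pooling cells changes the retained set in
data-dependent ways that are hard to reason about. Catch trials and misses
are tabulated but excluded from RT analysis. Cells left empty after the
range filter produce a warning and are skipped by the deviation stage.

Condition summaries compute participant-level means first and then the
group mean/SD/SE across participants, so `n` counts participants. The
repeated-measures ANOVA uses the classical univariate sums-of-squares
partition; Greenhouse–Geisser $\varepsilon$ is estimated from the sample
covariance of the condition columns (bounded to $[(k-1)^{-1}, 1]$) and
applied to both degrees of freedom. Mauchly's test comes from
`stats::mauchly.test` on the intercept-orthogonal contrast space; it is
undefined (reported `NA`) when there are fewer participants than
conditions. Because published analyses differ in which effect size they
print, both classical $\eta^2 = SS_{cond}/SS_{total}$ and partial
$\eta^2 = SS_{cond}/(SS_{cond}+SS_{error})$ are reported. Pairwise
comparisons are paired t-tests on the participant-level means with Holm's
step-down adjustment via `stats::p.adjust`. Degenerate inputs have defined
behaviour: identical condition columns give $F = 0$; two conditions give
$\varepsilon = 1$ exactly; missing cells raise an error instructing
listwise deletion upstream.

The corrected test is computed unconditionally, alongside the uncorrected
one, and the printed output leads with the corrected statistics; users who
prefer to gate the correction on Mauchly's p can do so from the returned
fields.

## 4. Waveform timing analysis

The envelope is frame-wise RMS with frame 2048 and hop 512 samples,
normalized to a peak of 1 (an all-zero signal stays zero), frame times at
frame centers. The default onset detector is an envelope threshold crossing
(default 0.05 normalized) with a 100 ms refractory interval, behind a
pluggable interface: any detector that outputs onset times with a pre-onset
amplitude annotation (for example a neural-network onset picker) can feed
the same downstream stages.

Two conventions deserve explanation:

* **Onset-time refinement.** With a 2048-sample frame, the first frame to
  cross the threshold is the first frame that *touches* the burst — its
  start can precede the physical onset by up to frame − hop samples
  (~35 ms at 44.1 kHz), and so the frame-level crossing only brackets the
  onset. The reported onset is therefore refined to the first raw sample
  whose absolute amplitude exceeds threshold × peak amplitude, searched
  over the ambiguous span. This bounds the recovery error by one hop for
  abrupt bursts, and for a linearly ramped burst it lands at the analytic
  threshold-crossing time, which is exactly what the generator oracle
  predicts.
* **Pre-onset floor annotation.** The spurious-onset filter rejects onsets
  flagged where the signal was already loud (normalized envelope above
  0.01, strict; exactly 0.01 is accepted). Frames are long and overlap, so
  frames straddling the onset already contain burst energy; each onset is
  therefore annotated with the envelope of the last frame ending at or
  before the onset time — the pre-onset noise floor — and that is what the
  filter inspects.

Device markers and detected onsets are aligned per trial to the
stimulus-onset trigger stream (nearest within 150 ms; unmatched triggers
are counted and reported, never fatal). Lag tables report marker − trigger;
marker-lag tables report marker − detected onset (for a ramped vibration,
the ramp period the marker waits through); asynchrony tables report
channel − reference (visual) per trial. The sign convention throughout is
that positive means "later than the reference event". All tables are in ms
with percentiles computed by linear interpolation between order statistics
(`quantile` type 7), stated so each cell is exactly reproducible. The ramp
regression is ordinary least squares with classical standard errors, via
`stats::lm`.

## 5. What the generators emulate — and what they do not

`gen_rte_trials` draws participant condition means from a multivariate
normal around configurable condition means/SDs (defaulting to published
group values for this paradigm: unimodal means near 0.48–0.51 s, trimodal
0.403 s, SDs ~0.1 s) with equicorrelated within-subject structure
(default ρ = 0.8 — repeated-measures RT data are strongly correlated
across conditions, and an uncorrelated generator would grossly understate
RM-ANOVA power). Trial RTs are normal around the participant mean with a
0.10 s trial-to-trial SD, a realistic within-participant dispersion for
simple RTs. Contamination defaults are 2% anticipations (uniform 0–90 ms),
2% slow outliers (uniform 1.05 s–deadline) and 2% misses; real sessions'
contamination rates vary widely, so these are exercise rates, not
estimates. The generator produces exactly the 100-trial session
composition: 30 catch trials plus 10 per target condition.

`gen_session_recording` builds 700-ms trials (300 ms foreperiod, 200 ms
stimuli) with triggers at 0/300/700 ms, a 440-Hz tone burst, a square light
pulse, and a vibration burst modelled as a 180-Hz carrier plus a small
broadband component under a linear amplitude ramp. Channel lag defaults
follow measured bench profiles for browser-delivered stimuli on a
smartphone (light 35.9 ± 4.3 ms, sound 40.9 ± 3.4 ms); the vibration
physical-onset lag defaults to 48.1 ± 3.0 ms with a 30.46 ± 5.28 ms ramp,
so the vibration device marker — which fires when the amplitude envelope
reaches `marker_threshold` (default 1.0, the end of the ramp) — lands near
79 ms, reproducing the characteristic pattern that threshold-based hardware
markers trail ramped stimuli. Device markers are computed on the amplitude
envelope rather than the oscillating waveform so the linear-ramp crossing
time has the exact closed form onset + threshold × ramp, usable as a test
oracle.

Limitations to keep in mind when interpreting green tests: lags are i.i.d.
across trials by default (an optional linear drift is available, but real
devices show block effects and temperature-dependent drift that the
generator does not model); the vibration spectrum of real motors is not
characterized here, and the 180-Hz carrier is a placeholder; real marker
SDs reflect correlated hardware noise that an i.i.d. generator cannot
reproduce jointly with the lag SDs; and the envelope-threshold detector is
not the neural-network detector used with real recordings, so agreement on
synthetic sessions does not certify agreement on field data. Passing
recovery tests show the pipeline is internally consistent against its own
ground truth — not that any particular phone behaves like the generator.

## 6. Problem sizes

The routine test suite uses reduced Monte Carlo sizes (2,000 power
replicates per grid point, 500 staircase replicates, 60–1000-trial
sessions at 22.05 kHz) chosen so the full suite runs in well under a
minute of simulation time while keeping Monte Carlo error far below every
asserted tolerance. `scripts/acceptance.R` runs the power analysis at its
full design size (10,000 replicates per grid point over the 17-point grid,
both noise levels).
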