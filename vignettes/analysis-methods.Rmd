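---
title: "Methods: spike regularity, band power, coherence, and maze scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike regularity, band power, coherence, and maze scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazephys)
```

`mazephys` implements the quantitative analysis battery of a combined
behavioral/electrophysiological rat study of adult-onset hearing loss:
single-unit firing statistics in the medial prefrontal cortex (mPFC) and
inferior colliculus (IC), spectral band power and inter-regional coherence of
local field potentials (LFP) and the sensorimotor-cortex electrocorticogram
(SMCtx-ECoG), error scoring for the 4-arm baited 8-arm radial maze, and the
group-level statistics tying them together. Because no such dataset is
publicly deposited, the package ships a seeded synthetic-cohort generator
that emulates the statistical structure of the recordings; every analysis is
exercised and validated against it.

## Single-unit statistics

All single-unit measures are functions of the inter-spike intervals (ISIs)
of one sorted unit over a recording epoch (100 s of spontaneous activity in
the emulated design). With ISIs $x_1,\dots,x_n$:

* **Firing rate** $FR = 1/\bar{x}$ (Hz), the reciprocal mean ISI.
* **Dispersion index** $DI = \sigma^2(x)/\bar{x}$ (seconds), the ISI
  variance over the mean. Regular, clock-like firing gives $DI \to 0$;
  Poisson firing gives $DI = \bar{x}$. For a gamma renewal process with
  shape $k$, $DI = \bar{x}/k$ analytically — the property the tests use.
* **Asymmetry index** $AI = \mathrm{mode}(x)/\bar{x}$ (dimensionless),
  near 1 for regular and near 0 for irregular firing.

Numerical choices the definitions leave open:

* The standard deviation is the population (divide-by-$n$) plug-in
  estimator; at hundreds of ISIs per unit the difference from the $n-1$
  convention is negligible, and the plug-in form matches the moment
  definition of $DI$.
* The mode of a continuous ISI distribution needs an estimator: we use the
  center of the most occupied histogram bin, 1 ms bins by default, over
  $[0, q_{99}]$ of the ISIs (the 99th-percentile cap keeps one long pause
  from stretching the grid). Ties break toward the smallest bin center. $AI$
  depends on the bin width, which is therefore a surfaced argument. When the
  estimated mode exceeds the mean ($AI > 1$, possible for near-symmetric ISI
  histograms), the value is flagged with a warning, never clamped.
* Units with fewer than 50 spikes per epoch (0.5 Hz over 100 s) are excluded
  from summaries and reported in an exclusion table; the threshold is
  configurable because no principled universal value exists.

Note one deliberate literalism: $DI$ as defined operates on ISIs and has
units of time, although it is described as a dispersion of the firing rate.
We implement the formula exactly as stated and keep seconds as the unit.

## Field-potential spectra

Traces (1 kHz sampling, microvolts) pass through:

1. **Artifact screening** — an amplitude threshold replaces the manual
   overshoot inspection of the original workflow. Contiguous spans that stay
   below threshold survive; surviving spans shorter than one Welch block are
   dropped because they cannot contribute a spectral block. A rejection
   report is always returned. (Slow-wave state exclusion, a manual step in
   the emulated workflow, is approximated by this screening plus an optional
   delta-power cap; the synthetic generator produces no state transitions,
   so the cap is off by default.)
2. **Filtering** — a 50 Hz FIR notch (band-stop, order 400) and a 100 Hz FIR
   low-pass (order 220, −6 dB at 108 Hz), both applied zero-phase
   (forward–backward). The two kernels are combined by convolution and
   applied via FFT convolution, which is numerically identical to direct
   forward–backward filtering away from the edges but $O(n \log n)$. The
   cascade attenuates 50 Hz and everything above 120 Hz by more than 30 dB
   while keeping passband ripple under 1%. The analyzed gamma band extends
   to the 100 Hz low-pass edge, so some attenuation at the very top of the
   gamma band is unavoidable; it affects both groups identically and is left
   uncorrected.
3. **Welch periodogram** — Hann-windowed blocks of 1024 samples, per-block
   mean removal, 50% overlap (a standard bias/variance compromise; the block
   length and window are fixed by the emulated pipeline, the overlap is
   not), block spectra averaged across all blocks of all clean segments. At
   1 kHz this gives the documented frequency resolution of
   1000/1024 = 0.9766 Hz. The one-sided density is scaled so that
   $\sum P(f)\,\Delta f$ reproduces the windowed-signal variance (Parseval;
   tested to 1% on stationary noise).

**Band power.** Canonical bands are theta 4–8, alpha 8–12, beta 12–30 and
gamma 30–100 Hz. Band membership of a grid frequency is half-open
$[f_{lo}, f_{hi})$, so 8 Hz belongs to alpha, not theta. Absolute band power
is the trapezoidal area of the PSD over the band, with the spectrum linearly
interpolated at the exact band edges — this makes band areas exactly
proportional to bandwidth for a flat spectrum and lets the four bands tile
4–100 Hz without gaps. Relative power is the percentage of the area over a
reference interval, 1–100 Hz by default (the denominator is not fixed by the
emulated description; 1 Hz excludes DC and sub-delta drift, and the choice
is surfaced as an argument).

## Coherence

Magnitude-squared coherence between a region LFP and the SMCtx-ECoG is
estimated from the same 1024-sample Hann blocks as the PSD,

$$C(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1],$$

so PSD and coherence share one spectral grid. Per-block mean removal is
applied before windowing to avoid DC leakage into theta. A single block
would give $C \equiv 1$ identically, so at least two blocks are required.
The 95% confidence threshold for zero coherence, $1 - 0.05^{1/(L-1)}$ with
$L$ segments, is attached to every estimate; with 50% overlap the raw
segment count is used for $L$, which overstates $L$'s information content
slightly and is therefore conservative *against* declaring zero coherence
absent. Band summaries are unweighted means of $C(f)$ over the grid points
in each band (integration would weight wide bands differently; the emulated
analysis does not state which was used, and the unweighted mean is the
simpler convention).

## Radial-maze scoring

Runs are ordered arm-entry sequences on an 8-arm maze with 4 baited arms.
Scoring rules, applied per run:

* **RME** (reference memory error): a *first* visit to an unbaited arm.
* **WME** (working memory error): any re-entry into an arm already entered
  during the same run — baited or not, and regardless of whether its reward
  was already collected. This is the literal reading of "previously entered
  arms"; an alternative reading in which only baited-arm re-entries count as
  WME (and every unbaited entry is an RME) is available as
  `wme_scope = "baited"`.
* Each entry contributes to at most one category: a revisit of an unbaited
  arm is a WME, not a second RME. Double-counting would break the invariant
  that a run's total errors never exceed its entry count.

Blocks are three consecutive runs; the **completion criterion** is met at
the first block $b$ such that blocks $b-2..b$ each have WME < 3 *and*
RME < 2 (so WME 2 and RME 1 qualify). Baited sets contain four arms with no
three circularly adjacent arms all baited (arm 8 neighbours arm 1);
**reversal** sessions bait the complement of the training set. The
complement of a valid training set can itself contain three adjacent arms
(e.g. training 1,2,4,5 leaves 3,6,7,8), so the adjacency constraint — which
governs only the randomized training assignment — is not re-imposed on
reversal sets.

The exhaustive test suite scores *every* entry sequence of length ≤ 6 under
*all* 38 valid baited sets against an independently written brute-force
scorer.

## Group statistics

* **Electrophysiology**: two-sided Mann-Whitney U. Exact p-values for
  combined $n \le 20$ without ties, otherwise the tie-corrected normal
  approximation — at the emulated sample sizes (hundreds of units) only the
  approximation is ever exercised. Units and epochs are pooled across
  animals within group, mirroring the emulated design's unit counts; this is
  a known pseudo-replication choice, and per-animal aggregation is available
  by first averaging the per-unit table within animals.
* **Behavior**: two-way repeated-measures (split-plot) ANOVA with the
  between factor *group* and within factor *week* (or *block*), fitted via
  `aov` with an animal error stratum. No sphericity correction is applied by
  default because the emulated analyses report uncorrected degrees of
  freedom. Bonferroni post-hoc tests are pooled-variance two-sample t-tests
  per week, adjusted across weeks; they run automatically when the group or
  interaction effect is significant at 0.05, and `posthoc = "always"`
  provides the explicit override for post-hoc testing after a mere trend —
  deliberately never the default.
* **Missing data**: animals lost mid-study are completed by the group mean
  of the observed values at each affected week. The rule leaves every
  (group, week) mean unchanged (tested algebraically) and logs every imputed
  cell. It does shrink within-group variance, which is why the log is
  surfaced rather than hidden.

A null-calibration test (1000 simulated datasets, 2 groups of 10 and 13
animals × 11 weeks, no group effect) checks that the group-effect rejection
rate stays at 5% ± 1.5%.

## The synthetic cohort

`generate_cohort()` draws, per synthetic animal: spike trains for mPFC and
IC, two field-potential pairs (mPFC-LFP/SMCtx-ECoG and IC-LFP/SMCtx-ECoG,
generated independently as in a sequential recording protocol), one maze
training session, and weekly behavioral summary measures. Defaults encode
the emulated study conditions: 10 deaf vs 13 control animals, 100 s epochs
at 1 kHz, and per-animal unit counts (Poisson means 47/66 for mPFC
control/deaf, 33/44 for IC).

* **Spike trains** are gamma renewal processes: ISIs i.i.d.
  gamma(shape $k$, mean $1/\lambda$), so the CV is $1/\sqrt{k}$ and the
  shape parameter maps monotonically onto both regularity measures
  ($DI = \bar{x}/k$ falls and $AI$ rises with $k$). A 2 ms absolute
  refractory period is enforced by dead-time deletion after generating at
  the compensating rate $\lambda/(1 - \lambda\,\tau)$, keeping the realized
  rate interpretable.
* **Field potentials** are synthesized in the frequency domain: band-limited
  complex-Gaussian carriers on the four canonical bands (randomized phase),
  $1/f$ background noise, and a deterministic 50 Hz line component (2 µV by
  default, so the notch stage is always exercised). Carrier amplitudes are
  RMS microvolts. For each band a fraction `coupling` of the carrier
  *variance* is shared between the two traces of a pair; the expected
  magnitude-squared coherence in the band is therefore `coupling`², with
  `coupling = 1` giving sample-identical carriers and `coupling = 0` the
  estimator bias floor $\approx 1/L$.
* **Maze sessions** draw each arm entry by a three-way choice: re-enter a
  visited arm with probability `p_wme` (once any arm has been visited),
  otherwise enter an unvisited unbaited arm with probability `p_rme`,
  otherwise an unvisited baited arm. Runs end when all four baited arms have
  been visited or after 50 entries — the stand-in for the 15-minute session
  timeout, since synthetic runs have no clock. Both probabilities decay by
  `learning_decay` per 3-run block, producing the learning curve.
* **Group effects** point in the reported directions: deaf animals get lower
  mPFC rate and shape (FR↓, DI↑), lower theta amplitude in all three
  channels, lower gamma amplitude in IC and SMCtx, lower mPFC–SMCtx theta
  coupling with higher gamma coupling, higher IC–SMCtx alpha/beta/gamma
  coupling, and higher initial maze error probabilities. Effect *magnitudes*
  are free design parameters of the generator — the emulated study reports
  its contrasts only graphically — chosen once to be physiologically
  plausible, and recorded in the cohort manifest. Per-animal lognormal
  jitter (sd 0.12 on rates and amplitudes, plus sd 0.1 per band and sd 0.2
  per unit) makes animals heterogeneous so that group tests are not
  trivially separated.

Determinism: every generator takes an integer seed and restores the global
RNG state afterwards; identical configuration + seed reproduces spike times,
traces, maze logs and the manifest bit-for-bit (R's default Mersenne-Twister
generator, documented here as the stated algorithm).

**What the generator does not emulate**: biophysical neuron or cochlear
dynamics, auditory brainstem responses, urethane brain-state alternations
(REM/non-REM), electrode drift, correlated noise between units, or
within-animal session-to-session learning transfer. Passing recovery tests
therefore show that the *analysis pipeline* detects effects of the designed
kind and direction at realistic sizes — they are not evidence about real
recordings.

## Problem sizes used by the validation suite

The test suite's simulation sizes are package choices balancing statistical
resolution against runtime: renewal-statistic convergence at 1000 s
duration (≈10⁴ ISIs, 5% tolerance), DI/AI gamma-family checks at 10⁴ ISIs
and shapes 1/4/16, the exhaustive maze oracle over all 299,592 sequences of
length ≤ 6 × 38 valid baited sets, Mann-Whitney permutation cross-checks at
10⁵ resamples × 20 cases, RM-ANOVA calibration over 1000 null datasets, and
parameter recovery over 100 seeded replicate cohorts at the full study
geometry (10 + 13 animals, ~2,200 units, six 100-s traces per animal).

## Known limitations

* Relative band power couples the four bands through the common
  denominator: lowering one band's absolute power necessarily raises the
  others' relative shares. Direction claims about untargeted bands should be
  read with this in mind.
* In a gamma renewal family DI and AI are both monotone functions of the
  shape parameter, so the generator cannot produce a DI difference without
  an accompanying AI difference, as in a study where AI stays flat while DI
  moves.
* The coherence pipeline assumes time-aligned, equal-length pairs; artifact
  screening is per channel and may split channels differently, so coherence
  is computed on the filtered full-length traces (synthetic traces are
  artifact-free by construction). Real data with heavy artifacts would need
  a joint clean-span intersection first.
* Pooling units/epochs across animals reproduces the emulated statistics
  but inflates effective sample size relative to animal-level inference.
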