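---
title: "Reconstructing hidden spatial priority maps from alpha-band power: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing hidden spatial priority maps from alpha-band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pingCTF)
```

## The scientific problem

When a salient distractor appears more often at one display location, search
becomes more efficient there: the visual system learns to suppress the
high-probability location (HPL). Whether that suppression is *proactive*
(priority weights are lowered before any attention shift) or *reactive*
(the location is first selected, then suppressed) cannot be decided from
reaction times alone. One window into the question is the hidden spatial
priority map itself: a neutral, high-contrast "ping" (a placeholder display)
evokes activity that passes through the current synaptic landscape, so
multichannel EEG recorded around ping onset carries an imprint of otherwise
activity-silent spatial representations. pingCTF implements the full
analysis by which such imprints are reconstructed and tested, and a
forward-model simulator that generates data with known ground truth so that
every stage can be validated by parameter recovery.

## The encoding model

The core assumption is that band-limited power at each electrode is a
weighted sum of `k = 8` spatial channels, each tuned to one of eight
equally spaced angular locations. Each channel's tuning curve is a half
sinusoid raised to the seventh power,

$$R(\theta) = \sin(\theta/2)^7,$$

shifted so channel $j$ peaks at $45^\circ (j-1)$. At angular distance $d$
from a channel's center the response is $\cos(d/2)^7$: 1 at the center,
0.5745 at 45°, 0.0884 at 90°, 0.0012 at 135°, 0 at 180°. Training data
$B_1$ ($m$ features × $n_1$ observations, per time sample) are modeled as

$$B_1 = W C_1,$$

where $C_1$ ($k \times n_1$) holds the basis-predicted channel responses of
the training observations and $W$ ($m \times k$) is estimated by least
squares. On held-out data $B_2$ the model is inverted, solving
$\hat W C_2 = B_2$ for the estimated channel responses $C_2$. Each
response vector is then circularly shifted so the channel matching the
observation's cue location sits at offset 0° — a channel tuning function
(CTF). Spatial selectivity is summarized by the *CTF slope*: the profile is
folded across its symmetric offsets (±45°, ±90°, ±135°) to five points at
distances 0–4 and a least-squares line is fitted; the coefficient is
sign-flipped so positive slope = selectivity. On the ideal basis profile the
slope is 0.2573, and a flat profile maps to exactly 0.

### Observations, partitioning, iterations

Observations are not single trials but per-set × per-location-bin averages
of power, after randomly partitioning trials into three independent sets
(two train, one test) with per-bin trial counts equated by random
subsampling to the largest multiple of the set count below the smallest bin
count. In cross-session mode the localizer (training phase) is split into
two training sets and the *entire* test phase forms the test set, with
training and test time samples strictly aligned. Because a single partition
is noisy, the partition→average→train→invert→re-center loop is repeated
(100 iterations at recording scale) and CTFs are averaged across
iterations; each iteration re-derives power from the analytic signals after
re-partitioning. Encoding uses the bin-center angles for $C_1$ (bins are
the design unit; the ±22.5° jitter is deliberately ignored at the modeling
stage, though exact angles are available).

## Evoked versus total power

Alpha-band analytic signals are obtained by a zero-phase (forward–backward)
fifth-order Butterworth band-pass at 8–13 Hz followed by the Hilbert
transform. Zero-phase filtering is essential: a causal filter would delay
every CTF latency. Two power definitions are kept strictly separate:

* **evoked power** — the squared magnitude of the across-trial *mean
  complex* analytic signal of a group: only phase-locked activity survives
  complex averaging;
* **total power** — the across-trial mean of per-trial squared magnitudes:
  all band-limited activity, phase-locked or not.

Jensen's inequality guarantees evoked ≤ total for any group, which the
test suite asserts on every synthetic run. Power series are smoothed with
a centered 8-sample moving average (15.62 ms at 512 Hz) and can optionally
be reduced to 16 principal components.

Two numerical choices deserve note. First, the production filter + Hilbert
path is implemented in the frequency domain: the epoch is odd-reflection
padded to a fast FFT length, multiplied by the exact squared Butterworth
magnitude response $|H(\omega)|^2$ (zero phase by construction) times the
analytic-signal mask, and inverse transformed. A time-domain
forward–backward recursion with steady-state initial conditions is kept in
the package as an independent second route; the two agree in the analysis
window and the tests assert it. The padding is sized from the filter's
slowest pole so that the circular convolution cannot wrap band-limited
content across the epoch (the 8–13 Hz filter rings for hundreds of
samples; with short padding, wrapped ping energy is detectable at the
epoch edge at group-level sensitivity — the test suite caught exactly
this). Second, the PCA rotation is fitted on training observations only,
pooled over time samples, and is *uncentered*: the encoding GLM has no
intercept, so centering would inject an affine offset the model cannot
absorb; an uncentered orthogonal rotation leaves the least-squares problem
unchanged exactly, which makes the "PCA with all components = no PCA"
equivalence testable to machine precision.

## Statistics

CTF slopes (subjects × time) are tested with a cluster-based one-sample
sign-flip permutation test: a t statistic per sample, clusters formed
where |t| exceeds the two-tailed critical value at α = 0.05 with n−1 df
(the cluster-forming rule is configurable; the field offers no single
convention), cluster mass = summed t, and a null distribution of maximum
absolute cluster masses from 1024 random per-subject sign flips. A cluster
is significant when its mass exceeds the 95th percentile of that
distribution; p-values carry the add-one correction
$(1 + \#\{perm \ge obs\})/(1 + n_{perm})$ so they can never be zero. The
distance-gradient analysis fits, per subject and time sample, a
least-squares line to the five distance-grouped CTF slopes (distances 0–4
from the HPL) and submits the per-subject coefficients to the same cluster
test; fitting per subject first, then testing at the group level, keeps
the inference paired.

The behavioral stage mirrors the standard search-task analysis: incorrect
responses and RTs < 200 ms are dropped, then per subject RTs beyond ±2.5
SD of the condition-collapsed mean (SD computed after the first two
filters); distractor conditions are absent / HPL / LPL with the exclusion
rule that a trial counts as low-probability only when *neither* the
distractor *nor the target* occupies the HPL (without it, target-position
costs contaminate the suppression contrast — with it, the planted HPL
benefit is recovered without bias, which the tests exploit); distance
conditions dist1–dist4 enter a one-way repeated-measures ANOVA with
Greenhouse-Geisser correction (ε computed from orthonormal contrasts of
the sample covariance; ε = 1 under compound symmetry by construction) and
Holm-Bonferroni-corrected pairwise follow-ups; paired t-tests report
Cohen's d on difference scores.

## The synthetic-data generator

The generator emulates the two-phase design: a training phase of 10 blocks
× 80 memory-only trials and a test phase of 10 blocks × 92 trials with an
embedded search task; 8 location bins at 45° spacing with uniform ±22.5°
jitter (the bin label is the generating bin); a distractor on 74% of test
trials, at the HPL on 65% of those and 5% at each other location; and 13%
no-memory test trials. Conditions are sampled i.i.d. per trial — matching
the probabilistic wording of the design — so realized proportions
fluctuate binomially, and all composition checks are statistical (4
standard errors at ≥ 50,000 trials).

Behavioral outcomes are additive: a base RT plus condition deltas
(distractor-at-HPL benefit, target-at-HPL cost, per-distance deltas,
repetition benefit) plus Gaussian noise, with negative draws resampled;
accuracy is Bernoulli per condition; recall deviation is wrapped-normal
with a larger SD in the test phase (emulating dual-task degradation
without reproducing any recorded value).

Epochs come from an explicit forward model: the channel activation vector
is the basis evaluated at the trial's true (jittered) cue angle; electrode
signal = mixing × activation × alpha carrier. The phase-locked (evoked)
component has a fixed carrier phase across trials; the induced component
draws a uniform random phase per trial; in placeholder-locked epochs the
phase-locked revival amplitude is multiplied by a planted gradient over
bin distance from the HPL — the ground truth for all recovery tests. Pink
(1/f) plus white noise is added per electrode. The mixing matrix gives
each channel a smooth von-Mises-shaped topography over electrode azimuth
with a small random perturbation guaranteeing full column rank; real alpha
topographies are unknown at this level of description, so this is a
documented modeling choice that the inverse model never sees. The
generator does **not** simulate saccade dynamics, realistic lead fields,
eye-tracker sample streams, or the recall mouse response; passing recovery
tests therefore demonstrates the correctness of the analysis chain, not
that real EEG satisfies the forward model.

Artifact injection adds 125 Hz tapered bursts (inside the 110–140 Hz
detection band) to chosen trials/electrodes, step-like HEOG deflections,
and gaze excursions on a simulated radial gaze trace, with truth masks.
The muscle screen band-passes 110–140 Hz, z-scores the envelope per
electrode, scores each epoch by the peak electrode-summed z in the window
of interest, and thresholds at median + 4 × MAD of the epoch scores — the
robust counterpart of a mean + SD rule, chosen because the artifacts
themselves inflate a non-robust spread estimate at realistic contamination
rates. Flagged epochs are repaired by interpolating up to five most
contributing electrodes one at a time (inverse-distance weighting over the
four nearest neighbors — interpolation quality is not the scientific
target here, so no spherical splines), and dropped only if still above
threshold. Eye rejection uses a 1.2° gaze-excursion rule in the
lock-specific window, falling back to a sliding 200 ms / 10 ms HEOG step
detector at 15 µV.

## Desk-scale study conditions

The default pipeline configuration is sized so a full 24-subject run
completes in well under a minute per cohort on one core, while keeping
every structural property of the recording-scale analysis:

* 24 simulated subjects; 16 electrodes; 2 blocks per phase for the neural
  simulation (160 training + 184 test trials per subject) while the
  behavioral analyses use the full 10-block design;
* 128 Hz sampling — ample for an 8–13 Hz analysis; the smoothing window
  is scaled to preserve its 15.62 ms duration; the generator's default
  remains 512 Hz;
* placeholder-locked epochs spanning −1.25 to 0.75 s with an analysis
  window of −1.0 to 0.5 s. The long pre-ping stretch is deliberate: the
  zero-phase narrowband filter smears genuinely planted post-ping tuning
  backwards by several hundred milliseconds (its pole pairs beat, so the
  backward tail even has side lobes), which means cluster onsets are not
  sharp and a short baseline is never smear-free. Specificity is
  therefore assessed beyond the filter's reach (no significant cluster
  entirely before −0.7 s), and planted-window checks ask for overlap with
  the ping window rather than exact onsets;
* 10 encoding iterations and 512 permutations for routine runs; the
  recording-scale 100/1024 remain function defaults where they are cheap;
* noise levels (pink SD 1.5, white SD 0.5, ping amplitude 1) calibrated
  once so that single-subject CTF recovery succeeds at roughly 300 trials
  and group-level recovery is reliable at the sizes above.

## Known limitations

* The forward model shares one spatial pattern between evoked and induced
  components and adds spatially independent noise; real data have
  correlated noise fields and multiple sources.
* Epoch-based narrowband filtering is intrinsically edge-limited: poles at
  |z| ≈ 0.97–0.996 ring far longer than typical epochs, so *any*
  implementation differs from filtering an unbroken recording, and
  temporal precision near window edges is limited by physics, not code.
* The cluster-forming threshold and tail handling follow one common
  convention among several; both are configurable, and conclusions should
  be robust to that choice.
* ICA-based blink removal, continuous-recording filtering, re-referencing
  and recording-format ingestion are out of scope; artifact handling
  starts from epochs.
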