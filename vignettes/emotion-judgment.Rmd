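---
title: "Rule-based valence–arousal judgment from EDA and pulse-wave streams"
author: "affectstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based valence-arousal judgment from EDA and pulse-wave streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectstream)
```

## The problem

Peripheral physiological signals index emotional state without asking the
user anything: electrodermal activity (EDA, skin conductance) tracks
sympathetic arousal, and the pulse wave (PPG, blood-volume change per
heartbeat) carries heart-rate and heart-rate-variability information. In
the circumplex view, an emotional state is a point in the
valence–arousal plane, and the four quadrants — HAPV (high arousal,
positive valence), HANV (high arousal, negative valence), LANV (low
arousal, negative valence) and LAPV (low arousal, positive valence) —
are a coarse but actionable classification: an adaptive game can react
differently to each.

`affectstream` implements a complete streaming pipeline for this
judgment: every 10 seconds it summarizes the two channels into a handful
of features, compares them against per-feature adaptive thresholds, and
walks a small rule tree to emit one quadrant label (or `UNDECIDED`).
Alongside the rule engine it carries the supporting apparatus: a
labelled synthetic-session generator, the preprocessing chain, a
feature catalogue with an optimal-subset selection procedure, an SVM
baseline for head-to-head comparison, and the policy that maps sustained
quadrant decisions to game-adaptation events.

## Preprocessing

**Hardware calibration.** Raw skin-conductance counts from the
acquisition device carry a deterministic interference that is removed by
the rational correction

$$f(r) = r - \frac{(2014 + 2r) \times 10000}{512 - r},$$

whose constants are device-debugging values. The transform has a pole at
`r = 512`; a sample at exactly that count raises a singularity error
naming the sample. Synthetic and pre-calibrated data skip the transform
(`mode = "off"`, the default).

**Wavelet denoising (EDA).** The EDA trace is decomposed three levels
deep with the orthogonal Daubechies-4 (8-tap) wavelet, the detail
coefficients are soft-thresholded, and the trace is reconstructed. The
default threshold is the universal rule $\sigma\sqrt{2\log N}$ with
$\sigma$ estimated from the finest detail level by the
median-absolute-deviation rule. The transform is written in the package
(periodized Mallat pyramid with odd-length handling); with the threshold
forced to zero it reconstructs the input to ~1e-14, which the tests
assert, so the denoiser degrades gracefully to the identity.

**Low-pass filtering (PPG).** The pulse wave is smoothed with a
Butterworth low-pass — maximally flat in the pass band, monotone to zero
in the stop band, magnitude response
$H(D) = 1/(1 + (D/D_0)^{2n})$ with $H(D_0) = 1/2$ at the cutoff. The
digital realization is a 4th-order IIR filter applied forward and
backward (zero phase, so fiducial timing is untouched) with a 10 Hz
cutoff. The input is odd-reflection padded before filtering; without the
padding the forward–backward pass has startup transients proportional to
the DC level, which would leak into the min–max normalization below and
break the pipeline's invariance to channel offset.

**Normalization.** Each whole trace is min–max normalized to 0–100.
Normalization is per *trace*, not per window: per-window normalization
would force every window's range to 100 and erase exactly the
between-window amplitude differences the rule tree tests. Because every
judged feature stream is re-normalized against its own calibration span
(next section), decisions are invariant to this choice and, more
generally, to any positive affine rescaling of either raw channel — a
property the test suite checks end to end.

## Features

**Pulse fiducials.** Each beat has four landmarks: the main (systolic)
wave, the dicrotic anterior wave (the shoulder on the systolic decay),
the dicrotic notch (the single local minimum between the main and
dicrotic waves) and the dicrotic wave (the diastolic secondary peak).
`detect_beats()` finds main-wave peaks by prominence-and-spacing peak
picking (height above half the window span, ≥ 0.35 s apart), then
locates per beat the highest interior local maximum (dicrotic wave), the
lowest local minimum before it (notch) and the flattest point between
peak and notch (anterior shoulder). Inter-beat intervals are successive
main-wave peak differences.

**The judged features.** Five streams feed the rule tree:

* `eda_range` — window max minus min of the EDA channel;
* `eda_1dmean` — mean first-order difference of the EDA window,
  $\frac{1}{N-1}\sum_i (x_{i+1} - x_i)$, a signed slope proxy that
  telescopes to $(x_N - x_1)/(N-1)$;
* `ppg_bpnn50` — the fraction of successive inter-beat-interval
  differences exceeding 50 ms (strict inequality), the pulse analogue of
  the HRV statistic pNN50. The absolute difference is used by default;
  a `signed_diffs` switch gives the literal one-sided reading;
* `ppg_range` — window max minus min of the PPG channel;
* `ppg_1dmean` — mean first difference of the per-beat *main-wave
  amplitude* series, i.e. the slope of the pulse envelope. The
  sample-level first-difference mean of an oscillatory pulse telescopes
  to the phase difference at the window boundaries and carries no
  envelope information, so the envelope form is the only reading under
  which a "pulse 1dmean" test can respond to pulse-amplitude growth.
  The sample-level statistic is still computed (`ppg_1dmean` in the
  catalogue's time-domain family).

**The catalogue.** The selection procedure operates on a realistic
dimensionality: 24 EDA and 18 pulse time-domain descriptors, 8
frequency-domain descriptors per channel computed by one shared
periodogram implementation (total and band powers around typical phasic
and cardiac content, spectral centroid/entropy, peak frequency), and
physiological descriptors (7 EDA: SCR count/amplitude/rise, tonic level,
phasic variability, AUC, maximum deflection; 10 pulse: IBI mean/SDNN/
RMSSD/BpNN50, amplitude statistics, notch and dicrotic amplitude ratios,
onset-to-notch and onset-to-peak times). Counts per family are fixed and
asserted in the tests; features of windows without two detectable beats
are absent (`NA`), never zero.

## The adaptive threshold and the rule tree

Each feature stream gets a normalized threshold

$$x_{th} = \frac{1}{n}\sum_{i=1}^{n} \frac{x_i - x_{\min}}{x_{\max} - x_{\min}},$$

the mean of the min–max-normalized values over a *reference span*: the
first `calibration_windows` (default 4) windows of the session. The
normalization parameters are frozen from that span; later values are
normalized with the same parameters and clipped to [0, 1]. Freezing
keeps the decision stream causal and reproducible — a rolling-window
mode exists but is off by default. Calibration windows are emitted as
`UNDECIDED`. A stream that is constant over the calibration span cannot
be normalized; its tests are skipped with a warning, and only if *every*
stream is degenerate does the session fail.

Each window is then judged by two branches of strict comparisons
(boundary equality always falls to the "otherwise" arm):

* **EDA branch** — if normalized `eda_range` > $x_{th}$: a falling
  deflection (`n_max` ≤ `n_min`, first-occurrence indices of the window
  extrema) is **LAPV**; a rising deflection with normalized
  `eda_1dmean` > $x_{th}$ is **HANV**.
* **Pulse branch** — if normalized `ppg_bpnn50` > $x_{th}$: high
  normalized `ppg_range` is **LANV**; otherwise high normalized
  `ppg_1dmean` is **HAPV**.

If both branches fire, the fixed priority HANV > LANV > LAPV > HAPV
resolves the conflict (negative-valence states drive the game
adaptation, and HAPV triggers nothing, so it yields last); the conflict
and its resolution are recorded in the decision's `rule_trace`, which
replays to the same outcome. The tests hold the engine against a
literal nested-conditional transcription of this logic on 10,000 random
feature tuples.

## Optimal-feature selection

Selection is two-staged. First, PCA on the standardized feature table:
components are retained to 95% cumulative explained variance, and each
feature is scored by its absolute loading normalized by the largest
absolute loading on that component, maximized over retained components.
The per-component normalization measures how close a feature comes to
*leading* some retained direction; without it, a family of mutually
redundant informative descriptors (mean, percentiles, range … all
tracking the same deflection) dilutes its loadings to $1/\sqrt{m}$ and
loses to whichever noise feature happens to dominate a small retained
component. The 95% target keeps the lower-variance contrast directions
— in particular the one separating the two high-EDA-range quadrants by
slope — that an 85% target demonstrably drops. Features above the mean
weight form the candidate subset; constant columns are excluded with a
warning.

Second, each candidate is Pearson-correlated with the one-vs-rest
indicator of each quadrant; a feature is kept for a quadrant when
$|r| \ge 0.3$ and the two-sided $P < 0.10$. The screen is deliberately
liberal and the magnitude floor does the gating: on a 12-window session
with balanced four-quadrant labels, a feature elevated in exactly two
quadrants (EDA range, which rises for both LAPV and HANV; BpNN50, for
both LANV and HAPV) has one-vs-rest $r = 0.577$, whose
$t = r\sqrt{(n-2)/(1-r^2)} = 2.236$ sits *on* the df = 10 two-sided 5%
critical value 2.228 — an $\alpha = 0.05$ screen would accept or reject
on noise. Under the null the $|r| \ge 0.3$ floor alone excludes a
200-window noise feature essentially always, which the tests verify by
simulation.

On sessions generated under the default quadrant signatures the final
subset contains `ppg_bpnn50`, `eda_range` and `eda_1dmean` — the three
features the rule tree runs on — and `eda_range` screens in for both
LAPV and HANV, reflecting the strong positive correlation of the EDA
range with both of those emotion trends.

## The synthetic-session generator

No public corpus pairs these two channels with per-window quadrant
labels, so the generator is a first-class module: it encodes one
canonical signature per quadrant — exactly the conditions the rule tree
tests — and produces bit-reproducible sessions under a fixed seed.

| quadrant | EDA range | EDA deflection | IBI jitter | pulse amplitude | pulse envelope |
|----------|-----------|----------------|------------|-----------------|----------------|
| HANV | high | rising ramp (steep) | 15 ms | low | flat |
| LAPV | high | falling ramp | 15 ms | low | flat |
| LANV | low | tent (flat net slope) | 150 ms | high | flat |
| HAPV | low | tent | 150 ms | low | rising |

Fixed constants (arbitrary units; every judgment is
normalization-based, so only relative structure matters): EDA baseline
10, range 2 (low) / 10 (high); pulse amplitude 1 (low) / 8 (high);
additive Gaussian noise with σ = 2% of the deflection span; base
inter-beat interval 800 ms, jitter draws clamped to 0.4–1.6 × base so
beats never collide; envelope gain 0.6 per window when rising. The beat
template is a sum of three Gaussian bumps tuned so that exactly one
local minimum (the notch, phase 0.594) separates the main wave (phase
0.236) from the dicrotic wave (phase 0.699), with the anterior shoulder
as an inflection between peak and notch. The rising envelope is keyed
to the *peak* time modulo the window length, so the sawtooth restarts
exactly at window boundaries as a window-local detector sees them.

The default benchmark session is one segment per quadrant in the order
HANV → LANV → LAPV → HAPV, three 10-s windows each. The order matters:
with a four-window calibration prefix it guarantees the prefix observes
both the low and the high level of every judged stream, which is what
makes the frozen min–max normalization meaningful. (The pulse-envelope
stream is flat over every such prefix; its clipped normalization still
ranks a later genuine rise at 1, so the HAPV test survives.)

What the generator deliberately does **not** emulate: habituation and
tonic drift across a session, motion artifacts, respiratory modulation,
missing data, or physiologically calibrated SCR/pulse morphology.
Passing tests therefore demonstrate that the pipeline recovers the
structure the rules assume when it is present — parameter recovery, not
field validity on human recordings.

## The comparison baseline

The conventional alternative is a support-vector machine (RBF kernel,
`cost = 1`, default gamma) trained on the full catalogue with a seeded,
stratified 70/30 split. The scripted benchmark is cross-subject: the
SVM is trained on one synthetic subject and both approaches are
evaluated on a second whose heart rate (base IBI 950 vs 800 ms), HRV
jitter levels (25/110 vs 15/150 ms) and channel gains/offsets differ —
the typical between-subject variation. Whole-trace normalization
removes the gain differences for both approaches, but the HR/HRV traits
remain: the rule engine re-derives its thresholds from the evaluation
subject's own calibration prefix and transfers, while the fixed
feature-space SVM degrades toward chance. Both approaches are scored on
identical post-calibration windows; activation counts are reported both
raw and restricted to events matching the ground-truth label.

## The adaptation policy

Sustained decisions trigger game events: HANV → reward bricks (pull the
player out of negative valence), LAPV → spawn monsters (raise arousal),
LANV → a new scene, HAPV → no action (the ideal entertainment state is
logged, never acted on — which is why activation tables carry an empty
HAPV column, deliberately distinct from zero). An event fires when the
same quadrant persists `persistence` windows (default 1); a refractory
period (default 1 window) suppresses re-triggering of the same
quadrant; `UNDECIDED` resets persistence. After two `new_scene` events
the session-end flag raises, matching the reference account of a
subject who twice entered a new scene and ended the game.

The package ships the two reference activation-count tables from the
ten-subject evaluation study (one round per approach) as plain-CSV
fixtures; `verify_activation_tables()` recomputes every subtotal row
and the subject-3 narrative counts from the per-subject rows.

## Numerical choices and problem sizes

* Windows are half-open, non-overlapping, 10 s; a trailing partial
  window is dropped so every window has equal length. Extremum index
  ties resolve to the first occurrence; indices are 0-based.
* All rule comparisons are strict; min–max degeneracy is detected with
  a relative tolerance of 1e-12 so float-level wiggle on a constant
  segment still counts as degenerate.
* Every random draw flows from one user seed through named integer
  substreams; library code restores the caller's RNG state.
* Test and acceptance problem sizes: 12-window sessions (4 quadrant
  segments × 3 windows) for recovery, 20 replicates; a 64-window
  training session for the baseline; 10,000 random tuples for the
  rule-engine equivalence; 1,000 random interval lists for the BpNN50
  oracle. These sizes give stable statistics while keeping the full
  suite in tens of seconds.

## Limitations

The rule tree is a hard-decision classifier: it has no confidence, no
probabilistic membership, and inherits the brittleness of its
calibration prefix — a prefix that never sees one level of a stream
leaves that stream's threshold pinned to clipped extremes. The
generator's quadrant signatures are the rules' own assumptions; real
elicited emotion will satisfy them only partially, and the reported
recovery rates should be read as verification of the machinery, not as
expected field accuracy.
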