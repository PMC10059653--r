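# affectstream

Streaming valence–arousal emotion judgment from peripheral biosignals,
for affective-computing and adaptive-interaction researchers who want a
transparent, auditable alternative to black-box classifiers.

Every 10 seconds, an electrodermal activity (EDA) window and a
pulse-wave (PPG) window are summarized into a handful of features —
the window range, the mean first-order difference
`1dmean = (1/(N−1)) Σ (x[i+1] − x[i])`, and the pNN50-style interval
statistic `BpNN50 = count(|IBI[i+1] − IBI[i]| > 50 ms)/(N−1)` — each
compared against its stream's adaptive normalized threshold

    x_th = mean( (x − x_min) / (x_max − x_min) )

frozen on a calibration prefix. A small rule tree then emits one of the
four valence–arousal quadrants per window: HANV (high arousal, negative
valence), LAPV, LANV, HAPV, or UNDECIDED. Around the judge, the package
provides:

* a labelled **synthetic-session generator** (per-beat PPG morphology
  with main wave / dicrotic anterior wave / dicrotic notch / dicrotic
  wave, EDA with controllable range, slope and extremum ordering);
* the **preprocessing chain**: hardware calibration
  `f(r) = r − ((2014 + 2r)·10000)/(512 − r)`, 3-level db4 wavelet
  denoising, zero-phase 10 Hz Butterworth low-pass
  (`H(D) = 1/(1 + (D/D0)^(2n))`), min–max normalization to 0–100;
* a **75-feature catalogue** (24 + 18 time-domain, 8 + 8
  frequency-domain, 7 + 10 physiological) and the **optimal-feature
  selection** procedure (PCA loading-weight threshold, then Pearson
  correlation with significance screening against the quadrants);
* an **SVM baseline** with a stratified 70/30 split and a scripted
  cross-subject comparison;
* the **game-adaptation policy** (HANV → reward bricks, LAPV → spawn
  monsters, LANV → new scene, HAPV → no action) with activation-count
  tables, including packaged reference tables from a ten-subject
  evaluation study.

## Worked example

```r
library(affectstream)

session   <- generate_session(default_scenarios(windows_per_segment = 3, seed = 7))
prep      <- preprocess_session(session)
decisions <- judge_session(prep)              # first 4 windows calibrate
cbind(decisions[, c("window", "quadrant", "branch")], truth = session$labels)
#>    window  quadrant branch truth
#> 1       0 UNDECIDED   <NA>  HANV
#> ...
#> 5       4      LANV  pulse  LANV
#> 6       5      LANV  pulse  LANV
#> 7       6      LAPV    eda  LAPV
#> 8       7      LAPV    eda  LAPV
#> 9       8      LAPV    eda  LAPV
#> 10      9      HAPV  pulse  HAPV
#> 11     10      HAPV  pulse  HAPV
#> 12     11      HAPV  pulse  HAPV
judge_accuracy(decisions, session$labels)
#> [1] 1
```

The first four windows only seed the per-stream thresholds (emitted as
`UNDECIDED`); every later window is judged, here all correctly against
the generator's ground truth. Each decision carries a `rule_trace` that
replays the comparisons that produced it.

Feature selection recovers the three features the rule tree runs on:

```r
sel <- select_features(extract_features(prep), session$labels)
all(c("ppg_bpnn50", "eda_range", "eda_1dmean") %in% sel$subset_final)
#> [1] TRUE
```

and sustained decisions map to game events:

```r
policy_step(decisions)$events
#>   step window quadrant         action persistence
#> 1    5      4     LANV      new_scene           1
#> 2    7      6     LAPV spawn_monsters           1
#> 3    9      8     LAPV spawn_monsters           3
```

(the second LAPV window sits in the one-window refractory period, so the
next monster wave fires at window 8).

A thin command-line wrapper ships under `inst/cli/`:

```sh
affectstream simulate --out session/ --seed 7
affectstream judge --session session/ --out decisions.csv
affectstream verify-tables
```

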