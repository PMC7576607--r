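---
title: "Detecting deep breaths and breathing bursts in resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting deep breaths and breathing bursts in resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respfmri)
```

## The problem

Healthy adults lying at rest do not breathe like metronomes. Two departures
from eupnea (normal tidal breathing) recur in long resting-state fMRI
sessions:

* **Deep breaths (sighs)** — isolated breaths much larger than their
  neighbors, often followed by a brief central apnea of up to ~20 s.
* **Bursts** — trains of cycles in which breathing depth swells and then
  tapers serially to shallow breaths, each cycle lasting roughly 30–50 s,
  with trains spanning minutes; the pattern resembles periodic breathing.

Both patterns perturb arterial CO~2~ and hence cerebral blood flow, which
imprints them on the fMRI signal: a sigh produces a brief global signal
rise followed by a marked trough with nadir near 15 s and resolution by
about 30 s; a burst cycle produces a larger, later peak and a prolonged
trough resolving near 40 s. Because these responses are global and are
loaded most strongly onto sensorimotor cortex (visual, auditory, motor,
somatosensory), they inflate functional-connectivity estimates — global
connectivity most of all — and they do so differentially across people:
bursts are more prevalent in male scans (~45% vs ~35% of female scans),
so breathing can masquerade as a sex difference in connectivity.

`respfmri` implements the full analysis chain for this problem: cleaning
and summarizing the physiological recordings, the fMRI-side quality
series, an automated index of each breathing pattern per scan,
event-locked and connectivity statistics, and cohort-level models — plus
a ground-truthed synthetic-data generator so that every stage is testable
without access to any imaging repository.

## Respiratory measures

The respiratory belt trace (400 Hz, arbitrary units) is cleaned in a
fixed order: spike-artifact replacement (moving-median outlier filter,
100-sample window, 3 scaled MADs, linearly interpolated), gentle local
quadratic (Savitzky–Golay) smoothing over 1 s, then z-scoring. The
outlier filter iterates detection and replacement to a fixed point, so
re-cleaning a cleaned trace changes nothing.

Three standard measures are derived from the cleaned trace:

* **ENV** — sliding-window RMS envelope over 10 s;
* **RV** — sliding-window standard deviation over 6 s;
* **RVT** — per breath, (peak − preceding trough) / (inter-peak
  interval), with peaks and troughs from prominence-based detection
  (prominence ≥ 0.5 z, spacing ≥ 2 s, presuming breaths more than 2 s
  apart); a peak without an interceding trough is left unscored.

The three measures move together during bursts but dissociate at sighs: a
slow deep breath scales amplitude and period together, and RVT — a
depth-per-time ratio — is invariant to co-scaling, while ENV and RV grow
with amplitude. The generator reproduces this by stretching the implanted
sigh's period by the same factor as its depth.

```{r rvt-dissociation}
hz <- 400
t <- (seq_len(240 * hz) - 1) / hz
base <- sqrt(2) * sin(2 * pi * t / 4)
coscaled <- 2 * sqrt(2) * sin(2 * pi * t / 8)
rvt_of <- function(x)
  mean(compute_rvt(x, detect_breaths(x, hz), hz)$peaks$rvt, na.rm = TRUE)
c(rvt_base = rvt_of(base), rvt_coscaled = rvt_of(coscaled))
```

Pulse oximetry is handled analogously (prominence ≥ 0.5 z, spacing ≥ 180
samples at 400 Hz — presuming heart rates under 133 bpm); heart rate is
60 over the inter-beat interval. Where the original workflow screened
cardiac traces visually, `cardiac_series()` adds an automated flag: a
scan is unreliable when more than 5% of inter-beat intervals fall outside
0.33–2 s.

## fMRI-side series

`scan_metrics()` derives, per frame: the global (gray-matter mean)
signal; DVARS (RMS across units of the backward temporal difference,
zero at the first frame by convention); and framewise displacement in
three variants — original (backward difference of the six rigid-body
parameters with rotations as 50 mm arc length), filtered (each position
trace band-stop filtered over 0.2–0.5 Hz, the tidal-breathing band, with
a zero-phase Butterworth filter of order 5 per pass; the filter family
and order are configuration choices, only the stopband edges are fixed),
and a 4-TR variant differenced over four frames (2.88 s at TR = 0.72 s)
for comparability with legacy slow-TR FD. Carpet (gray) plots stack the
physiological panels above per-unit z-scored rows ordered stably by
tissue compartment with symmetric display limits of ±2 z.

## The pattern index

The detector's architecture is fixed: a probability-like **prior**
derived from the belt trace for each pattern is multiplied, frame by
frame, by the rectified **template fit** of that pattern's global-signal
kernel, the product is averaged over the scan, and the result is
downweighted by the scan's breathing-rate variability; subject-level
indices are means over scans, and binarized calls summed over a
subject's four scans give a 0–4 pattern score.

The concrete constructions inside that architecture are this package's
own (the original's full recipe is not public), with every constant
exposed as an argument:

* **Deep-breath prior.** Each breath's prominence is compared with the
  local median prominence (±90 s). The excess ratio is mapped through a
  quartic saturating function reaching 0.5 at twice the local median, and
  damped when adjacent breaths are themselves enlarged (isolation term —
  this is what keeps burst breaths out of the sigh prior). The prior is
  flat from 6 s before the breath peak (covering the onset) and decays
  exponentially (τ = 4 s) over a 10-s support.
* **Burst prior.** The ENV is averaged to the frame grid and scanned
  with a 150-s window. Two statistics multiply: the modulation depth
  (window SD over window mean of ENV) and a periodicity score — the
  maximum over candidate periods of 25–70 s of a variance-balanced lagged
  autocorrelation *comb*, min(r(lag), r(lag) − r(lag/2)). Requiring
  positive correlation at the full lag *and* a trough at the half lag
  rejects both slow depth drifts (high r at all lags) and lone
  sigh-plus-apnea transients (one pseudo-cycle, no repetition). The
  balanced correlation normalizes by the larger of the two window
  variances so that a single large transient cannot probe noise in the
  lagged window at full Pearson scale. The product saturates at 0.5 when
  it reaches 0.15.
* **Templates.** Differences of two gamma densities parameterized to the
  timing landmarks above (sigh: positive lobe then trough at ~15 s,
  negligible past 30 s; burst: later, larger lobes, trough past 20 s,
  negligible past 40 s). The match is the sliding Pearson correlation of
  the kernel with the signal window starting at each frame, clamped at
  zero. Exact kernel shape is not critical: detection AUC stays above
  0.85 when every timing landmark is perturbed by ±20%.
* **Cross-pattern exclusion.** A deep breath is by definition an
  *isolated* large breath, so the sigh prior is gated to zero wherever a
  dilated copy of the burst prior (running max over ±45 s, linear
  ramp-down from 0, zero at 0.5) says a train is in progress. Without
  this, cycle-start breaths tower over the taper-depressed local median
  prominence and the sigh index tracks bursts instead of sighs; with it,
  the two indices are uncorrelated across scans, as the patterns
  themselves are.
* **Downweighting.** w = exp(−λ · max(0, CV − c~0~)) with λ = 5 and
  c~0~ = 0.15 on the coefficient of variation of inter-breath intervals;
  haphazard breathing (CV > 0.4) is discounted by more than 60%.
* **Thresholds.** Binarization thresholds are set where pattern-free
  synthetic scans show 5% index exceedance, since no human rater
  decisions exist for synthetic data.

These choices were calibrated once against the generator (separability
of implanted vs clean scans, specificity between patterns) and then
frozen; the tests assert the resulting behavior.

## The synthetic generator

`generate_cohort()` / `generate_scan()` emulate the statistical
structure the analysis assumes:

* Eupnea as trough-to-trough raised-cosine breaths; breath-to-breath
  log-normal period jitter (the inter-peak CV approximates the jitter
  parameter) and a slow AR(1) log-depth drift whose *stationary* SD is
  the drift parameter (defaults: jitter 0.06, drift 0.08 — a subject
  breathing tidily at 12–20 breaths/min).
* Implanted events edit the breath schedule and re-render, so traces
  stay continuous and the ground-truth log records exact onsets. Sighs
  co-scale depth and period (factor ~2–3) with 0–20 s apnea; bursts are
  2–5-minute trains of 30–50 s cycles whose per-breath depth tapers
  linearly (optionally exponentially) to 0.3× eupneic depth.
* Parcel signals (9 networks × 10 parcels by default) are AR(1) unit
  noise (ρ = 0.3) plus network-common and globally shared components,
  plus the event train convolved with the matching kernel, scaled by
  `gfc_coupling` and by `sensorimotor_gain` (default 2) on the
  sensorimotor networks. The globally shared component's SD shrinks with
  head size (−0.15 per ICV z-unit), encoding the head-size route to
  global connectivity.
* Pulse at a 60–80 bpm baseline with a +8 bpm exponential bump (τ = 5 s)
  after each sigh and none after bursts; motion as jitter and drift with
  a small spike at each sigh onset.
* Cohorts: Bernoulli per-scan pattern assignment at 45%/35% (bursts,
  male/female) and 53% (sighs), sex-specific ICV (1550/1350 ± 110 cm³).

What the generator does **not** emulate: real belt waveform morphology
(raised cosines, not pressure-transducer shapes), scanner drifts and
hardware artifacts, within-scan arousal-state changes, FIX-ICA residual
structure, voxel-level spatial autocorrelation, or any coupling between
breathing and motion beyond the sigh-onset spike. Passing tests
therefore demonstrate that the pipeline recovers the modeled structure —
not that it is robust to everything real data can do.

## Statistics

Event-locked analyses extract half-open windows of 30 s before to 60 s
after onsets (125 frames at TR = 0.72 s); onsets snap to the nearest
frame with ties toward earlier. Pointwise two-sample Welch tests against
random onsets color p < 0.001 on a log scale capped at 1e−10.
Event-window connectivity uses −10 to +40 s spans; matrices are averaged
in Fisher-Z and reported in r (correlations clipped to ±(1 − 1e−6)
before the transform).

gFC is the Fisher-Z of the median pairwise gray-unit correlation per
scan, averaged within subject. Cellwise group contrasts use label
permutation (default 10,000; exact enumeration replaces sampling when it
is cheaper) with add-one p-values, in |Δ| or signed-tail mode; a group's
matrices can also be ranked among random same-sized subject draws.
ANCOVA of gFC uses marginal (Type II) per-term F tests. The exact upper
binomial tail reproduces the sleep-list enrichment (15 of 21 at a 37%
base rate → p = 0.0014). The joint sex-composition probability is a
product of one-sided exact binomial tails directed at each group's
extreme; at male counts (6, 5, 14) of 21 and male fraction 228/440 it
evaluates to ≈2.9e−5, not exactly the 3.3e−5 sometimes quoted for this
configuration — the precise convention behind that figure (binomial vs
hypergeometric, tail handling) is ambiguous, so the package documents
the oracle it implements rather than forcing the number.

## Validation sizes and numerical choices

The packaged validation uses problem sizes chosen to exercise the study
conditions while staying desk-sized: detector calibration curves on
50 clean / 50 burst / 25 sigh scans; subject-level recovery on a
200-subject, 800-scan cohort (Spearman of implanted scan counts vs mean
indices ≥ 0.8 for bursts, ≥ 0.7 for sighs); null calibrations at
400–1000 replicates; sex-prevalence power over 20 study-sized cohorts.
At the study's ~1760 scans, the 45%/35% burst difference carries power
≈0.88 at α = 0.001 and ≈1 at α = 0.01; the package's acceptance check
uses α = 0.01, where the decision is stable across seeds.

Other numerical conventions: time is 0-based (sample i at i/fs; frame j
covers [j·TR, (j+1)·TR)); physiology is averaged within frames for any
frame-rate comparison; HCP-style motion files carry 12 columns of which
the first 6 are used, rotations read as degrees and stored as radians;
degenerate inputs (constant traces, too few peaks) flag rather than
error wherever an empty result is meaningful.

## Known limitations

* The priors/templates are a reconstruction of a published architecture,
  calibrated on synthetic data; on real recordings their constants (k,
  m~0~, λ, c~0~, windows) may need re-tuning against human ratings.
* Voxel-level workflows are supported only as flattened matrices against
  a mask; no volumetric smoothing or segmentation is performed.
* Cardiac analysis stops at peak timing and amplitude; no waveform
  morphology or frequency-domain HRV.
* The binarization thresholds are cohort-relative (clean-scan
  exceedance); absolute thresholds would require rater-calibrated data.
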