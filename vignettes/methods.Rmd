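---
title: "Single-beat nearfield/farfield discrimination: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-beat nearfield/farfield discrimination: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During pulmonary vein isolation (PVI) for atrial fibrillation, the
procedural endpoint is the disappearance of the local pulmonary-vein (PV)
electrogram on a circular mapping catheter (CMC) placed in the vein. The
bipolar voltage electrogram (BVE) on each of the catheter's eight bipoles,
however, superimposes two sources: the *nearfield* (NF) — sharp,
high-frequency depolarization of the myocardial sleeve directly under the
bipole, the ablation target — and the *farfield* (FF) — broader,
low-frequency activity conducted from the atrium and neighbouring
structures such as the left atrial appendage (LAA). When the two overlap
in time, deciding from a single beat whether a nearfield component is
still present is hard even for experienced readers, yet it determines
whether further ablation is needed.

`pvnf` implements a single-beat classifier for this decision: six
features computed from one annotated beat across the eight bipoles, four
spectral and two temporal, feeding standard classifier families under a
patient-level validation design. A synthetic CMC simulator with the same
statistical structure makes the entire pipeline testable without clinical
recordings.

## Signal model and acquisition chain

Recordings are modelled at 2000 Hz sampling with the clinical filter
chain: a 30–300 Hz band-pass and a 50 Hz mains notch. The package
realizes these as a 4th-order Butterworth band-pass plus a biquad notch
(quality factor 30), each applied forward–backward. Zero-phase filtering
matters here because two of the features (slew-rate proportion, onset
morphology of the sharp NF transient) would be distorted by the group
delay of a causal filter. If the low-pass edge reaches the Nyquist
frequency the band-pass degenerates to the corresponding high-pass.

Noisy beats are discarded before feature extraction by comparing the RMS
of a reference window immediately preceding the beat (before the P-wave)
with the RMS of the beat itself, per channel. The defaults — a 50 ms
reference window and a maximum baseline/beat RMS ratio of 0.2, with a
beat rejected only when *every* channel fails — are package choices: the
clinical criterion is qualitative, and since feature extraction later
retains a single best bipole, one clean channel is enough to keep a beat.
The comparison is strict (a ratio exactly at the threshold is accepted)
and scale-invariant.

## The six features

Spectral features come from a short-time FFT: a 35 ms window slides in
5 ms steps across the annotated beat, each window zero-padded to
`fs / 10 Hz` = 200 samples so the frequency grid has exactly 10 Hz
spacing. Windowed power is summed below and above a 150 Hz split:

* `p_lf` — power in [0, 150) Hz, dominated by atrial farfield;
* `p_hf` — power in [150, 300] Hz, dominated by PV nearfield;
* `p_hf_rel` — `p_hf` relative to total 0–300 Hz power;
* `p_hf_neighbor_ratio` — `p_hf` of the retained bipole over that of its
  two ring neighbours, keeping the larger ratio. A truly local source
  decays steeply around the loop; a distant one illuminates the whole
  ring evenly.

Per channel, the sliding windows are aggregated by their maximum `p_hf`
(the sharp NF transient contributes wherever it occurs within the beat),
and the bipole with the highest channel-level `p_hf` is retained —
closest pair to the NF source. `p_lf` and `p_hf_rel` are read at that
same maximizing window; whether these should instead be aggregated
separately is underdetermined, and "same window" is fixed here as the
simpler, internally consistent convention. Ties in the argmax break to
the lowest bipole index. Band edges follow the convention that the bin at
exactly 150 Hz belongs to the high band and the 300 Hz bin is included;
some convention is required on a 10 Hz grid and this one is asserted by
tests. Zero neighbour powers (possible in noiseless synthetic data) are
floored at 1e-12 mV² to keep the ratio finite.

The temporal features are computed on the retained bipole:

* `v_max` — peak-to-peak amplitude within the beat window. "Amplitude"
  alone is ambiguous; peak-to-peak is the EP-lab convention for bipolar
  voltage and is the definition used throughout.
* `slew_rate_prop` — the proportion of beat samples whose first
  derivative exceeds 0.15 V/s in magnitude. The derivative uses central
  differences (one-sided at the endpoints), with the mV-scale signal
  converted to volts.

The default taper is rectangular — the window is defined by its width
only — with a Hann taper available by configuration.

## Classification and validation

Electrogram powers and amplitudes are heavily right-skewed, so features
whose training-set skewness exceeds 1 in absolute value are
log-transformed (`log(x + 1e-12)`, only for non-negative features)
before z-scoring; the transform is frozen on training rows and embedded
in the model. Four classifier families are provided — CART decision tree
(depth 4), linear discriminant analysis, linear-kernel SVM (C = 1), and
KNN (k = 5) — with the SVM on (`p_hf`, `v_max`) as the reference
two-feature model. The binary target is the *presence of a nearfield
component*: beats labelled PV-NF or combined FF-NF are
nearfield-positive, pure atrial-FF beats negative. A beat that is pure
PV-NF cannot occur after isolation, and the annotation reader enforces
this.

Validation splits *patients*, never beats: 25% of patients form a
holdout set, the rest are cross-validated in 4 patient-grouped folds,
and the report is computed on holdout predictions (a pooled
cross-validation mode is also provided and labelled, since either could
be meant by an overall accuracy figure). Forward feature selection is a
greedy wrapper on cross-validated accuracy with a 0.5-percentage-point
stopping improvement. The ROC/AUC is the rank statistic (ties averaged),
with a 95% percentile bootstrap over 1000 class-stratified beat
resamples; the interval is widened, if necessary, to contain the point
estimate, which a finite percentile bootstrap does not otherwise
guarantee.

## The synthetic simulator

Each electrogram component is a Gabor atom — a Gaussian-envelope
sinusoid, the simplest waveform reproducing the characteristic bimodal
spectrum of superimposed FF and NF. Defaults: farfield at 80 Hz lasting
70 ms at 0.3 mV on all bipoles with mild ring decay (0.95/step);
nearfield at 220 Hz lasting 58 ms at 0.5 mV on one active bipole with
steep decay (0.4/step); combined beats delay the nearfield by 36 ms,
giving an annotated duration of about 94 ms. These durations match the
class-wise medians the annotation model assumes (58/70/94 ms). White
noise at 0.02 mV RMS and a 0.01 mV mains component are added. The RNG
draw order is class-independent, so the model is exactly additive under
a shared seed, and datasets use per-patient substreams derived from one
master seed.

Freeze-cycle recordings emulate the cryoballoon endpoint: combined beats
whose NF delay grows beat by beat, then pure atrial-FF beats from the
isolation index on.

Two difficulty regimes are fixed:

* **separated** — the defaults above; `p_hf` alone is nearly decisive.
* **overlap_heavy** — the hard regime: NF amplitude reduced to 0.2 mV
  and superimposed at zero delay; a broad per-beat contact gain
  (log-normal, sdlog 0.7) multiplying *all* components at once; and 55%
  of farfield beats carrying a sharp 210 Hz component (0.15 mV, 35 ms)
  with jittered FF centre frequency. The last ingredient models the
  close-LAA situation in which farfield spectra genuinely reach into the
  high band; the shared gain models variable catheter contact, which
  scales the whole electrogram. Together they give `p_hf` alone an AUC
  below 0.9 while leaving amplitude information that a two-feature model
  can exploit — the single-feature/two-feature gap is structural, not a
  seed accident, because the gain confound is removable through `v_max`.

These parameters were fixed once to realize the two regimes and are not
free knobs of the experiments built on them. What passing tests on this
generator do show: the spectral engine, selection logic, validation
design and the relative value of the feature sets behave as designed
under the stated morphology. What they do not show: clinical performance
— real electrograms carry fractionation, pacing artefacts, respiration
drift, rhythm variability and inter-patient morphology differences that
no Gabor-atom model reproduces, and the clinical headline numbers come
from recordings that are not publicly available.

## Numerical and design choices

* Milliseconds map to samples half-open (`floor(onset·fs/1000)`
  inclusive to `ceil(offset·fs/1000)` exclusive), so adjacent windows
  never share a sample.
* Recording channel order *is* catheter adjacency, circularly closed;
  the bipole wiring of the clinical catheter is not otherwise specified.
* Beats shorter than the 35 ms analysis window get a single zero-padded
  window; segments shorter than 3 samples cannot support a derivative
  and are errors.
* CSV fixtures print doubles at 17 significant digits and are written in
  binary mode with fixed newlines, making writes byte-stable; the EDF
  writer quantizes to the 16-bit grid, so its round trip is exact only
  to that step.
* The EDF reader/writer is a minimal implementation of the fixed-layout
  EDF header plus 16-bit little-endian records, sufficient for
  single-record interchange of CMC blocks.
* Problem sizes in the shipped tests and the acceptance script — 320
  beats (32 patients) for the separated regime, 400 (40 patients) for
  overlap-heavy — are chosen so that holdout accuracies and AUCs are
  stable to a few percent while a full run stays under a minute per
  regime; the chance level under label permutation is reported as the
  mean over five permutation/split repeats because a single 160-beat
  holdout draw has a standard deviation of about 4 points.

## Known limitations

Beat onsets/offsets are inputs, not detected; AF-rhythm beats are out of
scope (the model targets sinus rhythm); no probability calibration is
attempted; the LAA–LSPV distance is carried as optional metadata for
stratified reporting only. The noise-gate statistic and its defaults,
and the per-channel versus per-beat gating rule, are package conventions
for a qualitatively stated criterion and are exposed in configuration.
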