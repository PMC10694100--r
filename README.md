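# pvnf — single-beat discrimination of pulmonary-vein nearfield from atrial farfield electrograms

During pulmonary vein isolation (PVI) for atrial fibrillation, the endpoint
of the procedure is the electrical disappearance of the local pulmonary-vein
(PV) potential on a circular mapping catheter (CMC) placed in the vein. Each
bipolar voltage electrogram (BVE) on the catheter's eight bipoles
superimposes a sharp, high-frequency **nearfield** (NF) component from the
myocardial sleeve under the bipole — the ablation target — and a broader,
low-frequency **farfield** (FF) component conducted from the atrium and
neighbouring structures. When the two overlap in time, deciding from a
single beat whether a nearfield is still present is difficult, and the
answer determines whether further ablation is needed.

`pvnf` implements an automatic single-beat classifier for this decision,
for electrophysiologists and biomedical signal-processing researchers:

- **Acquisition chain** — zero-phase 30–300 Hz Butterworth band-pass plus a
  50 Hz notch (Q = 30), and an RMS noise gate on a pre-P-wave reference
  window.
- **Six features per beat** — from a sliding 35 ms zero-padded FFT with a
  10 Hz grid, the spectrum is split at 150 Hz into the power pair
  P<sub>LF</sub> = P[0, 150) Hz and P<sub>HF</sub> = P[150, 300] Hz; plus the
  relative high-band power P<sub>HF</sub>/(P<sub>LF</sub>+P<sub>HF</sub>), the
  high-band ratio to the two ring-neighbour bipoles
  max(P<sub>HF</sub>/P<sub>HF,left</sub>, P<sub>HF</sub>/P<sub>HF,right</sub>),
  the peak-to-peak amplitude V<sub>max</sub>, and the proportion of beat
  samples with |dV/dt| > 0.15 V/s. Of the eight bipoles, the one with the
  highest P<sub>HF</sub> is retained — the pair closest to the NF source.
- **Classification** — decision tree, LDA, linear SVM and KNN with
  skewness-corrected (log + z-score) normalization, greedy forward feature
  selection, patient-level 25% holdout with 4-fold patient-grouped
  cross-validation, and rank-statistic AUC with a stratified bootstrap CI.
  Nearfield presence is the positive class: PV-NF and combined FF-NF beats
  count as positive, pure atrial-FF beats as negative.
- **Synthetic CMC simulator** — Gabor-atom beats of all three classes with
  realistic durations (58/70/94 ms), spectral separation (220 Hz NF vs
  80 Hz FF), spatial decay around the catheter ring, cryoballoon
  freeze-cycle delay/disappearance sequences, and two difficulty regimes
  (`separated`, `overlap_heavy`).

Recordings are read from EDF or a diff-able CSV+JSON dialect; annotations,
feature tables, models, and reports use plain CSV/JSON.

## Worked example

```r
library(pvnf)
set.seed(42)

# one synthetic combined FF-NF beat, filtered, all six features
g  <- generate_beat("combined")
fv <- extract_feature_vector(apply_standard_filters(g$recording), g$beat)
print(fv[, 1:8], digits = 3)
#>   p_hf   p_lf p_hf_rel p_hf_neighbor_ratio v_max slew_rate_prop
#> 1  4.5 0.0174    0.996                7.09 0.832          0.224
#>   selected_channel duration_ms
#> 1                1         102
```

The beat's high band dominates its spectrum (`p_hf_rel` 0.996), the
high-band power on the retained bipole is 7.1 times that of its stronger
ring neighbour (a local source), and 22% of samples exceed the 0.15 V/s
slew threshold — all signatures of a nearfield component within this
102 ms beat.

```r
# full pipeline: simulate -> extract -> patient-level validation
d <- file.path(tempdir(), "demo")
generate_dataset(d, n_patients = 20, beats_per_patient = 10, seed = 42)
ds  <- load_dataset(d)
tab <- extract_feature_table(ds$recordings, ds$beats)
run_validation(tab, "svm", c("p_hf", "v_max"), scheme = list(seed = 42))
#> Single-beat nearfield/farfield classification (svm on p_hf + v_max; holdout predictions)
#>   beats: 50 from 5 patients
#>   confusion (nearfield positive): TP=27 FN=0 FP=0 TN=23
#>   accuracy 100.0%  sensitivity 100.0%  specificity 100.0%
#>   AUC 1.000 (95% CI 1.000 to 1.000)
#>   cross-validated accuracy (training patients): 100.0%
#>   per-vein accuracy:
#>     LIPV: 100.0% (n=20)
#>     LSPV: 100.0% (n=10)
#>     RIPV: 100.0% (n=10)
#>     RSPV: 100.0% (n=10)
```

On the default well-separated regime the two-feature SVM classifies the
held-out patients perfectly; the `overlap_heavy` regime (undelayed weak
nearfield, variable contact gain, high-frequency farfield contamination
from a close left atrial appendage) is where the two-feature model shows
its value over the single best feature. See `vignettes/methods.Rmd` for
the model, parameter meanings, and the simulator's scope.

A thin command-line wrapper is installed at `inst/cli/pvnf.R`:

```sh
Rscript inst/cli/pvnf.R simulate   --out data/demo --seed 1
Rscript inst/cli/pvnf.R extract    --dataset data/demo --out data/features.csv
Rscript inst/cli/pvnf.R train-eval --features data/features.csv --out data/eval
```

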