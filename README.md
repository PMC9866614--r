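# edafreq

Stress detection from wrist-measured electrodermal activity (EDA) using
frequency-spectrum features.

Consumer wearables measure skin conductance at low rates — the Empatica
E4 wrist band samples EDA at 4 Hz — and the practical questions for
on-wrist stress detection are (1) how accurately stress can be separated
from non-stress states and (2) how quickly a detection can be made after
stress onset (the time to detection, TTD). `edafreq` implements a
feature-extraction and evaluation pipeline built around multi-band
analysis of the segment amplitude spectrum, for researchers in affective
computing and wearable signal processing who want a reproducible,
dependency-light reference implementation that runs on labelled EDA from
any source (including the public WESAD dataset, via an optional adapter)
or on its own synthetic cohorts.

## Method

A labelled conductance recording is cut by a sliding window (length
`t_length`, step `t_step = t_length − t_overlap`, in samples) into
segments that each contain a single affective state — windows spanning a
state transition are rejected. Each segment `x(k)`, `k = 0..N−1`, is
mean-centred and transformed with the unnormalized DFT

    X(f) = Σ_k x(k) · e^(−i2πfk/N),

keeping the one-sided magnitudes `|X(f)|` over bins `0..N/2` (resolution
`1/(t_s N)` Hz). For each of `m` frequency bands `[f_low, f_high)` —
default 0–1 Hz and 1–2 Hz — three features are computed over the `N_b`
in-band bins: the mean, the sample standard deviation (divisor
`N_b − 1`), and the maximum of `|X(f)|`. A fourth, band-independent
feature is the half-energy frequency `f_P/2`: with energy density
`Ψ(f) = |X(f)|²` and normalized cumulative sum `Ψ∫(f)`, it is the
smallest bin frequency with `Ψ∫(f) ≥ 0.5`. That gives `3m + 1` base
features per segment.

Sequence analysis then slides a window of `w` consecutive same-state,
same-subject segments over the feature series and appends each feature's
windowed mean `M_w` and population variance `V_w` (divisor `w`), tripling
the feature count to `3(3m + 1)` — 21 features for the default two bands.

Classifiers (decision tree, 1-NN/10-NN, random forests, RBF SVM, bagged
SVM, AdaBoost over random forests — deliberately untuned) are scored
under leave-one-subject-out (LOSO) cross-validation: accuracy
`(TP+TN)/total` and F1 `2TP/(2TP+FP+FN)` (stress positive; macro for the
three-class task), averaged unweighted over held-out subjects. Each
decision consumes `w` segments, so its detection latency is

    TTD = t_length + (w − 1) · t_step   [seconds].

The headline configuration — 48-sample windows (12 s at 4 Hz), 20-sample
overlap (7 s step), `w = 7` — detects in 54 s.

A built-in generator (`simulate_cohort()`) produces labelled multi-subject
cohorts from the standard electrodermal model (Poisson trains of
bi-exponential skin-conductance responses on a drifting tonic level) with
class-dependent spectral structure, so the entire pipeline is testable
without downloading anything.

## Worked example

```r
library(edafreq)

cohort <- simulate_cohort(generator_params(n_subjects = 6, seed = 1))
feats  <- build_feature_table(cohort, w = 7)   # 1152 rows x 24 cols
report <- loso_evaluate(feats, classifier_spec("knn", k = 10, seed = 0),
                        task = "binary", ttd_seconds = 54)
summary(report)
#> <loso_report> binary task, 6 subjects (knn)
#>   time to detection: 54 s
#>   averaged accuracy 0.9679, F1 0.9627
#>   per subject:
#>  subject n_train n_test  accuracy        f1
#>  synth01     960    192 0.9791667 0.9746835
#>  synth02     960    192 1.0000000 1.0000000
#>  synth03     960    192 0.9843750 0.9811321
#>  synth04     960    192 0.9375000 0.9277108
#>  synth05     960    192 0.9791667 0.9750000
#>  synth06     960    192 0.9270833 0.9176471
```

Each row of `feats` is one decision point: the current segment's 7
spectral features plus their windowed mean and variance over the last 7
segments (21 feature columns after the 3 metadata columns). The report
shows, per held-out subject, how well a 10-NN classifier trained on the
other five subjects separates stress from non-stress, and the averaged
scores; the synthetic classes are built to be separable, so accuracies
near 1 indicate correct pipeline wiring, not performance on real data.

A command-line front end wraps the same functions:

```sh
EXE=$(Rscript -e 'cat(system.file("exec", "edafreq", package = "edafreq"))')
Rscript $EXE simulate --subjects 6 --seed 1 --out cohort/
Rscript $EXE extract  --input cohort --format csv --w 7 --out features.csv
Rscript $EXE evaluate --features features.csv --task binary \
                      --classifier knn10 --report report.json
```

## Scope

The package extracts features and evaluates classifiers; it does not
tune hyperparameters, decompose EDA into tonic/phasic components, or
process chest-sensor modalities. The WESAD adapter
(`read_wesad_subject()`) reads the dataset's per-subject pickle records
when the data are present locally; no downloader is included.
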