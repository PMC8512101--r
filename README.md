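# semgfatigue

Muscle-fatigue recognition from surface electromyography (sEMG) in R:
wavelet-packet threshold denoising, windowed fatigue-feature extraction,
and recurrent classification, with a seeded synthetic sEMG generator so
the whole chain is testable without laboratory recordings.

## What it does, and for whom

During sustained exercise a fatiguing muscle's sEMG grows in amplitude and
its power spectrum shifts toward low frequencies. This package is for
researchers and engineers in biomechanics, sports science and
physiological signal processing who want to detect that transition
automatically from single- or multi-channel sEMG sampled at ~2000 Hz. It
provides the three stages of the standard recognition chain, each usable
on its own:

**1. Denoising.** The signal is decomposed by an orthonormal wavelet-packet
filter bank (default `db45`, 4 levels), pruned to the minimum
Shannon-entropy *best tree* (a node `N1` splits into `N2`, `N3` iff
`E(N2) + E(N3) < E(N1)` with `E(s) = -Σ s_i² log s_i²`), and each leaf's
coefficients are shrunk with one of three threshold functions. Besides the
classical hard (keep-or-kill) and soft (shrink-or-kill) rules, an improved
function interpolates smoothly between them:

```
ŵ = w − m·w / (1 + log(|w|/λ))                              |w| ≥ λ
ŵ = (1−m)·sign(w)·|w|^(k+1)·(1 − log(|w|/λ)) / λ^k          0 < |w| < λ
```

continuous at λ (both branches equal `(1−m)λ` there), nearly identity for
large `|w|`, with tunable `k ∈ ℕ`, `m ∈ (0,1)`. Per-leaf thresholds come
from a heuristic SURE-style risk minimized over the sorted squared
coefficients; denoising quality is scored by SNR (dB) and RMSE against a
clean reference.

**2. Features.** A 2-s moving window yields RMS and integrated EMG (time
domain) plus median frequency (MF) and mean power frequency (MPF) of the
periodogram `P(f) = |X(f)|²/L` over a configurable 10–500 Hz band.
Windows are labelled fatigue/non-fatigue by a boundary time (in the lab:
the anaerobic threshold; in simulation: generator ground truth).

**3. Classification.** Ordered 5-window feature sequences feed an LSTM
(standard forget/input/output-gate equations, implemented in-package with
BPTT; 100 units, Adam, batch 70, lr 0.001, dropout 0.5, early stopping),
with CNN and Gaussian-kernel SVM baselines. Stratified 70/10/20 holdout;
confusion counts TF/TN/FF/FN give accuracy, sensitivity, specificity and
precision with fatigue as the positive class.

A synthetic generator (`generate_semg()`) produces band-limited shaped
noise whose spectral edge falls and amplitude rises across a labelled
fatigue boundary, plus white noise at an exact requested input SNR — the
study conditions under which the package validates itself.

## Worked example

```r
library(semgfatigue)

gt <- generate_semg(synth_config(seed = 1))
#> <semg_ground_truth> 120.0 s @ 2000 Hz, fatigue onset 60.0 s, input SNR 5 dB

dn <- wp_denoise(gt$noisy, threshold_config("improved"))
snr_db(gt$clean, dn$signal)    # 5.81 dB, up from the 5 dB input
# hard and soft thresholding give 4.56 and 2.61 dB on the same record

fm <- extract_features(dn$signal, window_spec(), band_spec(10, 500),
                       at_time_s = gt$at_time_s)
aggregate(cbind(rms, mf_hz) ~ label, fm, mean)
#>         label       rms    mf_hz
#> 1     fatigue 0.7779151 205.5220
#> 2 non-fatigue 0.6559428 241.5038

ds <- features_to_dataset(fm, seq_len = 5)
#> <labeled_dataset> 12 sequences (6 fatigue / 6 non-fatigue), 5 steps x 4 features
```

The feature table shows exactly the physiology the classifier exploits:
median frequency drops by ~36 Hz and RMS rises by ~19% after the fatigue
boundary. With several records pooled (see `run_pipeline()`), a stratified
split and `train_lstm()` recover the labels with high accuracy
(`evaluate_model()` prints the confusion counts and the four metrics).

## Command line

A thin wrapper over the same functions lives at `inst/cli/semgfatigue.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","semgfatigue.R", package="semgfatigue"))')" \
    simulate --seed 1 --out /tmp/run
# subcommands: simulate | denoise | features | train | evaluate | pipeline | benchmark
```

Configuration is YAML validated against `default_run_config()` (unknown
keys are rejected); `--print-config` dumps the effective configuration.

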