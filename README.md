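# myofatigue

Monitoring exercise-induced muscle fatigue from surface electromyography
(SEMG) and B-mode ultrasound image sequences, as a tested, reproducible R
pipeline. The package is written for movement-science and rehabilitation
researchers who need the full chain — denoising raw SEMG, extracting
fatigue features, classifying fatigue state, and quantifying muscle
morphology and texture from ultrasound — with every stage validated
against synthetic ground truth.

## What it computes

**SEMG denoising.** Wavelet-threshold denoising (db4, 4 levels) with
three shrinkage rules applied to the detail coefficients *w* at threshold
λ = σ̂·√(2 ln N), σ̂ = median(|d₁|)/0.6745:

- hard: keep *w* if |w| ≥ λ, else 0
- soft: sign(w)·(|w| − λ) if |w| ≥ λ, else 0
- improved (shape k): `w − sign(w)·k·λ^(k+1) / ((k+1)·|w|^k)` above λ,
  `sign(w)·|w|^(k+1) / ((k+1)·λ^k)` below — continuous at λ, between
  soft and hard above the threshold, tending to hard as k → ∞.

`denoise_benchmark()` scores the rules by SNR/RMSE against known clean
truth on seeded synthetic SEMG.

**Fatigue features.** Per window (1 s, 50 % overlap by default):
IEMG = ∫|x(t)|dt (mV·s), RMS = √(1/T ∫x²dt) (mV), and MPF — the spectral
centroid ∫f·PS df / ∫PS df of a Hann periodogram within 20–500 Hz.

**Fatigue classification.** An LSTM (one recurrent layer, 100 units,
Adam, lr 0.001, batch 70, early stopping) on the raw window, with SVM,
BPNN and 1-D CNN baselines; stratified 7:3 train/evaluation split;
accuracy, sensitivity, specificity, precision from the confusion matrix.

**Ultrasound analysis.** Normalized cross-correlation block matching to
track an ROI through a frame sequence; muscle thickness from boundary
rows (surface/deep/total, mm); gray-level co-occurrence texture features
ASM = ΣU², Contrast = Σ(i−j)²U, HOM = ΣU/(1+(i−j)²).

**Synthetic ground truth.** Generators for band-limited fatiguing SEMG
(controllable RMS and MPF ramps, white/power-line/baseline contamination)
and layered Rayleigh-speckle phantoms (known boundary depths, per-frame
displacement, controllable texture grain), so the entire pipeline runs
and is tested with no external data.

## Worked example

```r
library(myofatigue)

# a 60 s fatiguing recording: RMS ramps 0.5 -> 1.5 mV, MPF stays at 80 Hz
clean <- generate_clean_semg(
  fatigue_profile(duration_s = 60, rms_start = 0.5, rms_end = 1.5),
  seed = 1)
noisy <- add_noise(clean, noise_spec(seed = 2))$noisy
den   <- denoise_semg(noisy, mode = "improved", k = 2)

feats <- compute_feature_series(den)
head(feats, 3)
#> # A tibble: 3 x 4
#>   t_start_s iemg_mVs rms_mV mpf_Hz
#>       <dbl>    <dbl>  <dbl>  <dbl>
#> 1       0      0.299  0.395   58.2
#> 2       0.5    0.297  0.392   58.9
#> 3       1      0.322  0.419   51.0
cor(feats$rms_mV, feats$t_start_s)
#> [1] 0.9879552
```

The RMS trajectory climbs almost monotonically with time (correlation
0.99) while MPF stays flat apart from window-to-window jitter — the
signature separating amplitude-driven fatigue progression from spectral
drift. (Denoising shrinks some genuine high-frequency content along with
the noise, so the post-denoising centroid sits below the 80 Hz synthesis
target; what matters for fatigue monitoring is that it does not trend.) Classifying
fatigued versus non-fatigued windows:

```r
ds <- generate_labeled_windows(200, window_len = 1000, seed = 3)
sp <- split_dataset(ds, 0.7, seed = 4)
lstm <- train_lstm(sp$train, lstm_config(max_epochs = 80, seed = 5))
evaluate_model(lstm, sp$eval)
#> <eval_metrics> acc 97.50% | sens 95.00% | spec 100.00% | prec 100.00% (tp 57 fp 0 tn 60 fn 3)
```

And the ultrasound arm on a moving phantom:

```r
ph  <- generate_phantom_sequence(
  phantom_spec(frame_displacement_mm = 1, n_frames = 6, seed = 6))
trk <- track_roi(ph, roi(40, 60, 40, 40), search_margin = 4)
all(trk$shift_row == ph$truth$shift_px)   # 2 px/frame recovered exactly
#> [1] TRUE
roi_texture(ph$frames[[1]], roi(40, 60, 40, 40))
#> # A tibble: 1 x 3
#>      asm contrast   hom
#>    <dbl>    <dbl> <dbl>
#> 1 0.0259     6.55 0.372
```

`run_semg_pipeline()` and `run_usbi_pipeline()` orchestrate these stages
end to end, writing feature/benchmark/metric tables plus a seeded,
config-hashed manifest; `group_compare()` supplies the Welch two-sample
test used for endpoint tables.

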