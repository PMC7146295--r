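# scgkit

Unsupervised heartbeat detection and morphology embedding for
seismocardiogram (SCG) signals.

An SCG is the vibration signal recorded by an accelerometer on the sternum:
every cardiac cycle leaves a burst of chest-wall oscillations tied to the
heart's mechanical events. `scgkit` finds and timestamps those heartbeats
directly in the accelerometer trace — no concurrent ECG is needed at run
time — and then compresses the segmented beat waveforms with a convolutional
variational autoencoder so that subject-specific morphology can be studied
by unsupervised clustering. ECG (with a Pan–Tompkins R-peak detector) enters
only as the benchmarking reference. The package is aimed at researchers in
cardiomechanical signal processing and unobtrusive vital-sign monitoring.

## The method in brief

**Detection.** The z-scored SCG `x_z = (x − μ_x)/σ_x` is squared and
convolved with an `M = 256`-tap, 2 Hz low-pass FIR to form an energy
envelope

    x_DET[n] = Σ_k b[k] · x_z²[n−k],

which an adaptive sliding-window threshold turns into a ±1 square wave
(`+1` where `x_DET(i) ≥ μ_{i:i−p} + k·σ_{i:i−p}`, trailing window `p = 30`,
multiplier `k = 2`). Envelope maxima around positive runs become candidate
beats; candidates must respect 400–1500 ms inter-beat intervals with < 30%
relative variation, and `k` is halved and the search retried when intervals
stay too long. The first 20 candidates are aligned by cross-correlation
within `±τ_S = ±s·sd(run lengths)` (`s = 3`) and their pointwise median
becomes the subject's beat template; every beat is then annotated at the lag
that maximizes the normalized cross-correlation between template and signal.

**Morphology.** Beats are cropped −100/+700 ms around each instant,
decimated to 200 samples, saturated to ±5 and offset to the 0–10 range. A
modular VAE — `Nconv` Conv-Stacks (two 1D convolutions + halving max-pool)
feeding dense mean/log-variance heads of `Ld` units, with an anti-symmetric
decoder — is trained to minimize reconstruction error plus the KL divergence
to an `N(0, I)` prior. k-means on the latent means is scored against subject
identity (adjusted Rand, adjusted mutual information, completeness,
homogeneity), and

    y_perf = β₀ + β₁·(√Ld − √2) + β₂·(Nconv − 1)

quantifies how latent size and depth drive clustering quality.

Everything is scriptable end-to-end on synthetic cohorts: the generator
produces multi-subject SCG + surrogate-ECG records with per-subject Gabor
atom morphologies, respiration drift, band-limited noise at a configurable
SNR, and exact ground-truth beat and R-peak instants.

## A worked example

```r
library(scgkit)

# a 5-subject synthetic cohort: 120 beats each at 500 Hz, 10 dB SNR
cohort <- simulate_cohort(simulation_config(
  n_subjects = 5, beats_per_subject = 120, fs = 500, snr_db = 10, seed = 17))

det <- detect_and_annotate(cohort$S01$record)
det
#> <scg_detection> subject=S01: 120 beats @ 500 Hz (k_used=2)
#>   C-C intervals: mean 854.3 ms, sd 39.2 ms

m <- match_beats(cohort$S01$truth_rpeaks_s, det$annotations)
detection_metrics(m)
#> # A tibble: 1 × 3
#>   sensitivity precision specificity
#>         <dbl>     <dbl>       <dbl>
#> 1           1         1           1

interval_errors(m)
#> <interval_error_report> n=119  mu_e=0.017 ms  sigma_e=1.438 ms  RMSE=1.432 ms  R2=99.87%
```

Sensitivity and precision are the fractions of reference beats found and of
detections that are true beats, scored with the 100 ms tolerance-window
protocol; the interval report compares consecutive beat-to-beat intervals
against the ECG reference — an RMSE of ~1.4 ms means the SCG-derived rhythm
tracks the electrical rhythm to well under a sample at 500 Hz.

```r
beats <- segment_cohort(cohort)
model <- train_vae(build_vae(vae_config(n_conv = 2, latent_dim = 8,
                                        epochs = 60, seed = 7)), beats)
test_rows <- model$split$test
codes <- encode_beats(model, beats$segments[test_rows, ],
                      subject_ids = beats$subject_ids[test_rows])
cluster_scores(cluster_latent(codes, seed = 7), codes$subject_ids)
#> # A tibble: 1 × 4
#>   adjusted_rand adjusted_mutual_info completeness homogeneity
#>           <dbl>                <dbl>        <dbl>       <dbl>
#> 1             1                    1            1           1
```

A score of 1 means k-means on the 8-dimensional latent means groups held-out
test beats exactly by subject: the VAE has learned the morphology without
labels. `autoplot()` methods exist for detections, Bland–Altman data, latent
codes, training trajectories and sweeps; `tidy()`/`glance()` methods cover
detections, the VAE fit and the architecture linear model.

A thin command-line interface mirrors the R API
(`inst/cli/scgkit simulate|detect|segment|train-vae|embed|cluster|evaluate|sweep`).

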