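# pcgfusion

Heart-sound (phonocardiogram, PCG) recordings carry diagnostic information
about valvular heart disease: the timing and intensity of the S1/S2 valve
sounds and, crucially, murmurs — band-limited noise between the heart
sounds whose frequency band and timing identify the lesion (aortic stenosis
100–450 Hz systolic, mitral regurgitation 45–160 Hz systolic, mitral
stenosis 40–95 Hz diastolic, mitral valve prolapse 45–90 Hz systolic).
pcgfusion is an R toolkit for building and evaluating a complete PCG
classification pipeline on such signals, exercisable entirely on synthetic
recordings, for researchers prototyping heart-sound analysis methods.

The pipeline, end to end:

1. **Synthetic PCG generation** — cyclic S1/S2 tone bursts plus
   disease-specific band-limited murmurs at configurable SNR, with WAV and
   manifest I/O (`simulate_dataset()`, `read_wav()`).
2. **Denoising** — ensemble empirical mode decomposition (EEMD) with exact
   reconstruction `x = Σ IMF_k + residual`, rejection of noise-dominated
   leading IMFs by a stationarity test, and an adaptive least-mean-squares
   canceller `w ← w + μ e[n] u[n]` with stability bound
   `μ_max = 2/(3 L P_ref)` (`denoise_pcg()`).
3. **Features** — Shannon-energy envelope `-x² log x²`, S1/S2 cycle
   segmentation, murmur-band Welch power fractions, delta/theta
   envelope-modulation powers, systolic/diastolic timing statistics
   (`extract_features()`).
4. **Rebalancing** — SMOTE: synthetic minority rows `x + α(x' − x)`,
   `α ~ U(0,1)`, `x'` among the k nearest same-class neighbours
   (`smote_oversample()`).
5. **Impact scoring** — the soft-margin hyperplane objective
   `I_R = ½‖s‖² + C Σ ξ` solved by deterministic SMO; per-feature impact
   `|s_j|·sd(X_j)` (`fit_hyperplane()`, `feature_impacts()`).
6. **Feature selection** — linear-vectored particle swarm optimization:
   acceleration coefficients drawn in [0, 2] and classed low/medium/high,
   inertia 0.9/0.65/0.4 by the opposing rule, fitness = held-out error of
   an LVQ1 classifier with information-gain-weighted distances
   (`select_features()`).
7. **Classification** — a first-order Sugeno fuzzy inference system
   (product firing, normalization, linear consequents, hybrid
   least-squares + gradient learning) produces a fuzzy risk score fused
   into a small 1-D separable-convolution network
   (conv5 → BN → ReLU → pool → sepconv3 → BN → ReLU → pool → GAP →
   ⊕ risk score → dense → dropout → softmax), trained with Adam on
   cross-entropy with hand-verified analytic gradients
   (`fis_train_hybrid()`, `xcnn_train()`).
8. **Evaluation** — confusion matrix, precision/recall/F1/accuracy,
   Cohen's kappa, macro AUC, polygon area metric, leakage-free stratified
   k-fold cross-validation (`cross_validate()`).

All tabular inputs and outputs are tibbles and chain with the pipe;
fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(pcgfusion)

# a small labeled dataset: 10 recordings per class at 15 dB SNR
ds <- simulate_dataset(sim_config(n_per_class = 10, snr_db = 15, seed = 42))
ds$recordings[[1]]
#> <pcg_recording> NHF_001  label=NHF  fs=4000 Hz  3.000 s (12000 samples)

# denoise a 0 dB recording and measure what it bought us
noisy <- simulate_recording("AS", sim_config(snr_db = 0, seed = 7),
                            return_parts = TRUE)
den <- denoise_pcg(noisy, eemd_config(n_trials = 4, noise_sd = 0.1, seed = 7))
clean <- attr(noisy, "clean")
round(c(snr_in = snr_db(clean, noisy$samples),
        snr_out = snr_db(clean, den$samples)), 2)
#>  snr_in snr_out
#>   -0.07    5.18
```

The denoiser lifted a 0 dB recording (noise as strong as the signal) to
+5.2 dB — about two thirds of the noise power removed while keeping the
heart sounds.

```r
feats <- extract_features(ds$recordings)
head(feature_impacts(feats), 5)
#> # A tibble: 5 × 3
#>   feature            score  rank
#>   <chr>              <dbl> <int>
#> 1 spectral_centroid 13.3       1
#> 2 sys_band_MR        0.539     2
#> 3 sys_band_MS        0.520     3
#> 4 sys_band_MVP       0.451     4
#> 5 sys_band_AS        0.397     5
```

The impact ranking puts the spectral centroid and the systole-restricted
murmur-band fractions on top — exactly the quantities that differ between
murmur classes.

```r
report <- cross_validate(feats, k = 2, seed = 42, n_particles = 8,
                         n_iter = 10,
                         xcnn = xcnn_config(epochs = 30, dropout = 0.2,
                                            batch_size = 8, seed = 42))
glance(report)
#> # A tibble: 1 × 6
#>   accuracy macro_precision macro_recall macro_f1 kappa jaccard
#>      <dbl>           <dbl>        <dbl>    <dbl> <dbl>   <dbl>
#> 1     0.98           0.982         0.98    0.980 0.975   0.962
```

49 of 50 held-out recordings are classified correctly (kappa 0.975 —
near-perfect chance-corrected agreement); `autoplot(report)` draws the
confusion matrix.

A command-line front end wrapping the same functions lives at
`inst/cli/pcgfusion.R` (subcommands `simulate`, `denoise`, `features`,
`select`, `evaluate`, `run`); `run_pipeline()` drives the whole chain from
a YAML config and writes every artifact with a config hash.

## Documentation

The methods vignette (`vignettes/pcgfusion-methods.Rmd`) describes the
models, the tunable parameters with their defaults and units, the
numerical safeguards, what the synthetic generator does and does not
emulate, and the package's design choices where the underlying method left
them open.
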