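# usvnet

Mouse ultrasonic vocalizations (USVs) — short frequency-modulated
whistles between 25 and 125 kHz — carry information about the emitting
animal that simple acoustic summaries fail to expose: no single feature
separates, say, male from female calls, yet classifiers that can exploit
*combinations* of spectrotemporal properties recover the emitter's class
well above chance. `usvnet` is an R toolkit for exactly this analysis
chain, aimed at bioacousticians and neuroscientists working with 300 kHz
rodent recordings:

* **Segmentation** — the classical percentile/criteria extractor: 25 kHz
  Butterworth high-pass, magnitude spectrogram from 500-sample (1.67 ms)
  windows at 50% overlap (frame rate 1.2 kHz, 233 frequency rows at
  600 Hz spacing), sparsification below the recording-wide 70th
  percentile, three acceptance criteria (spectral energy above the
  99.8% quantile, spectral continuity of the peak track — accumulated
  displacement below 15 bins over ~3.3 ms windows — and energy-weighted
  mean frequency ≥ 25 kHz), merging of detections closer than 15 ms, and
  export as left-aligned 100×100 uint8 images truncated at 100 ms.
* **Features** — curvature-flow denoising, fundamental-frequency
  tracking `FF(t)` with break marking, and the formula-defined scalar
  suite on `S(f,t) = |STFT|²`: spectral width `max FF − min FF`,
  duration, Wiener entropy (geometric/arithmetic mean per frame),
  spectral purity (max/median), spectral salience and tremolo
  (off-zero vs zero-lag autocorrelation peaks), moments, direction, two
  mean-frequency estimates — assembled with three 1-D marginals into a
  457-dimensional extended vector (24 + 100 + 233 + 100).
* **Classifiers** — a from-scratch training engine (im2col+GEMM
  convolutions, batch-norm, dropout, Adam, Xavier init, class-weighted
  cross-entropy, on-the-fly augmentation) behind declarative
  architecture and protocol tables: the 6-conv/3-dense spectrogram
  network, the 4×70 dense feature network and the three-stream
  semi-convolutional network, plus ridge (direct normal equations) and
  SVM (quadratic/linear kernel) baselines, leave-one-subject-out and
  random-fold cross-validation, and shuffled-label chance controls.
* **Interpretation** — activation sparsity `1 − active/total`,
  within/across-class activation correlations, transposed-weight
  deconvolution (an exact adjoint on linear stacks), PCA and exact
  t-SNE embeddings, leave-one-out nearest-neighbour decoding and class
  density-difference maps.
* **A synthetic-USV generator** — class-conditioned call parameter
  distributions over a noise floor, including *relational* profiles
  whose class signal lives only in the combination of call parts — so
  every stage above is testable against known ground truth.

## A worked example

Generate a small labeled dataset, segment a rendered recording, and
extract features from one call:

```r
library(usvnet)
set.seed(1)

profs <- default_profiles()
specs <- lapply(1:20, function(i) sample_trajectory(profs[[1 + i %% 2]]))
onsets <- schedule_calls(vapply(specs, `[[`, numeric(1), "duration_ms"))
rec <- render_recording(specs, onsets, snr_db = 20)

seg <- segment_recording(rec)
segmentation_score(seg$segments, rec$annotations)
#> # A tibble: 1 × 6
#>   n_detected n_annotated matched precision recall    f1
#>        <int>       <int>   <int>     <dbl>  <dbl> <dbl>
#> 1         20          20      20         1      1     1

spec <- stft_magnitude(synthesize_call(specs[[2]]))
extract_features(spec)[, c("duration_ms", "mean_freq_ff_khz",
                           "spectral_width_khz", "direction",
                           "wiener_entropy", "n_breaks")]
#> # A tibble: 1 × 6
#>   duration_ms mean_freq_ff_khz spectral_width_khz direction wiener_entropy
#>         <dbl>            <dbl>              <dbl>     <int>          <dbl>
#> 1          50             83.4               22.8        -1       0.000340
#> # ℹ 1 more variable: n_breaks <int>
```

All 20 scheduled calls are recovered exactly at 20 dB SNR, and the
recovered features agree with the generated trajectory: call 2 was
drawn as a 51.6 ms down-sweep from 94.8 to 70.9 kHz, and the tracker
reports a 50 ms call of width 22.8 kHz around 83 kHz with direction −1
and no breaks. The near-zero Wiener entropy is the signature of a tonal
call — a pure whistle's spectrum is maximally far from flat.

Train the reduced spectrogram network on a nonlinear two-class problem
and compare it with the baselines:

```r
set.seed(42)
res <- classifier_ordering_experiment()
res
#> # A tibble: 6 × 3
#>   classifier labels   percent_correct
#>   <chr>      <chr>              <dbl>
#> 1 cnn        true               100
#> 2 svm        true                95.7
#> 3 ridge      true                62.7
#> 4 cnn        shuffled            54.0
#> 5 svm        shuffled            48.0
#> 6 ridge      shuffled            46.4
```

The class signal here is carried purely by the *relation* between the
two halves of each call (matched vs crossed frequency bands) plus a
small duration shift: the convolutional network exploits the
interaction almost fully, the quadratic-kernel SVM captures the
pixel-pair part of it, ridge regression sees only the marginal duration
leak, and every classifier collapses to within a few points of chance
when the training labels are shuffled (single control runs scatter
around 50% — see the methods vignette for why, and for how the network
control is variance-reduced).

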