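---
title: "Methods: segmentation, features and classifiers for mouse USVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, features and classifiers for mouse USVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Mouse ultrasonic vocalizations (USVs) are short (10-150 ms)
frequency-modulated whistles in the 25-125 kHz band, essentially free of
harmonics. `usvnet` implements a complete analysis chain for such
recordings: detection and extraction of single calls from continuous
300 kHz audio, a formula-defined acoustic feature suite, a family of
neural-network classifiers for the emitter's sex, strain or identity
with classical baselines, and analyses of what a trained network
represents. Because the interesting questions (does a segmentation
criterion do what it claims? does a classifier family order the way
theory predicts?) need ground truth that real recordings cannot supply,
the package ships a synthetic-USV generator as a first-class, tested
module; every quantitative claim in the test suite is made against that
generator.

## The synthetic generator

A call is specified as a trajectory: a piecewise-linear instantaneous
frequency path (optionally with a sinusoidal tremolo overlay), silent
break gaps of 2-12 ms, optional broadband content, and a relative
amplitude. Rendering is phase-continuous (`synthesize_call()`), so the
spectrogram ridge follows the specified path to within one frequency
bin. Broadband content is realized by amplitude-modulating the carrier
with low-pass noise, which spreads energy into a band of the requested
width around the instantaneous frequency without altering the ridge
position. Recordings (`render_recording()`) place calls on a schedule
over white Gaussian background noise at a stated SNR relative to the
mean call power; white noise is the simplest model consistent with a
close-to-silent high-frequency background. Two deliberate sources of
nuisance variation are built in: per-call amplitude jitter of
0.5-1.5x (the distance between a freely moving mouse and the microphone
is uncontrolled) and a default calling rate of roughly three calls per
second with 150-450 ms gaps, matching the 180-210 calls/min range
typical of resident-intruder recordings.

Class-conditioned parameter distributions live in `usv_profile`
objects. The default female/male pair applies modest, qualitative
effects (females slightly longer and higher, males wider-band, more
broadband and slightly quieter); the literature provides directions for
these differences but no usable per-class distributions, so the
magnitudes are configuration, chosen once to be plausible, and scaled
by a single `effect` knob. What the generator does *not* emulate -
vocal-fold physics, room acoustics, overlapping callers, the long-tailed
repertoire structure of real mice - bounds what passing tests show: they
certify the algorithms' contracts, not field performance on real
animals.

### The nonlinear (relational) profiles

`nonlinear_profiles()` exists to test interaction-sensitive
classification. Each call has two halves; each half is a sweep placed in
a low (40-60 kHz) or high (85-105 kHz) band, with independently drawn
centre, extent and direction. The first half's band is a fair coin; the
class controls only whether the second half *matches* or *crosses* the
first. Every marginal parameter distribution is therefore identical
across classes (verified by rank-sum tests at n = 2000 in the suite),
yet the joint configuration separates them perfectly.

The design is deliberately *relational* rather than a parameter-mode
parity (e.g. short-low vs long-high). With left-aligned time-frequency
images, any conjunction of duration and frequency is visible to a single
pixel - a pixel at (late time, high frequency) fires exactly for long,
high calls - so a mode-parity class would be linearly separable from raw
pixels and would defeat the purpose of the benchmark. Band parity of two
variably-placed parts is invisible to single-pixel statistics but lives
exactly in pixel *pairs*, i.e. in the span of a quadratic kernel, and is
learnable by a convolutional network.

`surrogate_profiles()` adds a 6 ms marginal duration shift on top
(against a per-call duration spread of roughly 8 ms). This mirrors the
empirical regime for spectrogram-based sex classification, where the
linear baseline sits just above chance rather than at it; without the
leak a linear classifier's accuracy is a coin toss around 50% and the
ordering comparison would be decided by noise.

## Segmentation

The extraction pipeline follows the classical percentile/criteria
design: a 4th-order Butterworth high-pass at 25 kHz (causal filtering;
the analytic magnitude at 10 kHz, about -32 dB, and at 60 kHz, within
1%, are asserted in the tests); a magnitude spectrogram from 500-sample
(1.67 ms) Hann windows with 50% overlap, giving the 1.2 kHz frame rate;
sparsification of everything below the recording-wide 70th percentile;
and three acceptance criteria - spectral energy (a frame is kept iff any
bin exceeds the recording-wide 99.8% quantile), spectral continuity (the
accumulated displacement of the per-frame peak over 4-step windows must
somewhere fall below 15 bins), and an energy-weighted mean frequency of
at least 25 kHz. Detections closer than 15 ms are merged (strictly
`<`), and each call is exported as a left-aligned 100 x 100 uint8 image,
truncated at 100 ms, with both axes rescaled by the common factor
100/233 so a call of N ms occupies `round(N * 100/233)` columns.

Choices the method description leaves open, decided here:

* **Window function**: Hann (standard for magnitude spectrograms);
  switchable to rectangular in `segmentation_config()`.
* **Frequency rows**: a 500-point transform has 251 non-negative bins;
  the top 233 (10.8-150 kHz at 600 Hz spacing) are kept, which both
  reproduces the canonical 233-row image height and discards rows the
  high-pass filter has emptied.
* **Candidate formation**: contiguous runs of energy-passing frames form
  candidates before the continuity and frequency criteria are applied;
  the criteria are independent predicates, so their order is
  irrelevant (asserted as a property test).
* **Single-frame candidates** pass the continuity criterion by
  convention (there is no displacement to accumulate).
* **Percentile convention**: inverse-ECDF (type 1), so on a matrix of
  distinct values exactly the bins strictly below the percentile value
  are zeroed.
* **uint8 mapping**: per-image linear scaling of `[0, max]` to 0-255.
* **Sparsification percentile**: exposed as one configurable number,
  default 70.

On synthetic recordings at the default calling rate, 200 calls at
20 dB SNR are recovered with F1 >= 0.9 against the generator's
annotations (match = at least half of the annotated call covered); the
continuity criterion is what rejects noise-only candidates, whose peak
track jumps wildly across bins. The energy criterion assumes call
energy is *rare* (top 0.2% of bins); at unrealistically dense calling
rates the recording-wide quantile climbs into the call-energy
distribution and quiet calls are missed, which is why the generator's
default schedule matters to the benchmark.

## Features

Feature formulas operate on the power spectrogram `S = |STFT|^2` of a
call patch, restricted to the band above 25 kHz. Before tracking, the
patch is denoised by a level-set min/max curvature flow (10 iterations,
dt = 0.075 by default - the step balances two competing demands: larger
steps erode the temporal tips and modulation apexes of the ridge and
fill short break gaps, biasing spectral width and break counts, while
smaller steps leave speckle behind): the image evolves by its level-line curvature,
with motion restricted so pixels brighter than their 3 x 3 surroundings
may only erode and darker ones only fill. Where the central-difference
gradient degenerates (isolated spikes, ridge crests) the curvature term
is continued as the smaller-magnitude Hessian eigenvalue, so a
single-bin speckle - curved in every direction - erodes within a few
iterations while a straight spectral ridge, flat along its length, is
preserved (the suite asserts >= 90% speckle-energy removal with the
ridge's peak track unchanged).

The fundamental line FF(t) is the frequency of the maximal bin in each
edge-bearing frame, where a Prewitt gradient map (threshold: four times
the mean gradient magnitude, the usual convention) delimits the call's
temporal range; frames without an edge between edge-bearing frames are
breaks (FF = 0), and a single-frame value differing by more than 5 kHz
from both voiced neighbours is replaced by their interpolation (one
pass). FE(t) is the patch value along FF(t).

The 18 automatic scalars are: duration (first to last tracked frame,
breaks included), spectral width `max(FF) - min(FF)`, start/end/min/max
frequency, the mean of the voiced FF and the intensity-weighted mean
over the raw patch, skewness/kurtosis of FE(t) and of the spectral
marginal (population moments by default; a `sample_moments` switch is
provided), direction, Wiener entropy (per-frame geometric over
arithmetic mean, averaged over non-empty frames), spectral salience
(largest off-zero peak over the zero-lag peak of the across-frequency
autocorrelation), tremolo (the same salience statistic applied to the
voiced FF sequence), mean fundamental energy, and spectral purity
(per-frame max over median, averaged). Conventions worth stating:

* **Autocorrelations are mean-centred, and "off-zero peak" means a
  local maximum over positive lags.** On raw non-negative spectra the
  lag-1 autocorrelation is always close to lag 0 and a global maximum
  would saturate at 1; likewise a linear frequency ramp has a monotone
  decaying autocorrelation whose lag-1 value is large without any
  periodicity being present. Centring plus the peak requirement make a
  flat or aperiodic spectrum score near 0, a constant fundamental score
  exactly 0 (the tremolo convention, stated prominently because the
  formula's source does not fix it), and a linear sweep score 0.
* **Direction** is the sign of the mean single-step FF difference over
  voiced frames, with a 0.1 kHz dead zone absorbing the +-0.6 kHz bin
  quantization that would otherwise flip symmetric calls to +-1.
* **Zero medians** (typical of sparsified frames) in spectral purity are
  replaced by the frame's smallest positive value.
* **Moments of degenerate tracks** (fewer than two voiced frames) are
  `NA`, not numbers.

Each formula is additionally implemented a second time in the test
suite as plain brute-force loops, and the two implementations must agree
to 1e-9 relative error on random matrices.

The extended per-call description is a 457-dimensional vector with a
fixed layout: 24 scalars (the 18 automatic ones plus the six scored
properties - direction, peaks, breaks, broadband, tremolo, complexity -
which the generator supplies as ground truth), then the fundamental line
resampled to 100 points over the 100 ms span (zero-padded for shorter
calls), the 233-bin spectral marginal, and the 100-point
fundamental-energy line. The composition of the 24 follows from
counting the two mean-frequency estimates separately (18 automatic) and
filling the six scored slots from ground truth; scoring behaviour of
human raters is explicitly out of scope.

## Classifiers and training

Three architectures are specified declaratively and built by one
engine:

* the **spectrogram network**: six convolutional layers (kernels 10x10,
  5x5, then four 3x3; strides 2, 2, 1, 1, 1, 1; 256 units each) and
  three fully connected layers of 120 units (80 for the broadband
  variant, applied to all three), with a sigmoid head for binary tasks
  and softmax heads of 4/4/3/17 units for peaks, breaks, direction and
  individual identity;
* the **feature network**: four fully connected layers of 70 units on
  the 9 basic features;
* the **semi-convolutional network**: three parallel 1-D stacks
  (kernels 7, 5, 3, 3, 3; strides 2, 2, 1, 1, 1; 32 units) over the
  fundamental line, time marginal and frequency marginal, concatenated
  with the 24 scalars into three 90-unit layers.

All hidden layers are batch-normalized (after the affine map, before
the ReLU - the conventional placement) and ReLU-activated; outputs are
sigmoid/softmax; weights are Xavier-initialized; training is Adam with
batch size 64 under staged protocols (epochs, learning rate, dropout
per stage, including one stage with quadratic learning-rate decay from
1e-3 to 1e-5). Dropout applies to the fully connected stack only.
Convolutions use "same" padding with no pooling, so the documented
spatial sizes at the conv-to-dense transition are 25 x 25 maps
(`layer_shapes()` prints the full geometry). Class imbalance is handled
by inverse-frequency loss weights for the networks and by downsampling
the larger class for the baselines. On-the-fly augmentation clips up to
10% of the occupied duration from the ends, scales intensity by
U[0.5, 1.5] and adds Gaussian noise with variance U[0, 0.01] on the
[0, 1] scale; the 1-D streams get clip + noise only, except the
frequency marginal, which gets U[0.8, 1.2] amplification + noise.

The engine is written in C++ (im2col + GEMM convolutions in single
precision; gradients checked against the loss decrease on toy problems)
and draws every random number - initialization, shuffling, dropout,
augmentation - from R's RNG, so `set.seed()` makes training exactly
reproducible on a CPU. Batch-norm statistics use momentum 0.9; a
non-finite loss aborts with a diagnostic rather than training on.

Baselines: ridge regression solves the normal equations
`w = (X'X + lambda I)^-1 X' y` directly on 0/1 targets with an
equally-penalized intercept; when there are more features than samples
and `lambda > 0` the algebraically identical dual form
`w = X'(XX' + lambda I)^-1 y` is used, which avoids forming the
p x p Gram matrix. The SVM baseline uses the plain quadratic kernel
`(u.v + 1)^2` for images and the dot-product kernel for feature
vectors (the per-feature rescaling some libraries apply by default
makes a 10^4-dimensional quadratic kernel nearly constant and was
disabled deliberately).

### The scaled-down ordering benchmark

`classifier_ordering_experiment()` is the package's standing experiment
for the qualitative claim that interaction-sensitive classifiers beat
kernel methods beat linear ones when the class signal is a nonlinear
feature combination. Its conditions, fixed once: 2000 calls (1000 per
class) from `surrogate_profiles()` rendered at 10 dB per-call SNR; a
reduced spectrogram network (32 units in every layer) trained with the
single-stage `"reduced"` protocol (5 epochs, lr 1e-3, no dropout,
batch 64); SVM and ridge (lambda = 100) on the raw 10^4-pixel images;
an 85/15 train/test split; and shuffled-label retraining of all three
as chance controls. Three details keep the chance band honest, all
addressing the same phenomenon: on a dataset organized by one dominant
relational feature, a network trained on noise labels does not stay
neutral - it settles into a parity-aligned basin of random sign, so a
single control run can sit several points away from 50%. First, the
control labels are a *stratified* permutation (exactly half of each
true class receives each label), so the shuffled training set provably
carries zero marginal class information. Second, the controls are
evaluated on an independently generated 2000-call sample drawn from
the *leak-free* relational profiles, removing any contribution of the
marginal duration leak. Third, the network control is the mean of an
*antithetic pair*: the same initialization and batch order trained on
the permutation and on its complement, whose alignment biases mirror
each other and partially cancel in the mean (measured pair means
scatter within a couple of points of 50%, against up to 9-point
deviations for single runs; the residual scatter is the price of
running one pair rather than a fold-averaged family of controls, which
the compute budget of the standing experiment does not allow). The
kernel and linear controls are single runs; they memorize far less and
their deviations are much smaller. The noise level is
what keeps the benchmark honest: on noiseless images the quadratic
kernel nearly matches the network (pixel pairs carry the signal
exactly), while at 10 dB the products of noisy pixels degrade much
faster than learned convolutional averages, reproducing the expected
separation. Under these conditions the network reaches the high 90s,
the SVM the mid 80s to mid 90s and ridge around 55-65.

The full Table-scale network (256 units, three-stage protocol) is
constructed and shape-checked in the suite but not trained there;
training it is a GPU-scale undertaking and reproducing real-data
accuracies is a non-goal without the original recordings.

## Interpretation analyses

Activation sparsity is `1 - active/total` with "active" defined as
strictly positive post-ReLU response (no threshold is defined by
convention, so zero is the natural cut); it is invariant to positive
rescaling. Within- and across-class correlations are mean pairwise
Pearson correlations of flattened per-sample activation vectors
(constant vectors excluded); on any surrogate network with test
accuracy >= 70% the suite asserts the separation direction
(within > across in the last fully connected layer) but no magnitudes,
which are data-bound. Deconvolution back-projects a chosen layer's
feature map (optionally a single unit) through plain transposed weights
- honouring strides and padding - with switches for rectified and
guided variants; for a linear convolutional stack the back-projection
is the exact adjoint operator, asserted to 1e-6 in matrix form.

Embeddings: PCA via the standard singular value decomposition, and an
exact O(n^2) t-SNE (perplexity calibration by bisection, early
exaggeration 12 for 100 iterations, momentum 0.5 to 0.8, adaptive
gains) that takes an explicit PCA pre-reduction dimension to mirror the
two conventional settings (9 for feature vectors, 100 for
spectrograms); duplicate rows are jittered by a relative 1e-8 before
calibration. Nearest-neighbour leave-one-out decoding resolves distance
ties to the lowest index and is checked against an exhaustive O(n^2)
loop. Class density differences use kernel density estimates on a
common grid (Scott's rule bandwidth by default), each normalized to
unit mass before subtraction, so the signed field integrates to zero.

## Statistics

Group comparisons are nonparametric by default - Wilcoxon rank-sum,
Wilcoxon signed-rank, Kruskal-Wallis - two-sided, with exact
distributions at small n (the fully-separated 3 vs 3 case gives exactly
p = 2/20); above-chance claims use one-sided exact binomial tails; the
effect size reported alongside is the variance accounted for by the
grouping factor (between over total sum of squares); Bonferroni
correction is available for post-hoc families.

## Problem sizes and reproducibility

The standing experiments use sizes a single CPU handles in minutes:
200 calls for segmentation recovery, 100 noiseless calls for feature
recovery, 2000 calls for the ordering benchmark, 100 random matrices
for the formula oracles, and 300 held-out images for the embedding and
representation analyses. `run_experiment()` ties generation,
segmentation, features, classification and evaluation to one seed and
writes a manifest (configuration, fingerprint, versions) with its CSV
tables; rerunning from the same configuration reproduces every table
byte for byte. The acceptance script (`scripts/acceptance.R`) recomputes
all headline quantities from scratch for any seed.

## Known limitations

Synthetic calls are cleaner than real ones: no reverberation, no
overlapping animals, no repertoire structure, and break gaps that are
perfectly silent. The curvature-flow denoiser assumes speckle-like
noise; structured interference (scratching, cage noise) is the
frequency criterion's job, not the denoiser's. The engine trains
networks of the reduced size used in the benchmarks comfortably; the
full 256-unit architecture, while fully supported, is not something to
train on a laptop CPU. Real-data accuracies depend on the deposited
recordings and are deliberately not asserted anywhere in the package.
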