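---
title: "Synthesizing event-related potentials from concept embeddings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing event-related potentials from concept embeddings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Event-related potentials (ERPs) are stimulus-locked averages of scalp EEG.
Their late components — above all the late positive potential (LPP, a
parietal positivity from roughly 400 to 800 ms after picture onset — index
how a given brain processes the semantic and emotional content of what it
sees or reads. `erpsynth` implements a generative bridge between the two
domains: a *conditioned variational autoencoder* (cVAE) learns a compact
latent description of channel-by-time ERP matrices, and a *cross-domain
network* maps 512-dimensional multimodal concept embeddings (the output of
a contrastive image–text encoder) into that latent space. Composing the
two turns any picture or text embedding, together with a subject identity,
into a synthetic per-subject ERP matrix.

## The conditioned VAE

Each trial is a `n_channels x n_samples` matrix (129 x 750 at full scale:
1.5 s at 500 Hz, from 0.1 s before to 1.4 s after onset). The encoder
applies three 2-D convolutions over the channel-by-time grid (kernel 3,
stride 2, padding 1, output channels 32/64/128, rectified-linear
activations) and flattens the result; at full scale this gives a
204,544-dimensional feature vector (128 x 17 x 94). The subject's one-hot
identity vector (length 88 at full scale) is concatenated, and two parallel
dense heads produce the latent mean $\mu$ and log-variance
$\log\sigma^2$, each of dimension 256.

Training samples the latent via the reparameterization trick,
$z = \mu + \sigma\,\epsilon$ with $\epsilon \sim N(0, I)$, and the decoder
mirrors the encoder: the latent (again concatenated with the one-hot) is
expanded by two dense layers, reshaped, and passed through three
transposed convolutions back to the input shape, with a linear output
layer. Generation-time decoding uses $\mu$ deterministically — the model
is trained on averaged-ERP-like signals and produces averaged-ERP-like
output, so no trial-level sampling is added by default.

The loss is mean squared reconstruction error plus a KL divergence of the
posterior from the standard-normal prior,
$-\tfrac12 \sum (1 + \log\sigma^2 - \mu^2 - \sigma^2)$, batch-averaged.
The KL term is *annealed*: its weight follows
$\beta / (1 + e^{-0.5\,(\mathrm{epoch} - 100)})$, essentially zero early,
$\beta/2$ at the midpoint epoch, saturating at $\beta$. Annealing lets
reconstruction organize the latent space before the prior is enforced and
protects against posterior collapse (all $\mu \to 0$, which would destroy
the model's generativity). Full-scale constants: $\beta = 10^{-5}$, Adam
with learning rate $10^{-6}$, batch size 64, 1300 epochs.

Two architectural choices were genuinely open and are resolved as follows.
The conv geometry (stride 2, padding 1, channels 32/64/128) is the unique
natural configuration that reproduces the 204,544-long flatten from a
129 x 750 input with three kernel-3 layers. Conditioning is injected at
the two concrete points of the dataflow: concatenated to the flattened
features before the $\mu$/$\log\sigma^2$ heads, and concatenated to the
latent before the decoder; no third injection point is guessed. The
decoder's first dense layer width (1024 full-scale, 256 desk) is not
externally fixed and is plain configuration. Variance is parameterized as
log-variance for numerical stability; $\sigma$ is recovered as
$\exp(\log\sigma^2/2)$.

Our transposed convolutions are implemented as the exact adjoint of the
mirrored encoder convolution (a scatter through the same sparse gather
matrix), which guarantees shape inversion without output-padding
bookkeeping and keeps the hand-written backward pass simple; its gradients
are verified against finite differences in the test suite. All layers,
backpropagation and the Adam optimizer are implemented in plain R with
BLAS matrix products — at desk scale this trains in minutes on one CPU.

## The cross-domain bridge

The bridge is a dense network from `[embedding (512); one-hot]` to the
latent mean: two hidden layers with exponential-linear activations and a
linear output, trained with Adam (learning rate $10^{-3}$) on mean squared
error against the latent means of the training trials, early-stopped at
the best validation loss on a held-out, subject-stratified 10% of pairs.
Hidden widths are not externally fixed; the defaults taper 512 to 384
(full) or 128 to 96 (desk). Embeddings are L2-normalized before training
and mapping (recorded in provenance); inputs from the bundled mock encoder
are unit-norm by construction, so this is a no-op there but keeps
externally supplied embeddings on the same scale.

No pretrained image-text encoder ships with the package. `clip_encode()`
is an adapter hook that raises a capability error unless an encoder
function is supplied; the deterministic `mock_encode()` (class centroids on
the unit sphere plus id-specific jitter) stands in for all offline work and
testing, and is labelled as such everywhere.

## The synthetic-data generator

Because no empirical recordings ship with the package, the simulator is
the reference data source, with analytically known ground truth. Each
trial is a sum of stereotyped components — P100 (100 ms, occipital), N200
(200 ms, negative, occipital), P300 (300 ms, parietal), LPP (600 ms,
parietal, 120 ms temporal SD) — each a Gaussian-in-time waveform projected
through a smooth spatial topography (Gaussian in chord distance on the
unit sphere, spread 1.0), plus white noise (SD 0.15 in template units).
Temporal templates are truncated at three standard deviations, so the
early components have compact support and the 400–800 ms scoring window
contains only the LPP: windowed scores then obey closed-form algebra
(e.g. scores scale exactly with the condition multiplier), which the
oracle tests exploit.

Subject idiosyncrasy is injected as per-(component, subject) log-normal
amplitude factors (SD 0.1), latency shifts (SD 5 ms), and topography
center displacements (SD 0.15 chord units). The condition effect
multiplies the LPP only: pleasant 1.5, neutral 1.0, unpleasant 1.8.
Emotional content above neutral produces the canonical V-pattern; the
pleasant/unpleasant asymmetry mirrors the common empirical finding that
unpleasant content evokes the largest LPP, and keeps the three categories
mutually distinguishable for decoding analyses. The desk profile (6
subjects, 32 channels, 150 samples at 100 Hz, latent 32, 20 stimuli per
condition) is sized so that the full pipeline — simulate, z-score, split,
train both networks, generate, evaluate — runs in a few minutes on one
CPU; the full-scale geometry (88/129/750 at 500 Hz, latent 256) is one
profile flag away.

What the simulator deliberately does **not** emulate: 1/f background
spectra, ocular or movement artifacts, biophysical volume conduction
(dipoles, head conductivity), trial-to-trial latency jitter of components,
or correlated sensor noise. Tests passing on this fixture therefore show
that the pipeline recovers structure *of the kind injected*; they do not
certify performance on real recordings.

## Preprocessing choices

The conditioning chain for empirical-style data pairs an order-3
Butterworth high-pass at 0.2 Hz with an order-9 low-pass at 25 Hz, both
applied forward-backward (zero phase). Interpreting the two printed orders
as high-pass/low-pass in that sequence follows standard ERP practice of a
gentle high-pass and steep low-pass. Signals are extended by odd
reflection over about three high-pass time constants before filtering so
that the DC response converges on finite records.

Artifact control flags channels whose compound quality index — the mean of
robust-z-scored median absolute voltage, standard deviation, and maximum
absolute first difference — exceeds the distribution median by more than
2.5 SD. The three metrics are named by the procedure; their combination
is not, and the equal-weight robust average is the simplest faithful
reading. A companion trial-rejection rule (drop trials whose fraction of
aberrant channels exceeds 10%) is configurable, since the underlying
procedure's exact trial criterion lives in its original reference.
Flagged channels are replaced by spherical-spline interpolation
(order m = 4, regularization 1e-5, Legendre series truncated at degree
50 — conventional spline parameters). Z-scoring is per channel over the
training set (per-trial and global variants would also be defensible; the
chosen scope is recorded in the normalization parameters so generated
output can always be de-normalized). The 80/20 split size uses
round-half-even, which maps 13,640 trials to exactly 10,912.

The epoch time base puts sample *k* (1-based) at $t_0 + (k-1)/f_s$ with
$t_0 = -0.1$ s; windows are half-open `[start, end)` milliseconds, mapped
to samples by ceiling/floor on that base. At 500 Hz the 400–800 ms LPP
window covers exactly 200 samples, and 0.1 s + 1.4 s spans exactly 750.

## Evaluation statistics

- `correlation_map()` pairs averaged datasets (the pairing key —
  subject, condition, or both — is an explicit argument, since reasonable
  analyses differ here) and computes Pearson r and two-sided p per
  (channel, sample).
- `score_component()` is the windowed mean amplitude at a channel resolved
  through the montage's 10-10 equivalences (Pz = E62, Oz = E75, PO8 = E96
  on the bundled 129-channel net; Cz is the reference).
- `v_pattern()` is `(pleasant + unpleasant)/2 − neutral` per subject.
- `latent_decode()` is 5-fold stratified linear-SVM classification of
  condition from latent means, per subject; the fold protocol is a
  package choice.
- `project_2d()` is a deterministic centered principal-component
  projection for display; no quantitative claims attach to it. A
  stochastic neighbour embedding would serve equally; a deterministic
  projection was preferred so that repeated runs are identical.

The headline real-data statistics of the approach this package implements
(reconstruction correlations near 0.64, arousal-rating correlations near
0.23, the N170 face topography) require empirical recordings, a pretrained
multimodal encoder, and the original trained weights; none are
reproducible from synthetic data, so they are out of scope here. The
package instead validates every operation against synthetic oracles and
structural identities (flatten length, split sizes, trial counts).

## Numerical and reproducibility choices

Every stochastic stage draws from an explicit seed; child seeds are
derived per stage (kept inside the 32-bit integer range), so training,
simulation, splitting, and fold assignment are all bit-reproducible and
independent of call order. Batch generation iterates subject-major and
calls the same single-epoch decode path per stimulus, so a batched run is
bit-identical to composing `concept_to_erp()` calls. Checkpoints are
self-describing (format tag, config snapshot, named weight arrays).
Weight initialization is He-scaled Gaussian; the log-variance head is
initialized near zero so early sampling stays tame. Degenerate inputs are
rejected with typed errors (dimension, parameter, pairing, capability,
composition), and zero-dispersion QC input flags nothing.

The MAT-compatible container stores named arrays
(`data` as trials x channels x samples, metadata as char arrays, montage
positions, JSON provenance) in the uncompressed MAT v5 format, written and
parsed by a minimal reader/writer in the package; it round-trips exactly
and is readable by standard MAT tooling.

## Desk-scale study sizes

The test suite and the acceptance script run the recovery benchmark at
desk scale: 360 simulated trials (288 training), 60 cVAE epochs, bridge
early-stopped within 40 epochs, full 6 x 60 generation. With those sizes
the held-out mean per-trial reconstruction correlation, the per-subject
V-pattern of generated data, latent decoding, and the posterior-collapse
guard are all computed end-to-end in a few minutes. The full-scale
constants are pinned in the `full` profile but are not exercised by the
tests; training at that scale is a multi-GPU undertaking out of scope for
this package.

## Known limitations

- The desk-scale cVAE is trained on one CPU in plain R; wall-clock scaling
  to the full 129 x 750 geometry is far beyond its intent.
- The simulator's realism limits are listed above; none of the evaluation
  numbers transfer to empirical data claims.
- `clip_encode()` requires a user-supplied encoder; the package never
  silently substitutes the mock encoder for it.
- The latent-noise generation flag (sampling z instead of decoding mu)
  exists but defaults off and is excluded from the benchmark.
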