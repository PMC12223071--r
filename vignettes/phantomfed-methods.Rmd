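---
title: "Methods: simulated federated brain-tumor analysis on CT phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated federated brain-tumor analysis on CT phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter
choices, and numerical conventions, and of what the synthetic experiments
do and do not demonstrate.

## The problem and the simulation strategy

Multi-institution tumor-detection studies combine stages that are usually
evaluated only end-to-end on private data: image preprocessing,
segmentation, handcrafted plus learned feature extraction, wrapper feature
selection, classification, federated aggregation, and model-update
auditing. `phantomfed` re-creates that whole chain at desk scale on
synthetic brain phantoms so each stage has a ground truth and the full
pipeline is reproducible from one seed. All conclusions are therefore
about algorithmic correctness and behavior under controlled conditions,
not about clinical performance.

## Synthetic phantoms

A phantom is an oval brain (semi-axes 20 and 24 px in a 64×64 frame,
intensity 0.45) inside a bright skull ring (thickness 3 px, intensity
0.95), separated by a 2 px CSF gap at background intensity (0.05). The
intensity ordering background < brain < tumor < skull is enforced by the
spec constructor. A tumor, when present, is a star-shaped blob: radius
`R(θ) = R·(1 + ρ·s(θ))` with `s` a bounded zero-mean harmonic series, and
elliptical axes `R√e`, `R/√e`, so the pixel area stays near `πR²` for any
axis ratio `e` and the pixelized blob is one connected component. The
three tumor "types" are geometric presets — size multiplier, axis ratio
and boundary roughness — because in this pipeline the type labels exist
only to drive client heterogeneity, not biology:

| type | size | axis ratio | roughness |
|---|---|---|---|
| glioma-like | 1.00 | 0.70 | 0.30 |
| meningioma-like | 0.80 | 1.00 | 0.10 |
| pituitary-like | 0.55 | 0.85 | 0.20 |

Noise is additive Gaussian (`σ = 0.03` by default) followed by clipping to
`[0, 1]`. Per-scan seeds are the SHA-256 fold of the master seed and the
scan index, so a dataset is reproducible independent of generation order.

The pseudo-modality channel applies a strictly monotone lookup (default
gamma-like `v^0.6`) and a 0.7 px Gaussian blur. Monotonicity preserves
intensity ranks, which is exactly the property mutual-information
registration must be robust to; a learned translation model is out of
scope and deliberately replaced by this deterministic stand-in. The
SSIM/PSNR quality gate (defaults 0.75 / 22 dB, both configurable) screens
synthetic images the way a translation-quality filter would; the default
remap scores SSIM ≈ 0.6–0.7 against its source, so pipeline code gates it
with relaxed thresholds and the strict defaults are exercised in tests.

The default federated cohort is five clients with unequal counts
(400/420/410/430/440 real plus 160/180/170/160/180 pseudo at scale 1) and
tumor-type mixes 70/30 glioma/meningioma, 50/50 meningioma/pituitary,
100% glioma, balanced, and 60/40 pituitary/glioma. When a finite phantom
pool is partitioned, the generator's type mix defaults to the cohort's
aggregate composition (0.48/0.23/0.29) so the heterogeneous demands are
satisfiable; realized client mixes are within one sample of the request
(largest-remainder rounding), and an infeasible request fails with an
explicit shortage message rather than silently rebalancing.

## Preprocessing

*Morphology.* Erosion and dilation are implemented from their set
definitions with the footprint-fit and footprint-hit tests; pixels outside
the image count as background. Under this finite-domain convention,
erosion/dilation duality and closing extensivity hold exactly away from
the border (within one footprint radius of it the truncation breaks them),
which is how the property tests are phrased. Skull stripping is Otsu
threshold → erosion (disk radius 2, detaching the skull ring across the
CSF gap) → largest connected component → dilation → hole filling; the
threshold choice is Otsu because only the morphological steps themselves
are prescribed by the pipeline design. Blank images return an empty mask
with a warning instead of an error so batch runs continue.

*Anisotropic diffusion.* The explicit 4-neighbour Perona–Malik scheme with
replicate boundaries and per-edge conduction coefficients computed from
the intensity difference across each edge. Because the same coefficient
multiplies the flux on both sides of an edge, the scheme conserves the
global mean to machine precision each iteration — a property the tests
assert. The conduction function defaults to `exp(−(x/κ)²)` with the
rational `1/(1+(x/κ)²)` as an option; `λ ≤ 0.25` is enforced as the
stability bound of the stencil. `κ = 0.1` on unit-range images smooths
noise while preserving the ~0.3 tissue steps.

*Min-max normalization* is the standard affine map; constant input is an
explicit error unless a fill value is configured, because silently
returning zeros would hide degenerate inputs.

*Registration.* MI is computed from a joint histogram with each image
binned over its own range (32 equal-width bins by default); this makes MI
invariant to monotone relabeling at matched binning, which is the point of
using MI across modalities. The search is deterministic: exhaustive
integer-shift grid, then golden-section refinement over the rotation
angle, then a half-pixel local shift polish. Resampling is bilinear with
replicate edges. The returned transform is the estimated displacement of
the moving image's content relative to the fixed image.

## Segmentation network

The U-Net is built from residual blocks (two 3×3 convolutions with batch
normalization, identity skip, 1×1 projection when channel counts differ)
or dense blocks (each layer consumes the concatenation of all previous
outputs); encoder levels are joined by 2×2 max pooling, decoder levels by
2×2 stride-2 transposed convolutions with skip concatenation, and a 1×1
convolution plus sigmoid produces per-pixel tumor probabilities. Whether
residual and dense blocks should coexist in one network was an open
design question; they are implemented as alternatives selected per
network, which keeps the channel arithmetic predictable
(`segnet_param_count()` is the closed form, verified against enumeration).

Everything runs on hand-written matrix kernels: feature maps are
`(batch·H·W) × channels` matrices, convolutions are im2col gathers with
precomputed index tables followed by one BLAS product, and every backward
pass is derived analytically (the suite checks them against central
finite differences at 1e-7). This keeps the tiny preset — depth 3, base
8 channels — trainable in minutes of CPU while remaining the same
architecture family as large-scale variants; a `paper-like` deeper preset
exists for parity but is not exercised by the tests.

Training minimizes soft Dice loss with `ε = 1e-6` (the bare formula
divides by zero on empty masks; the smoothing also defines the
empty-empty case as loss 0), optionally plus weighted binary
cross-entropy. The optimizer is Adam at `lr = 1e-3`, batch 8. Determinism:
initialization, shuffling and updates all derive from the master seed;
with R's reference BLAS the runs are bit-reproducible. Problem sizes used
by the acceptance experiments: 200 training phantoms at 64×64 for 5
epochs (about 3 minutes), held-out Dice evaluated on 40 phantoms; the
single-image overfit and skip-ablation runs use 32×32 phantoms and 200
steps. On this phantom family the network reaches held-out Dice ≈ 0.98 —
the tumors are bright blobs, so the task validates the training machinery
rather than challenging it.

## Features

GLCM features are computed after min-max quantization to 8 gray levels
inside the ROI (both pixels of a pair must lie in the ROI), with
symmetric accumulation over offsets (0,1) and (1,0), averaged.
Quantization over the ROI's own range makes the texture features exactly
invariant to constant intensity shifts. Energy is the sum of squared
matrix entries (the uniformity definition); correlation is the standard
GLCM correlation since only its name, not its formula, is part of the
pipeline's specification. First-order moments are population formulas
(divide by N) with non-excess kurtosis (Gaussian → 3); zero spread is an
explicit error for the standardized moments. Deep features are the
globally average-pooled last stage of the classifier backbone — pooled
rather than pre-pool maps, resolving an ambiguity in favor of the
GAP-vector path used everywhere else. Fusion is weighted concatenation
`[α·deep ∥ β·hand]` with `α = β = 1` by default: a weighted elementwise
sum of different-length blocks is dimensionally impossible, and
concatenation preserves both blocks for the selector to arbitrate; the
sum variant exists for equal-length blocks.

## The hybrid optimizer

The optimizer maintains M agents; each iteration every agent receives an
exploration proposal and an exploitation proposal, each accepted only if
it improves that agent's fitness (greedy), so the best-so-far trace is
monotone by construction. The exploration rule draws one uniform `rand`
and takes: uniform reinitialization when `rand ≥ p`; the drift move
`(r₂−C)·X_r + L·H` when `rand ≥ 0.5`; otherwise the local-escape move
with `γ = 2·rand−1`. The auxiliary quantities follow the gorilla-troops
conventions (`C = F(1−t/T)` with `F = cos(2r₄)+1`, `L = C·l`,
`H = Z⊙GX`), since the hybrid is framed as a modification of that
optimizer and leaves them otherwise undefined. Exploitation follows the
best agent (`δ = sin(2.5 − t/T)`) when `|C| ≥ β` and otherwise overshoots
it with `α = 2e^{−t/T}`. Defaults `p = 0.03`, `β = 0.8`; phase control
(both phases every iteration, greedy acceptance) is the package's design
choice where the published control flow is silent, and is configurable.
Out-of-bounds proposals are clipped by default (reflection available).

With greedy acceptance the follow-the-silverback move contracts agents
multiplicatively, which is extremely effective on origin-centered
benchmarks — the 10-D sphere and Rastrigin medians reach numerical zero.
The equal-budget comparison against uniform random search
(30 + 2·30·200 evaluations each) is therefore the more meaningful check.

The feature-selection wrapper binarizes positions at 0.5 and minimizes
`w(1−acc) + (1−w)·selected/total` with `w = 0.9`; empty masks score 1.
The inner evaluator is a nearest-mean classifier under 3-fold
cross-validation on standardized features — a deliberate lightweight
substitution for a deep classifier in the inner loop, which would be
computationally indefensible there; the outer capsule classifier consumes
the selected features afterwards. Wrapper run sizes default to M = 20,
T = 30, chosen once as sufficient for 50-feature tables.

## Capsule classifier

Primary capsules are a linear projection of the (selected, fused) feature
vector, squashed per capsule; class capsules receive per-pair prediction
vectors and routing-by-agreement (logits start at zero, couplings are a
softmax over parents so each child's couplings sum to one, agreement
increments the logits). The squashing function keeps norms in `[0, 1)`
and preserves direction; the class-capsule norm is the reported
confidence and the argmax (ties to the lowest class index) the label.
Training uses margin loss with the standard constants
(`m⁺ = 0.9`, `m⁻ = 0.1`, `λ = 0.5`); binary cross-entropy is available
as an alternative. During backpropagation the routing couplings of the
final iteration are treated as constants (stop-gradient through the
routing loop); gradients flow through the weighted sum and both squash
layers and match finite differences exactly when routing is frozen. This
is a common, documented simplification; with the default three routing
iterations the neglected coupling sensitivity is small and training is
stable. An image-mode path prepends a small residual backbone whose
pooled last stage feeds the same capsule head; the feature path is the
pipeline default. Batch-normalization running statistics are buffers, not
parameters: they are excluded from the flat weight vector, which matters
for federated averaging and digesting (only the image path has them).

## Federated simulation and ledger

Each round broadcasts the flat global parameter vector; each client
resumes training on its local data (3 local epochs by default; a fresh
Adam state per round, so a K = 1, no-failure run is bit-identical to
centralized training restarted each round with the same derived seeds —
an identity the acceptance suite asserts). Only `(client id, n_k,
weights)` crosses the client boundary. Failures are injected
independently per client: dropout with probability 0.10, and poisoning of
survivors with probability 0.10 as additive Gaussian noise of standard
deviation 0.5 × the update's RMS weight (the rate is prescribed by the
simulated scenario; the magnitude is the package's choice and is
configurable). Differential privacy is the Gaussian mechanism — clip to
`C`, add `σ = C√(2 ln(1.25/δ))/ε` per coordinate, defaults `ε = 1`,
`δ = 1e-5` — applied per client update when enabled; `ε = ∞` is the
noiseless (clip-only) mode. Aggregation is the exact sample-weighted mean
with pairwise summation, keeping the result permutation-invariant to
1e-9. If every client drops, the round is skipped and the previous global
model retained.

Every aggregated model is digested — SHA-256 over a canonical
serialization: an optional UTF-8 shape-registry prefix, then the weights
as little-endian IEEE-754 doubles in registry order — and appended to a
hash chain whose blocks bind `(index, round, previous hash, payload
digest, validator, timestamp)`. Validators rotate through a fixed
five-member authority set; an unauthorized validator or non-monotone
round is rejected. This models what proof-of-authority provides at the
application level (append-only history validated by known parties)
without any consensus protocol; gas, latency and throughput figures of a
real chain are out of scope. Whether to hash weights, gradients or deltas
was open; the post-aggregation global weights are hashed by default, with
per-update digesting available through the same functions. Timestamps are
wall-clock by default and excluded from determinism checks; a fixed-clock
mode exists for golden tests, and pipeline manifests digest only the
reproducible payload.

The acceptance-scale federated study uses 260 real + 100 pseudo phantoms,
five clients at cohort scale 0.08 (about 45–50 samples each), 10 rounds,
and a 60-scan real-only held-out set; features are standardized once over
the simulated population before distribution (a simulation-harness
convenience — a deployment would use per-client or securely aggregated
statistics). On this separable phantom family the federated classifier
reaches ceiling accuracy, so the dropout/poisoning comparison is reported
as an ordering (no-failure ≥ dropout ≥ poisoning over five seeds), which
at ceiling holds with equality.

## Evaluation

Confusion-matrix metrics use the textbook formulas; any metric with a
zero denominator is reported as `NA`, never silently zero, and MCC is
clamped to `[−1, 1]` against floating-point excursions. Dice and IoU obey
`dice = 2·iou/(1+iou)`; two empty masks score 1 by convention (perfect
agreement on absence). Stratified k-fold splits real-modality samples
with per-fold class counts within one of proportionality; pseudo-modality
samples are never placed in validation/test folds (they receive fold id
0, training-only) — the leakage rule for synthetic-augmentation studies,
asserted over randomized datasets.

## Known limitations

Phantoms are far easier than clinical CT: tumors are bright, geometry is
stereotyped, and there is no scanner physics, so ceiling metrics here say
nothing about clinical accuracy — they validate correctness, determinism,
contract enforcement (leakage, isolation, auditability) and the relative
behavior of algorithm variants. The routing stop-gradient, the
global feature standardization in the simulation harness, the
fresh-Adam-per-round convention, and the deterministic pseudo-modality
stand-in are the main deliberate simplifications, each noted above.
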