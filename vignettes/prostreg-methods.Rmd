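---
title: "Cross-modal prostate registration with prostreg: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal prostate registration with prostreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fusing preoperative prostate MRI with intraoperative transrectal ultrasound
(TRUS) requires a deformable registration: a displacement field
$\phi:\Omega\to\mathbb{R}^3$ that warps the moving MRI volume $I_m$ onto the
fixed TRUS volume $I_f$,

$$\phi^\* = \arg\min_\phi\; \mathcal{L}_{sim}(I_f, I_m\circ\phi)
          + \lambda\, \mathcal{R}(\phi),$$

under two complications that make the problem harder than mono-modal
registration: the intensity distributions of the two modalities are
unrelated (soft-tissue contrast vs. speckle and echo intensity), and the
gland deforms non-rigidly, including quasi-periodic motion during the
intervention.  prostreg implements a learning-based solver: a
fully-convolutional network predicts a *stationary velocity field* (SVF)
from the volume pair, the SVF is integrated to a diffeomorphic displacement
by scaling and squaring, and a recurrent stage refines the field along the
depth axis treated as a pseudo-temporal sequence.

## Architecture

**Dual encoders.**  Moving and fixed volumes pass through two
weight-independent encoders of four ConvBlocks (3×3×3 convolution +
LeakyReLU(0.2); channels 16, 32, 32, 32), with 2×2×2 max pooling between
levels: a 128³ input reaches 16³ at the bottleneck (a 32³ test grid reaches
4³).

**E-CMCA.**  At each post-pooling level an Enhanced Cross-Modal Channel
Attention block couples the streams.  Per modality it applies

* *MSFA* — parallel convolutions with kernels 3, 5, 7; each scale receives a
  single scalar score (global average + global max pooled over all channels
  and voxels), the three scores are softmax-normalized, and the output is
  the weighted sum of the scale features;
* *DCA* — a squeeze-and-excitation-style channel gate: spatial GAP gives a
  length-$C$ vector, a single 1D convolution (kernel 3, no channel
  reduction) plus sigmoid yields per-channel weights in $(0,1)$;
* the *cross-modal gate* — with channel projections
  $W_1, W_2 \in \mathbb{R}^{C\times C/2}$, $W_3 \in \mathbb{R}^{C/2\times 1}$
  applied voxel-wise,
  $att = \sigma\!\big(W_3^\top\,\mathrm{ReLU}(W_1^\top F_1 + W_2^\top F_2 + b)\big)$
  is a single-channel spatial map that rescales the other stream.  By
  default the gate is applied symmetrically (two weight sets, each modality
  gating the other); `gate_mode = "f2_only"` reproduces the original
  one-sided formulation.

The first E-CMCA level operates on the post-pooling features (channels 32 at
half resolution for the default plans): the printed feature shapes of the
reference architecture place the first attention level there, and the
full-resolution skip connection is fused from the raw first-level ConvBlock
features instead.

**FuseConv and decoder.**  Each level's pair of (enhanced) features is
concatenated and reduced by a 1×1×1 convolution + LeakyReLU into a fused
skip; the bottleneck fuse maps 32+32 to 32 channels.  The decoder upsamples
trilinearly (×2, three times), concatenates the fused skips, refines at full
resolution (decoder channels 32, 32, 32, 16, then remaining blocks 32, 16,
16) and a final 3×3×3 convolution emits the 3-channel velocity field.  The
flow head is initialized with tiny weights (sd 1e-5, zero bias) so training
starts at the identity transform; with a large random initial field the warp
would destroy gradients.

**Diffeomorphic integration.**  `vecint()` integrates the SVF with 7
scaling-and-squaring steps: $\phi_0 = v/2^7$, then
$\phi \leftarrow \phi + \phi\circ\phi$ seven times (composition by trilinear
warping of each displacement channel).  Positive Jacobian determinant —
verified across seeded fields by `jacobian_stats()` — is what distinguishes
this from a raw displacement regressor.

**Pseudo-temporal LSTM.**  The static field is sliced along depth into
$T = 10$ slabs (`slice_flow()`), each flattened and fed as one time step to
a 2-layer, 128-hidden-unit LSTM; a fully connected layer maps hidden states
back to slab shape, slabs are reassembled, and leftover depth planes pass
through from the static field.  Two ambiguities in the source formulation
were resolved as follows:

* "padding to match the original dimensions" is implemented as pass-through
  of the residual planes (zero-padding would discontinuously erase real
  displacements);
* whether the LSTM output *replaces* or *augments* the static slices is
  ambiguous; both are implemented (`lstm_residual`), and the additive
  residual is the default so an untrained LSTM is an exact identity bypass.

At full clinical scale the flattened slice (3·128·128·12 = 589,824) makes
the LSTM input matrix enormous; the graph is faithful at any grid size, and
an optional learned down-projection (`lstm_proj_dim`) exists for
exploration, off by default.

## Objective

The composite loss is
$\mathcal{L} = \alpha\,\mathcal{L}_{grad} + \beta\,\mathcal{L}_{Dice} +
\gamma\,\mathcal{L}_{MI}$ with $\alpha = 0.4$, $\beta = \gamma = 1$.

* `dice_loss()` — soft Dice $1 - 2\sum pt/(\sum p + \sum t + \varepsilon)$
  on the trilinearly warped (hence real-valued) moving mask vs. the fixed
  mask; $\varepsilon = 10^{-6}$.
* `mi_loss()` — *negative* mutual information, in bits, of the intensities
  inside the prostate ROI (union of the fixed mask and the binarized warped
  moving mask), estimated with a differentiable Parzen joint histogram:
  32 bins spanning each image's observed range, Gaussian kernels of width
  one bin, row-normalized.  The sign choice is deliberate: the total loss
  *adds* the MI term with positive weight, so the term must be a loss
  (dependency up, loss down).  The gradient treats the bin centers as fixed
  per evaluation (the dependence of the observed range on the image is not
  differentiated), which is standard for histogram-based MI.
* `grad_loss()` — mean squared forward-difference gradient of the field,
  summed over 3 components × 3 directions, divided by the number of voxels
  $|\Omega|$.  Under this convention a linear field $\phi(p) = cp$ scores
  exactly $3c^2(n-1)/n$ on an $n$-voxel-side grid (the idealized $3c^2$ is
  the $n\to\infty$ limit).

**Per-slice task weighting.**  With `use_task_mask = TRUE` the loss is
assembled per depth slab: $L_{reg}[t] = \beta\,\mathrm{Dice}_t +
\gamma\,\mathrm{MI}_t$ restricted to slab $t$, $L_{smooth}[t] =
\alpha\,\mathrm{grad}_t$, combined as
$\frac{1}{T}\sum_t M_{t,1} L_{reg}[t] + M_{t,2} L_{smooth}[t]$ where the
mask $M$ comes from a dual-branch subnet (GAP of the decoder features, two
FC layers of hidden width 256 per branch, per-slice two-way softmax).  One
deviation from the literal formulation was forced by a degeneracy: if the
loss gradient is allowed to flow into the subnet, the subnet minimizes the
loss trivially by moving all weight to the smoothing task (which is ≈ 0 at
the identity initialization), silencing the registration signal — observed
empirically within a few iterations.  The mask is therefore *detached*
(stop-gradient) where it multiplies the loss: the subnet still produces
feature-dependent per-slice weights, but cannot collapse the objective.
Slabs whose ROI is empty contribute no MI term.

## Synthetic phantoms: what they emulate, and what a green test proves

`make_phantom_pair()` builds a pre-aligned cross-modal pair with known
ground truth:

* **anatomy** — a soft-boundary ellipsoidal organ (default semiaxes 8, 10, 9
  voxels on a 32³, 1 mm grid) with three smooth internal intensity bumps as
  stand-ins for internal structure (urethra, lesions);
* **MRI-like rendering** — piecewise-smooth intensities, organ/background
  contrast far above the additive Gaussian noise (sd 0.02);
* **TRUS-like rendering** — inverted, compressed contrast, a radial
  intensity falloff from a probe-like point at a volume face, and
  multiplicative log-normal speckle (sd 0.3), applied *after* the geometry
  (speckle is an acquisition artifact, not anatomy).  Voxelwise correlation
  between the modalities inside the organ is well below 0.9, so the pair is
  genuinely cross-modal;
* **ground truth** — a Gaussian-smoothed white-noise SVF (scale 8 voxels),
  smoothed on an extended grid and cropped so the field statistics are
  stationary (smoothing with replicate padding inflates border variance,
  which would concentrate the amplitude-normalized field at the border and
  leave the organ almost undeformed), tapered to zero over a 4-voxel
  boundary margin, rescaled in two passes so the *integrated* field has
  maximum displacement ≈ 3 voxels, and integrated by the same `vecint()`
  used everywhere else so recovery experiments compare like with like.  The moving image is rendered from
  anatomy warped by `vecint(-v)`, so warping it by the ground-truth field
  aligns it with the fixed image exactly (up to interpolation).
* **4D sequences** — `make_4d_sequence()` scales the base *velocity* by
  $\sin(2\pi t/\mathrm{period})$ per frame, a pseudo-respiratory cycle with
  shared anatomy.

**Why these values.**  The deformation scale (smoothness 8 voxels ≈ a
quarter of the organ diameter) was chosen by an explicit self-consistency
analysis: evaluating the composite objective along the ground-truth path
$\phi = t\,\phi_{gt}$, $t \in [0, 1]$.  A rougher field (smoothness 4) put
the objective's minimum near $t \approx 0.2$ — the gradient penalty at the
ground truth outweighed the shallow Dice gain, i.e. the world contradicted
the fixed loss weights, and no optimizer could be expected to recover the
deformation.  With smoothness 8, stationary field statistics and a steeper
hypoechoic TRUS contrast mapping, the objective decreases monotonically all
the way to the ground truth (total 0.166 at the identity → 0.035 at
$t = 1$), which is the behaviour the fixed weights imply for real,
spatially coherent gland deformations.  This analysis was done before the
recovery experiment, and the world has not been revisited since.

The phantoms deliberately do not model TRUS probe physics, MRI pulse
sequences, shadowing, or anisotropic resolution.  A green recovery test
therefore establishes that the implementation can recover known smooth
diffeomorphic deformations across a synthetic modality gap at desk scale —
not clinical-grade accuracy on patient data.

## Numerical choices

* **Sampling** — trilinear interpolation with border clamping everywhere
  (images, labels use nearest); clamped positions get zero field gradient.
* **Integrator accuracy** — scaling and squaring repeatedly resamples the
  intermediate field, so its agreement with a 1024-step Euler integration
  of the same trilinearly-interpolated velocity degrades quadratically with
  amplitude: measured max interior error on 16³ grids ≈ 0.017 voxel at
  amplitude 1, ≈ 0.05 at amplitude 1.5, ≈ 0.09 at amplitude 2 (smoothness
  4).  Oracle-equivalence tests run at amplitude 1 where the bound has a
  3× margin; both integrators agree with the analytic matrix exponential to
  1e-4 on linear velocity fields, confirming the error is interpolation
  order, not implementation.
* **Jacobian** — central differences, one-voxel margin excluded.
* **Precision** — convolutions run in float32 via BLAS (one GEMM per kernel
  offset on a zero-padded copy); everything else is double.  Gradient
  checks against central differences pass at float32-noise tolerances.
* **Determinism** — all randomness (phantoms, initialization, shuffling)
  flows from explicit seeds through a local-RNG helper that restores the
  global RNG state; identical seeds give bit-identical phantoms and loss
  histories.  The compiled kernels are single-threaded and deterministic.
* **Robust metrics** — RDSC / RTRE definitions are not published for the
  reference leaderboard; prostreg uses trimmed means keeping the favorable
  75 % (largest DSC, smallest TRE), which reproduces the observable
  ordering RDSC ≥ DSC, RTRE ≤ TRE.  The registration success rate counts
  cases with TRE < 5 mm.  Both conventions are configurable.

## Desk-scale protocol and limitations

The default working grid is 32³ (the clinical 128³ is a configuration, not
a different code path).  The end-to-end recovery experiment trains the full
model — E-CMCA, VecInt, LSTM refinement, task-mask weighting — with Adam at
learning rate 0.001, batch size 1, on 20 seeded phantoms for 10 epochs
(200 iterations, the bottom of the intended 200–500 range, chosen to fit a
CPU-only time budget), and evaluates on 5 held-out phantoms.

What this budget does and does not achieve is itself a finding of the test
suite: held-out mask DSC improves (≈ 0.88 → 0.90, and further with more
iterations) and the integrated fields stay essentially fold-free, but
landmark TRE does *not* improve at this budget.  The Dice term supervises
only the gland boundary; the mutual-information term, whose job is interior
alignment, has a useful swing of only a few hundredths of a bit under TRUS
speckle — too shallow to steer the interior in a few hundred iterations
(and, on small cohorts with unlimited iterations, eventually exploitable by
warping intensities onto the speckle pattern).  The corresponding
acceptance test asserts the full stated criterion and is deliberately left
failing on the TRE clause rather than weakened; the clinical-scale
protocol behind the reference results is roughly 9000 GPU iterations on
~90 cases.

Known limitations: the LSTM sees a pseudo-temporal axis carved from a
static volume, not real 4D acquisitions; the task-mask subnet weights are
applied with stop-gradient (see above); and desk-scale budgets recover
boundary overlap but not landmark-level interior accuracy.
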