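---
title: "Registering serial-section EM stacks with serialflow"
author: "serialflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering serial-section EM stacks with serialflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialflow)
```

## The problem

Serial-section electron microscopy (ssEM) cuts a tissue block into 30--50 nm
sections that are imaged independently. Cutting introduces nonlinear in-plane
distortion and destroys axial continuity, so the sections must be registered
before neurites can be reconstructed through the volume. Two failure modes
dominate naive approaches:

* **Overregistration.** A registration driven by raw pixel similarity will
  happily warp away genuine morphological change between sections — a
  mitochondrion that grows from one section to the next is "corrected" back
  to its previous outline, and obliquely running neurites are straightened
  until they run perpendicular to the section plane.
* **Cumulative error.** Registering each section to its already-registered
  predecessor accumulates the per-pair error. Over tens of sections the
  drift can grow large enough that pairwise matching fails outright and the
  reconstructed neurite breaks.

`serialflow` implements a registration framework that addresses both: dense
pairwise flow driven by *feature* similarity rather than pixel similarity,
sequential registration between rigidly anchored endpoint sections, explicit
estimation and weighted removal of the accumulated error ("structural
regression"), and a split-and-chain strategy for long series. A synthetic-
data module generates phantoms and deformations with exact ground truth so
that every stage can be validated quantitatively.

## Pairwise flow

A dense backward displacement field $F$ maps reference coordinates to moving
coordinates: $\mathrm{ws}(p) = s(p + F(p))$, sampled bilinearly
(nearest-neighbour for label maps). `estimateFlow(estimator, moving,
reference)` returns the $F$ that aligns the moving section onto the
reference grid; `warpImage` applies it. The backward convention is asserted
throughout the tests.

Two estimators implement one interface:

* **Classical (`classicalFlowEstimator`)** — deterministic coarse-to-fine
  matching over a Gaussian pyramid (five octaves by default, downscale 2;
  the pyramid stops once a level would fall under 16 px a side, because
  smaller levels carry only ramp-like structure after descriptor smoothing
  and destabilise matching). At the coarsest level one confidence-gated
  cost-volume pass (search radius 4 px, box aggregation half-width 4 px)
  captures displacements beyond the differential pull-in range; every level
  then runs damped Lucas–Kanade refinements (4 iterations, damping 0.05,
  per-step clamp 2 px) of the upsampled coarser flow on the descriptor
  channels, with each increment Gaussian-smoothed (sigma 1.5 px) before
  composition. Matching features are a light two-scale descriptor bank
  (sigma 0.5 and 1 px, local contrast normalisation 1.5 px): the pyramid
  itself supplies coarse scales, so per-level features keep small support.
* **Learned (`learnedFlowEstimator`)** — a lightweight trainable estimator
  in the PWC style: a five-octave feature pyramid, a learnable linear mixing
  of the descriptor channels shared across levels, per-level local
  cost-volume matching decoded by a soft-argmax with learnable temperature,
  and a learnable increment-smoothing scale. With no automatic
  differentiation available, training uses simultaneous-perturbation
  stochastic approximation (SPSA): two loss evaluations per iteration
  estimate a stochastic gradient for the whole parameter vector. The model
  is deliberately small (~60 parameters) so this converges in ~100
  iterations on a single CPU.

### Unsupervised losses

Training minimises $L = L_{ph} + \lambda_s L_{smooth} + \lambda_a L_{aug}$:

* $L_{ph}$ — the *feature* photometric loss: the squared L2 difference
  between the descriptors of the reference section and the descriptors of
  the warped moving section, normalised by pixel and channel count.
  Features are recomputed from the warped pixels each evaluation; warping in
  feature space would not be equivalent and is never done. Measuring
  similarity in descriptor space is what lets the flow concentrate on
  *where* structure sits rather than *what it looks like*, reducing
  overregistration.
* $L_{smooth}$ — mean Charbonnier penalty
  ($\rho(t) = \sqrt{t^2 + \epsilon^2} - \epsilon$, $\epsilon = 10^{-3}$) of
  the first finite differences of both displacement planes.
* $L_{aug}$ — augmentation consistency: the flow predicted on the original
  pair is frozen as a pseudo-label, the pair is transformed by a small rigid
  + appearance augmentation, and the re-predicted flow must match the
  pseudo-label transported through the augmentation (masked Charbonnier).

The weights default to $\lambda_s = 50$ and $\lambda_a = 0.2$; with the
normalisations above these place the three terms on comparable scales for
64-px training pairs, and they are exposed in `trainFlowEstimator`.

## The descriptor

The per-pixel descriptor stands in for a learned thickness-insensitive
representation. It is a fixed, deterministic bank: local contrast
normalisation (Gaussian scale 4 px, epsilon relative to the image's global
standard deviation so the output is exactly invariant under positive affine
intensity rescale), followed by Gaussian-smoothed intensity and first
derivative pairs at sigma = 1, 2, 4 px, each channel standardised to zero
mean and unit variance per image. An adapter (`externalExtractor`) accepts
externally supplied descriptor models with the same interface, so a learned
representation can be dropped in without touching the pipeline. The
descriptor distance between two sections is the plain L2 norm over all
pixels and channels.

## Sequential registration and structural regression

For a short series $s_1 \dots s_n$ (`sequentialRegister`):

1. $\mathrm{ws}_1 = s_1$; the last section is placed rigidly,
   $\mathrm{ws}_n = T(s_n)$, with $T$ estimated from $(s_n, s_1)$ by
   keypoint matching + RANSAC (or supplied, e.g. by the long-series chain).
   The endpoints are never deformed afterwards; they fix the frame that
   compensation works against.
2. For $i = 2 \dots n-1$: $F_{i\to i-1} = E(s_i, \mathrm{ws}_{i-1})$ and
   $\mathrm{ws}_i = \phi_F(s_i)$, a single estimate-and-warp pass per
   section.

`runStructuralRegression` then removes the accumulated error. Within a short
series a neurite is approximately a cylinder, so the per-section
registration error keeps a consistent direction and accumulates:
$e_i = e_{i-1} + \Delta e_i$. The residual flow between the last two warped
sections approximates the total accumulated error $e_{n-1}$, because
$\mathrm{ws}_n$ sits on its rigid anchor while $\mathrm{ws}_{n-1}$ carries
nearly the whole drift. Each interior section is compensated by a fraction
of that flow:

* descriptor distances $d_i = \lVert \mathrm{feat}(\mathrm{ws}_i) -
  \mathrm{feat}(\mathrm{ws}_{i-1}) \rVert_2$, with $d_1 = 0$ so the
  reference section is never compensated (distances are computed on the
  *warped* sections, which are what compensation acts on);
* weights $w_i = \sum_{j\le i} d_j / \sum_{j\le n} d_j$ — nondecreasing,
  $w_n = 1$; identical distances give the exact linear ramp, and an
  all-zero distance vector falls back to that ramp;
* $\mathrm{final}_i = \phi_{w_i F}(\mathrm{ws}_i)$ for interior $i$;
  endpoints pass through untouched.

The sign convention is fixed by construction: the error flow is estimated
with the second-to-last warped section as moving and the anchor as
reference, so scaling it by $w_i$ moves each interior section toward its
proportional position along the anchored axis. On tilted-cylinder phantoms
with injected drift this choice reduces the centroid deviation from the
true axes; the opposite sign doubles it. Interior weights are *not*
re-normalised after excluding the endpoints: the printed formula is used as
is, which slightly under-compensates the interior but never overshoots the
anchor.

## Long series

Structural regression relies on the cylinder approximation, which only holds
over short spans, so a long series is split into `nSegments` short series
(`splitSeries`). The last section of each segment doubles as the first of
the next — the *benchmark* sections. The $n-1$ inter-section steps are
divided as equally as possible with earlier segments taking any remainder;
every interior index is covered exactly once and every benchmark exactly
twice. The benchmarks form a series of lower axial resolution that is
rigidly chained (`registerBenchmarkChain`: pairwise keypoint registration,
transforms composed into the first benchmark's frame), each segment is
registered and compensated with its endpoints placed by the chain, and the
results are restacked with each shared benchmark emitted once
(`registerLong`). How many segments to use is a user choice governed by how
fast error accumulates — more segments when accumulation is fast.

## Rigid registration

No keypoint machinery exists in the R ecosystem used here, so
`registerRigid` implements the standard recipe directly:
difference-of-Gaussian scale-space extrema (8 scales from sigma 1.6, 3x3x3
strict extremum test, contrast threshold 0.02, Hessian edge-ratio filter),
orientation assignment from a smoothed 36-bin gradient histogram with
parabolic refinement, orientation-normalised 4x4-cell x 8-bin gradient
descriptors (Gaussian-weighted, clamped at 0.2 and renormalised), ratio-test
matching (0.8), and a seeded two-point RANSAC (2000 iterations, 3 px inlier
threshold, at least 6 inliers) followed by Procrustes least squares on the
inliers. On textured synthetic sections a constructed 10-degree / (5, 3) px
transform is recovered to about 0.02 degrees and 0.04 px; pure-noise pairs
fail with an explicit error rather than returning a junk transform.

## Synthetic data: what it emulates, and what it does not

`tpsDeform` emulates section-preparation distortion: displacement vectors
drawn from a zero-mean normal distribution (`sigmaPx` per component) at
control locations uniform over the section, interpolated by a thin-plate
spline ($r^2 \log r$ basis plus affine part) and applied as a backward
field. Defaults (`nControl = 10`, `sigmaPx = 4`, `marginPx = 16`) produce
local distortions of a few pixels with occasional larger excursions.
Degenerate (collinear) control sets are resampled, as are fields whose map
compresses any neighbourhood by more than about 5:1 (Jacobian determinant
below 0.2): sections distort but do not fold or collapse in plane, and such
fields destroy texture instead of displacing it (a folded field also has no
inverse). `makeRegistrationPairs` deforms an oversized source and
centre-crops, mirroring the crop-after-warp protocol used for real section
volumes, so pair borders contain genuine texture; the stored ground truth is
the numerical inverse of the deformation field (`invertFlow`, fixed-point
iteration), i.e. exactly the field a perfect estimator would return.

`makePhantom` builds tilted-cylinder neurite phantoms: disks whose centres
move linearly with section index, rendered with a dark membrane ring and
bright interior over a background texture *shared by all sections* (tissue
around the neurites continues through the block — this is what gives
pairwise registration its correct anchor and makes straightening of tilted
neurites the dominant error mode, as in real serial registration).
Per-section Gaussian pixel noise is added on top. Tilt vectors are sampled
by magnitude and direction; `marginPx` keeps structures clear of the frame,
and should be widened by the expected cumulative shift when drift will be
injected afterwards. `injectDrift` translates section $i$ by the prefix sum
of per-section increments — the constructible analogue of cumulative
registration error.

What the phantoms do **not** emulate: section folds, cracks, dust, charging
or focus artifacts, anisotropic resolution changes, and true biological
morphology (disks are convex and rigid between sections apart from the
tilt). Passing the synthetic suite therefore demonstrates that the
machinery — warping, matching, weighting, chaining — is correct and that
compensation removes constructed drift under the cylinder model; it does not
by itself establish accuracy on real tissue with folds or strong
morphological turnover.

All randomness flows from a single integer seed through named substreams
(an internal L'Ecuyer-stream helper that never touches the global RNG
state), so stacks, fields and training runs are bit-reproducible.

## Numerical choices and degenerate inputs

* Warping: bilinear for intensities, nearest-neighbour for labels; strict
  constant fill outside the image domain (or edge clamp on request); the
  in-bounds validity mask is returned to callers, and NCC is computed on
  masked pixels so border fill does not depress scores.
* Zero flow short-circuits to the bit-identical input.
* Flow composition $F(p) = F_{outer}(p) + F_{inner}(p + F_{outer}(p))$ with
  edge-clamped bilinear sampling of the inner field.
* `computeWeights` rejects negative distances; an all-zero distance sum
  falls back to the linear ramp.
* TPS control configurations are resampled (up to 20 substreams) on rank
  deficiency or excessive compression; `sigmaPx = 0` returns the exact
  identity without solving.
* Top-k label selection breaks area ties by ascending label id; per-label
  Dice is aggregated over the whole 3-D extent of each selected structure.
* Image-sequence filenames with unpadded numeric suffixes are rejected
  rather than ordered heuristically.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale, chosen so the full suite completes in minutes on one CPU
while staying in the regime where the method's assumptions are exercised:
warp/TPS oracles on 5--24 px grids; flow recovery on 128--192 px textured
images (10 seeds); drift compensation on 16-section, 160-px phantoms with 5
neurites (10 seeds, median reported); the end-to-end labelled phantom at 16
sections of 160 px; long-series checks at 25--31 sections; training at 50
pairs of 64 px for 100 SPSA iterations with 20 held-out pairs. Real ssEM
volumes are orders of magnitude larger; nothing in the implementation is
size-specific, but runtimes scale accordingly.

## Known limitations

* The classical estimator's accuracy degrades where the true correspondence
  leaves the image frame; evaluation masks such pixels explicitly.
* SPSA training suits the deliberately small learned model; scaling the
  learned estimator to a full convolutional architecture would need a real
  autodiff backend and is out of scope.
* Section folds and cracks are unmodelled and unhandled — a fold violates
  the injectivity assumption that both the simulator and the compensation
  model rely on.
* The benchmark chain anchors each segment rigidly; residual nonrigid error
  at benchmarks is inherited by both adjacent segments.

## A worked example

```{r example, eval = FALSE}
library(serialflow)

# a 16-section tilted-neurite phantom with drift
ph <- makePhantom(phantomSpec(nSections = 16, rows = 160, cols = 160,
                              nNeurites = 5, tiltMax = 0.5, marginPx = 20,
                              seed = 1))
dr <- injectDrift(ph$stack, c(1, 0.5), labels = ph$labels)

# register sequentially between anchored endpoints, then compensate
est <- classicalFlowEstimator()
res <- sequentialRegister(dr$stack, est, endpointMode = "provided",
                          endpointRigid = RigidTransform(0, -dr$shifts[16, ]))
reg <- runStructuralRegression(res, estimator = est)
reg$model          # distances, weights, error-flow summary

# evaluate against the known ground truth
evaluateRegistration(ph$stack, reg$stack)
```
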