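# serialflow

Registration of serial-section electron microscopy (ssEM) stacks in R.

ssEM cuts tissue into 30–50 nm sections that are imaged independently;
registration must remove the nonlinear distortion introduced by sectioning
*without* erasing the genuine morphological change between sections, and
must keep per-pair errors from accumulating into bent or broken neurites.
`serialflow` is aimed at connectomics and volume-EM practitioners who need a
fully scriptable, dependency-light registration pipeline with quantitative
synthetic validation.

## Method

For a short series `s_1 … s_n`:

1. **Rigid endpoints.** `ws_1 = s_1`; `ws_n = T(s_n)` with `T` estimated
   from `(s_n, s_1)` by keypoint matching + seeded RANSAC. The endpoints
   are never deformed again — they anchor the frame.
2. **Sequential dense flow.** For `i = 2 … n−1`,
   `F_{i→i−1} = E(s_i, ws_{i−1})` and `ws_i = φ_F(s_i)` (backward warping).
   The estimator `E` matches *descriptor features*, not raw pixels, so
   natural morphological change is not warped away. Two backends share one
   interface: a deterministic coarse-to-fine pyramidal matcher
   (cost-volume initialisation + damped Lucas–Kanade refinement on
   descriptor channels) and a small trainable PWC-style estimator optimised
   with the unsupervised loss `L_ph + λ_s L_smooth + λ_a L_aug`, where
   `L_ph` is measured in descriptor space.
3. **Structural regression.** The residual flow between the last two warped
   sections approximates the total accumulated error. Descriptor distances
   `d_i = ‖feat(ws_i) − feat(ws_{i−1})‖₂` (with `d_1 = 0`) give weights
   `w_i = Σ_{j≤i} d_j / Σ_{j≤n} d_j`, and each interior section is
   compensated by `w_i` times the error flow. Within a short series a
   neurite is approximately a cylinder, which is what makes the error
   direction consistent and the weighted removal well-posed.
4. **Long series.** The stack is split into short series sharing single
   *benchmark* sections; benchmarks are rigidly chained into a global
   frame, each segment is registered and compensated between its chained
   endpoints, and the segments are restacked.

A synthetic-data module (thin-plate-spline deformations with exact inverse
fields, tilted-cylinder neurite phantoms, drift injection) and evaluation
metrics (masked NCC, per-label and top-k Dice, flow endpoint error) make
every stage testable without external data.

## Worked example

Register a 16-section tilted-neurite phantom with injected drift and
evaluate against the known ground truth:

```r
library(serialflow)

ph <- makePhantom(phantomSpec(nSections = 16, rows = 160, cols = 160,
                              nNeurites = 5, tiltMax = 0.5, marginPx = 20,
                              seed = 1))
dr <- injectDrift(ph$stack, c(1, 0.5), labels = ph$labels)

est <- classicalFlowEstimator()
res <- sequentialRegister(dr$stack, est, endpointMode = "provided",
                          endpointRigid = RigidTransform(0, -dr$shifts[16, ]))
reg <- runStructuralRegression(res, estimator = est)
reg$model
#> CumulativeErrorModel: n = 16, mean |error flow| = 1.738 px
#>   weights: 0.000 0.047 0.099 0.151 0.205 0.259 0.316 0.375 0.435 0.493
#>            0.561 0.628 0.692 0.755 0.818 1.000
```

The error flow (≈1.7 px on average) is the residual between the last two
warped sections — the estimate of the total accumulated error — and the
weights are the cumulative descriptor-distance fractions by which each
interior section is compensated (monotone, 0 at the reference, 1 at the
anchor). Evaluating against the ground-truth phantom:

```r
evaluateRegistration(ph$stack, dr$stack)$meanNcc    # 0.168  (input)
evaluateRegistration(ph$stack, reg$stack)$meanNcc   # 0.881  (registered)

labReg <- applyResultToLabels(res, dr$labels, model = reg$model)
topKDice(ph$labels, dr$labels)   # 0.301  (input)
topKDice(ph$labels, labReg)      # 0.941  (registered)
```

Registration plus compensation raises the mean NCC to ground truth from
0.17 to 0.88 and the neurite-label Dice overlap from 0.30 to 0.94.

Command-line wrappers over the same functions live in `inst/scripts/`
(`register.R`, `simulate.R`, `evaluate.R`).

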