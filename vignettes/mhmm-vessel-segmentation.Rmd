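---
title: "Pathological vessel segmentation with a multiple hidden Markov model"
author: "mhmmseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathological vessel segmentation with a multiple hidden Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mhmmseg)
```

## The problem and the model

Delineating a vessel in 3-D CT is hardest exactly where it matters
clinically: where calcified plaque sits on the wall, where a stenosis
narrows the lumen, and where the boundary has low contrast. Filters that
score how *tube-like* the local intensity structure is (Hessian vesselness)
find the bright lumen easily but respond to a hyperdense calcification at
least as strongly, and they say little about a low-contrast wall.

This package implements an axis-constrained classifier for that situation.
Its ingredients:

* **Cross-sectional rays.** Given a vessel axis (an ordered 3-D polyline,
  always an *input* — axis extraction is a separate problem), a
  cross-section is placed at every axis point, 72 rays are cast every 5° in
  the plane orthogonal to the axis, and 18 samples are taken along each ray
  at the native voxel pitch. A ray is an ordered walk from certain lumen out
  into certain background, which turns segmentation into sequence
  labelling.

* **Four tissue states.** Along a ray, tissue passes through lumen (T1),
  intima — the vessel boundary layer, 2–4 voxels thick depending on vessel
  scale — (T2), then possibly pathology (T3) and finally adventitia /
  background (T4), never returning inward. Pathology is modelled strictly
  outside the intima, reflecting how calcification relates to the wall.

* **Five multiscale vesselness features.** Sato, Frangi, Shikata, Li and
  Manniesing responses, each computed from Hessian eigenvalues
  (`lambda1 > lambda2 > lambda3`) at scales
  $s = 0.6 \cdot 2^{(w-1)/2}$ mm, $w = 1..6$ (matching vessel diameters of
  0.7–6 mm), and maximised voxelwise over scale. No single filter covers
  calcified, stenosed and low-contrast situations; the classifier draws on
  the redundancy of all five.

* **One discrete HMM per feature.** Feature values are quantized into
  $N = 10$ observation symbols and modelled by a four-state HMM
  $\varphi = (M, N, \pi, A, B)$ with $\pi = (1, 0, 0, 0)$: every ray starts
  on the axis, i.e. in the lumen. $B$ is $N \times M$, one emission column
  per state.

* **A precision-weighted mixture.** The per-feature HMMs are combined as
  $\Phi = \sum_k \alpha_k \varphi_k$ with
  $\alpha_k = \mathrm{Precision}_k / \sum_w \mathrm{Precision}_w$, where
  $\mathrm{Precision}_k = TP/(TP+FP)$ counts per-voxel vessel-positive
  decisions (decoded lumen or intima) of expert $k$ on its training rays.
  The detection posterior is the convex mixture
  $P(T \mid \Phi, F') = \sum_k \alpha_k P(T \mid \varphi_k, F'^k)$ of the
  forward–backward similarity maps, decoded per position by argmax; ties
  break toward the lower state index, which cannot change the final mask
  because lumen and intima are both "vessel".

* **Volumetric fusion.** A voxel may be touched by samples of many rays
  (and of neighbouring cross-sections). Each voxel receives the mean of all
  contributing 4-state posterior rows; the state with maximum mean
  similarity wins; the vessel mask is the union of the lumen and intima
  states; voxels no ray touches are background — the method is deliberately
  blind outside the axis neighbourhood.

## The synthetic phantoms

There is no public ground truth for pathological vessel boundaries, so the
package ships a seeded generator of CT-like vessel phantoms
(`phantom_config()`, `generate_phantom()`, `random_phantom_config()`):

* a tubular lumen along a straight, helical or bifurcating axis, radius
  0.35–3 mm (diameters 0.7–6 mm), with optional smooth stenosis dips;
* an intima/wall shell 2, 3 or 4 voxels thick, chosen from the local radius
  (2 below 1.5 mm, 3 up to 2.5 mm, 4 above);
* calcified plaque arcs — angular sectors of hyperdense tissue sitting
  directly on the outside of the wall;
* piecewise-constant tissue intensities, by default background 40,
  lumen 250, wall 120, calcification 1100 (ordered so plaque is hyperdense
  and the wall has low contrast), optional partial-volume blur
  (0.5 voxel Gaussian, off by default);
* additive i.i.d. Gaussian noise at variances 20/40/60/80 — 20 and 40 are
  ordinary CT noise, 60 a low-dose scan, 80 low-dose with large body
  habitus.

Tubes end flat at the terminal cross-section planes rather than with
spherical caps: in-plane rays can never visit voxels beyond the end planes,
so caps would be unconditional false negatives of the geometry rather than
information about the classifier. The random generator draws radii in
1.2–2.2 mm, a stenosis of up to 50 % with probability one half, and one
plaque arc (60–180°, 1–2.5 mm thick) with probability 0.75 — one vessel per
volume at abdominal-artery-like calibre, on a 48³ grid of 0.7 mm isotropic
voxels so the 18-sample rays (12 mm) always stay inside the volume.

What the phantoms do *not* emulate: branching trees with realistic
hemodynamic radii, curved plaques with internal texture, beam-hardening and
streak artefacts, anisotropic slice thickness, or patient-specific wall
appearance. Passing the test suite therefore shows the pipeline is a
faithful, deterministic implementation of the model under controlled
conditions — not that the accuracy figures transfer to clinical scans.

## Quantization and calibration

The binning follows an overlap-aware design: one bin below $a_1$, $K_1 = 5$
equal bins on $[a_1, a_2)$, $K_2 = 3$ on $[a_2, a_3)$, one overflow bin —
10 symbols per feature, all intervals left-closed. The per-feature
breakpoints (Sato 25/35/50, Frangi 15/20/30, Shikata 85/95/120, Li
40/45/55, Manniesing 15/25/45) live on a normalised 0–100 scale; resolution
is spent where the pathology distribution overlaps the intima
($[a_1,a_2)$) and lumen ($[a_2,a_3)$) distributions, which is where the
classifier must be sharpest. An optional mode re-fits the breakpoints from
the training histograms (`fit_overlap_scheme()`).

Raw responses must be mapped onto that scale, and here two facts bite.
First, responses are not comparable across volumes: the structureness scale
$\gamma$ is defined as half the *maximum* Hessian Frobenius norm of the
whole image, so a single calcification rescales every Frangi/Manniesing
response in its volume by an order of magnitude. The package therefore
standardizes each feature volume by its median response at the axis points
— the axis is known lumen, the same fact that fixes $\pi$ — before any
fixed calibration is applied; this is label-free at detection time. Second,
a single linear anchor cannot put four tissue classes into their designed
bands, and for heavy-tailed features it fails outright: the Li ratio
divides by $\lambda_1 \approx 0$ on the axis, so its 99.5th percentile sits
many orders of magnitude above the bulk and every overlap bin comes out
empty. The pipeline's default calibration (`fit_calibration_overlap()`) is
therefore a monotone piecewise-linear map through labelled training
quantiles — adventitia q90 $\to a_1$, intima median $\to$ centre of
$[a_1,a_2)$, lumen median $\to$ centre of $[a_2,a_3)$, pathology q25
$\to a_3$ — with control points that violate monotonicity dropped (classes
whose distributions invert simply share a band). A plain percentile anchor
(`fit_calibration()`, 99.5th percentile $\to$ 100) is kept for reference.

## Training

`mhmm()` trains the five experts independently. The default initialisation
is supervised: $A$ from labelled transition counts, $B$ from labelled
symbol counts (add-one smoothing), with ray labels derived by the stripping
rule — along each ray the last 2–4 vessel samples before the first
non-vessel sample are relabelled intima, rays not starting in the vessel
are excluded. This fixes the semantic identity of the four states, which an
unsupervised start cannot guarantee.

Baum-Welch refinement (`baum_welch()`: scaled forward–backward, $\pi$ held
fixed, smoothing floor $10^{-6}$, tol $10^{-6}$, up to 500 iterations) is
implemented, tested for EM monotonicity and parameter recovery, and
available for all three initialisation modes; non-supervised fits are
state-matched to the tissue labels afterwards by exhaustive permutation
(`match_states()`, $4! = 24$ candidates). The *pipeline default is zero
refinement iterations*: on phantom data EM reliably raises the likelihood
while drifting the states away from their tissue meaning (the intima
self-transition collapses toward a one-sample boundary state), which costs
15–25 Dice points on held-out phantoms. Likelihood and segmentation
accuracy are different objective functions; where labels exist, the
labelled counts are already the maximum-likelihood estimates of the
semantically constrained model.

## Numerical choices

* Gaussian-derivative Hessians are computed by separable correlation with
  spacing-aware kernels, truncated at $3.5\sigma$ and discretely calibrated
  (smoothing sums to 1, first derivative reproduces unit slope, second
  derivative reproduces curvature 2 on $x^2$); replicate-edge padding.
* Eigenvalues of the symmetric 3×3 Hessian come from the closed-form
  trigonometric solver, vectorised over all voxels and polished with two
  Newton steps on the characteristic polynomial (agreement with a dense
  solver to 1e-10); eigenvalues are sorted descending by value, ties broken
  deterministically.
* Multiscale comparison uses $s^2$-normalised (scale-normalised)
  eigenvalues; Shikata's own $s^2$ factor is exactly this normalisation, so
  all five features share one eigen-decomposition per scale. Each feature
  returns the magnitude of its formula's value after applying the printed
  eigen-sign guards, so bright tubes give large positive responses suitable
  for binning.
* The Manniesing response follows the original vessel-enhancing-diffusion
  filter: the Frangi-form factors times
  $\exp(-2c^2/(|\lambda_2|\lambda_3^2))$, which crushes weak second-order
  structure and tends to 1 for strong structure; $c$ defaults to $\gamma/2$
  per scale (the filter's own recommendation of an image-derived
  sensitivity), configurable. Shikata's intensity division uses intensities
  shifted to $\ge 1$ (CT values may be non-positive).
* Forward–backward uses per-position scaling; likelihood is exact, no
  underflow up to series length $10^4$. Decoding is the per-position
  argmax; an all-zero-likelihood step raises an error naming the position.
* Frames along the axis are parallel-transported (minimal rotation between
  consecutive tangents), not Frenet, to avoid flips at inflections. Rays
  that would leave the volume raise an error rather than being padded.
* ASD uses 6-connectivity boundary voxels and exact chunked pairwise
  distances (spacing-aware); DOC of two empty masks is 100 by convention.
* Degenerate conventions: $\gamma = 0$ (constant image) sets the
  structureness term to 1; precision with no positive calls is 0 with a
  warning; a paired t-test with identically zero differences gives $p = 1$,
  with constant non-zero differences $p = 0$.

## The noise-sweep experiment

`run_experiment()` re-creates the synthetic validation design at desk
scale: per noise level $\sigma^2 \in \{20, 40, 60, 80\}$ it trains on 15
randomised phantoms and scores 5 held-out phantoms (the original study used
240 + 240 volumes; the scaled-down counts are this package's default and
keep a full sweep under five minutes on one CPU). Training and testing use
noise-matched volumes; train and test seeds are disjoint by construction,
and a fixed config reproduces every output bit-identically.

## Known limitations

* **The outer wall is nearly feature-invisible.** On phantoms with a
  distinct low-contrast wall layer, the wall is locally a curved *plate*,
  and all five features are tube detectors — Frangi and Manniesing suppress
  plates explicitly through the $R_A$ ratio. The outer part of the wall
  therefore emits background-like symbols, and the per-position MAP decode
  places the vessel/adventitia switch at the survival-median of the learned
  geometric intima duration — systematically about a third of the wall
  thickness (≈0.5–0.9 mm) inside the true boundary. Fusing the *true* ray
  labels yields Dice 97–100, so geometry is not the limit; the fused
  classifier mask plateaus near Dice 70–75 with ASD ≈ 0.9 mm on these
  phantoms at every noise level, which also masks the expected monotone
  degradation with noise. On data whose ground-truth boundary coincides
  with the bright-tube edge (as in synthetic trees without a wall layer),
  this failure mode is absent.
* **Shikata under heavy noise.** The intensity division makes background
  noise responses exceed lumen responses at $\sigma^2 \ge 40$, so the
  Shikata expert degenerates toward a prior-only classifier — which the
  precision weighting then *rewards* (conservative decoding makes few false
  positives). Ablation shows the five-expert mixture still beats dropping
  it, so the design is kept.
* Geometric state durations are a poor model for a deterministic 2–4 voxel
  wall; a semi-Markov duration model would remove the boundary bias but is
  outside this model family.
* The method is axis-constrained by design: errors in the input axis
  propagate, and nothing is segmented beyond the rays' 12 mm reach.
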