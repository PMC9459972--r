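---
title: "Quantifying facial palsy from 3D landmarks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial palsy from 3D landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesym)
```

## The problem

Facial palsy paralyses one side of the face. Clinicians grade it visually,
which is subjective; a quantitative companion needs (a) a way to compare
captures of the same patient taken months apart — with different head pose,
camera distance and expression — and (b) statistics that turn a dense set of
facial landmarks into a small number of per-muscle asymmetry scores.

`facesym` works on 478-point 3D landmark sets as produced by modern face-mesh
detectors from plain RGB images (a 68-point compatibility mode is included).
Landmark indices are semantically stable across captures, so the `i`-th
landmark of two captures is the same anatomical point; that implicit
correspondence is what the registration quality measure and the symmetry
statistics exploit.

## Registration: the scale-sweep pipeline

Captures at different times differ by an (approximately) isotropic scale, a
rotation and a translation. `register_landmarks()` proceeds in three steps,
swept over landmark indices:

1. **Scale matching.** For sweep index `i`, the target cloud is scaled about
   the coordinate origin `O` by
   `scale_i = ||s_i - O|| / ||t_i - O||`,
   which equalizes the `i`-th landmark's distance from the origin between the
   two clouds. There is no universally correct `i` (any landmark may have
   moved between captures), which is exactly why the sweep exists.
2. **Global registration.** A coarse rigid transform is found without any
   initial guess: FPFH-style histograms of Darboux-frame angles over local
   neighbourhoods are matched between the clouds, and RANSAC over 3-point
   correspondence samples selects the candidate with the most inliers within
   a distance threshold, refit on its consensus set. The step is seeded and
   fully deterministic for a fixed `random_seed`.
3. **Point-to-plane ICP.** The coarse transform is refined by iterating
   nearest-neighbour correspondence and a linearized least-squares solve of
   `sum(((R s + t - t_c) . n_c)^2)` over target normals `n_c`, with the
   rotation re-orthonormalized each step.

Each sweep iteration yields a composite similarity transform (the rigid
refinement composed with the inverse of the target scaling, so that residuals
are expressed in the original target frame). It is scored by the **inlier
RMSE**, the root mean square of the per-index residuals
`e_i = ||T s_i - t_i||` over **all** `n` landmarks — no residual cutoff, the
printed formula taken literally. The transform with the smallest inlier RMSE
wins. Scoring in the original target frame keeps the sweep comparable across
scale factors; scoring against the scaled target would shrink residuals for
small factors and bias the selection.

Baseline methods are provided for benchmarking: point-to-point ICP and
point-to-plane ICP initialized by the centroid-difference transform (identity
rotation, translation `mean(s) - mean(t)` — the sign convention follows the
source-minus-target formula used in the registration literature this design
follows, even though it points from target to source; for the small
inter-capture translations of face-cropped landmarks the ICP basin easily
absorbs it), and global registration alone. All baselines run after the same
scale sweep.

### What the sweep can and cannot recover

With a translation between captures, no landmark generally satisfies
`||c R s_i + tau|| = c ||s_i||` exactly, so the best sweep index leaves a
relative scale error of roughly `(spacing of s_i . tau values) / ||s||^2` —
a few `1e-4` for 478 landmarks in centred, crop-normalized coordinates, and
about tenfold larger if the sweep is subsampled at stride 10. Noise-free
similarity disturbances are therefore recovered to several `1e-4` in
max-abs matrix error under the full sweep, not to machine precision — an
inherent property of per-landmark scale matching, and the reason the unit
tests assert exact recovery only for translation-free cases.

### Defaults

| parameter | default | rationale |
|---|---|---|
| `normals_k` | 12 | stable surface normals on 478-point clouds |
| `icp_max_iterations` | 100 | ample for quadratic convergence |
| `icp_convergence_tol` | 1e-12 | run Gauss-Newton to stationarity; costs ~2 extra iterations and makes results correspondence-limited, not iteration-limited |
| `icp_max_correspondence_distance` | 10% of target bbox diagonal | gates gross mismatches without starving the solver |
| `global_ransac_iterations` | 100000 cap | early exit at 99.9% confidence makes the typical run a handful of iterations |
| `global_feature_radius_scale` | 0.2 | feature neighbourhoods span several anatomical regions |
| `global_correspondence_distance_scale` | 0.05 | inlier gate for RANSAC scoring |
| `sweep_indices` | all | the full per-landmark sweep; strided subsets trade accuracy for time |
| `init_stride` | 1 | see below; larger values amortize the coarse step over the sweep |

Two implementation devices keep the full 478-index sweep affordable without
changing what is computed. First, ICP stops early when no iterate has
improved the correspondence RMSE for five consecutive iterations (noisy
correspondence sets can cycle between near-tied configurations) and returns
the best iterate; clean inputs still run to stationarity via the tolerance.
Second, with `init_stride = k > 1` the proposed pipeline runs global
registration only at every `k`-th sweep index; the indices in between
start ICP from the scale-adjusted best transform found so far. Consecutive
sweep indices differ only in a slightly different target scaling, so this
warm start sits well inside the ICP convergence basin; every index still
gets its own ICP refinement and enters the min-RMSE selection. The
baseline methods are not accelerated this way — their defining
initialization (the centroid transform) is applied at every index, so
benchmark comparisons measure the methods as defined. The
nearest-neighbour search inside ICP is a small compiled kernel, which is
what keeps the full-sweep baselines affordable. Ties in nearest-neighbour
correspondence break toward the lowest target index, and all stochastic
steps are seeded, so every result is reproducible.

## The three asymmetry statistics

The **midsagittal plane** passes through the midpoint of the two iris
landmarks with unit normal along the inter-iris vector (left to right). All
three statistics are computed per left/right landmark pair and averaged over
the pairs whose two members both belong to a muscle group; by convention
reports multiply by 100 (rounded to 6 decimals for the static statistics, 3
for movement).

* **Distance symmetry** `d_i = ||p_i^R - reflect(p_i^L)||`: reflect the left
  landmark across the plane and measure the distance to its right partner.
  0 is perfect symmetry; the statistic scales linearly with global size and
  is invariant to rigid motion (the plane is recomputed from the irises).
* **Angle symmetry** `cos(theta_i)` between the plane normal and the pair
  vector `p_i^R - p_i^L`. 1 is perfect symmetry, 0 is perpendicular. With
  the normal oriented left-to-right and pair vectors taken right-minus-left,
  symmetric faces score +1, matching the convention that reported values
  cluster near 100. Scale- and rigid-invariant. The aggregation averages
  per-pair cosines; a "flattened" variant (one cosine per group over
  concatenated vectors) is provided for comparison, but it mixes pair-vector
  magnitudes — by Cauchy–Schwarz it only reaches 100 when all pair vectors
  in a group are identical — so the per-pair mean is the headline statistic.
* **Movement asymmetry**: after registering the smile capture onto the
  neutral one (the neutral frame is the rest frame), per-side movement
  amounts are `m_{L,i} = ||s_i^L - n_i^L||` and likewise for the right; the
  per-pair score is `|m_L - m_R|`. The absolute value is taken before
  averaging because signed differences of opposing pairs within a muscle
  would cancel; the signed per-pair values remain in the report.

Pairs that straddle two muscle groups contribute to neither (they are
counted and reported); groups with no eligible pair return an explicit `NA`
marker — in the 68-point mode several muscles have no landmarks at all.

## The muscle-group topology

The analysis needs three structural resources: the left/right index pairing,
the midline indices, and the 17 muscle-group memberships (16 muscles plus
the nose tip, which is not a muscle but bends under palsy of its neighbours
and has useful signal). The grouping convention this package follows fixes
only the per-group landmark *counts* (e.g. Orbicularis Oculi 59, Orbicularis Oris 44, Nose Tip 32 in the
478-point mode); the actual index assignments are authored here, against the
package's own procedural template, under those exact cardinality
constraints. Groups with odd cardinality are realized as full pairs plus one
"half pair" whose mirror partner is ungrouped (anatomically preferable to
placing, say, Zygomaticus Major on the midline); Procerus is a midline
landmark. The bundled JSON resources are validated on every load: pairing
must be a disjoint involution, pairs plus midline must cover the index range
exactly, the iris indices must form a pair, and every group cardinality must
equal its published count. In the 68-point mode there are no iris landmarks,
so the outer eye-corner pair stands in (configurable in the resource).

## The synthetic face generator

Patient images cannot be redistributed, so the test bed is procedural. The
template places landmarks on a parametric frontal head surface: the right
half is authored, the left half is its exact mirror across `x = 0`, midline
landmarks sit on `x = 0`, and the cloud is centred so the centroid is the
coordinate origin used by scale matching. The template is therefore exactly
mirror-symmetric by construction: distance symmetry 0 and angle symmetry 1
are analytic fixed points, which the acceptance checks verify to 1e-9.

`apply_expression()` derives captures from the template, in order:

1. optional static asymmetry jitter on the palsy side (structural
   asymmetry every real face has);
2. a mirror-equivariant smile field — two Gaussian lobes anchored at the
   mouth corners pulling outward/upward, peak amplitude `g` (default 0.15
   model units, about 10% of the 1.5-unit face width — a pronounced smile),
   width 0.22 so the field covers the perioral muscle groups;
3. palsy: the displacement of landmarks on the affected side is multiplied
   by `alpha` in `[0, 1]` — multiplicative attenuation is the simplest
   mechanism that drives all three statistics monotonically;
4. isotropic Gaussian noise, parameterized by the RMS 3D displacement per
   landmark (per-coordinate sd `noise_sd/sqrt(3)`), so that a closed-form
   similarity fit to a noisy copy has RMSE approximately `noise_sd`;
5. an optional similarity disturbance (scale, rotation, translation)
   standing in for pose and camera changes between sessions.

The generator returns its ground truth (transform and clean displacement
field) so tests can compare pipeline output against known answers. The
registration benchmark draws scale from `[0.8, 1.25]` and rotations up to
25 degrees; translations are uniform in `[-0.05, 0.05]` per axis, reflecting
that face detectors emit crop-normalized coordinates in which inter-session
translation is a small residual.

What the generator does **not** emulate: detector-specific noise structure
(real landmark errors are anisotropic and spatially correlated), non-smile
expressions, occlusion, and genuinely asymmetric healthy anatomy beyond the
jitter term. Passing tests demonstrate the pipeline's correctness and its
response to controlled palsy, not detector robustness on real patients.

## Numerical choices and degenerate inputs

* Eq-level arithmetic (scale factors, RMSE, reflection, cosine) is exact to
  floating point and pinned by closed-form worked examples in the tests.
* A target landmark coinciding with the origin makes its scale factor
  undefined — a degenerate-landmark error. Coincident irises make the plane
  undefined. Zero-length pair vectors are flagged, warned about, and
  excluded from angle means.
* Collinear or near-coplanar clouds are rejected by global registration;
  RANSAC failure to find a 3-correspondence consensus raises a dedicated
  error, as does an empty ICP correspondence set.
* ICP runs to stationarity (`1e-12` relative RMSE change). On
  mirror-symmetric inputs the point-to-plane optimum under a symmetric
  correspondence set is itself mirror-symmetric; converging fully is what
  lets the perfect-symmetry movement check hold at 1e-9 when the
  registration equals the true pose. When two *different* shapes are
  registered (smile onto neutral), the selected transform can retain a
  ~1e-4-level asymmetry — the ICP objective is not the index-correspondence
  RMSE, and its local optima are set by discrete correspondence choices.
  This is a property of the method family, visible in the acceptance
  script's movement fixed-point value, which is computed through the full
  pipeline and is small but not zero.
* The movement tables of `run_longitudinal()` need at least two sessions
  (movement is tracked over time); a single-session manifest produces the
  symmetry tables only.

## Problem sizes used in the checks

The registration benchmark runs 20 seed-fixed cases with the full
478-index scale sweep and coarse initializations at every 10th index
(`init_stride = 10`); the longitudinal tests run the 68-point mode with a
stride-5 sweep. These sizes were chosen so the whole validation suite
completes comfortably on a laptop while leaving the sweep's selection
behaviour observable; real-patient analyses should use the defaults (full
sweep, per-index initialization).

## Known limitations

* Per-landmark scale matching cannot recover scale exactly under
  translation (see above); the residual is negligible against measurement
  noise but visible in noise-free synthetic checks.
* Absolute symmetry magnitudes depend on the coordinate normalization of
  the upstream detector; values are comparable within a subject across
  sessions (after registration to the reference session), not across
  detectors.
* No non-rigid registration: expression-induced shape change is deliberately
  not warped away, since the movement statistic measures exactly that
  change.
* The authored muscle-group assignment reproduces published cardinalities
  but is still a best-effort anatomical choice; the nose-tip region in
  particular has no published spatial extent beyond its landmark count.
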