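---
title: "Self-calibrating bundle adjustment for image-intensifier fluoroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-calibrating bundle adjustment for image-intensifier fluoroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorocal)
```

## The problem

Image-intensifier fluoroscopes warp their imagery: the curved input phosphor
produces pincushion (radial) distortion, component misalignment produces
decentering distortion, unequal sensor scaling produces affinity distortion,
the Earth's magnetic field produces an S-shaped spiral warp, and local
magnetic inhomogeneities produce localized warps. For qualitative reading
this hardly matters; for quantitative work — measuring diaphragm excursion,
navigating instruments, reconstructing 3D marker positions — a shift of
several pixels near the field edge is a first-order error.

`fluorocal` estimates all of these effects at once from images of a cheap
planar phantom: an acrylic plate carrying a regular grid of radiopaque beads,
imaged from a couple of dozen poses. No metrology-grade reference is needed;
the network of images calibrates itself.

## The model

Each observed image point follows the collinearity condition with additive
distortion. For object point $i$ in image $j$ of system $k$:

$$x_{ijk} = x_{P} - c\,\frac{U_{ij}}{W_{ij}} + \Delta x_{ijk}, \qquad
  y_{ijk} = y_{P} + c\,\frac{V_{ij}}{W_{ij}} + \Delta y_{ijk},$$

with camera-frame coordinates

$$(U, V, W)^T_{ij} = R_3(\kappa_j)\,R_2(\phi_j)\,R_1(\omega_j)\,
  (X_i - X^c_j,\; Y_i - Y^c_j,\; Z_i - Z^c_j)^T.$$

Here $(x_P, y_P)$ is the principal point, $c$ the principal distance (px),
$(X^c, Y^c, Z^c, \omega, \phi, \kappa)$ the exterior orientation of each
exposure, and $(\Delta x, \Delta y)$ the distortion correction evaluated at
reduced coordinates $\bar x = x - x_P$, $\bar y = y - y_P$,
$r^2 = \bar x^2 + \bar y^2$. The term pool is Brown-style:

| family | terms | x-shift | y-shift |
|---|---|---|---|
| radial | `k1,k2,k3` | $\bar x(k_1 r^2 + k_2 r^4 + k_3 r^6)$ | $\bar y(\cdot)$ |
| decentering | `p1,p2` | $p_1(r^2+2\bar x^2) + 2p_2\bar x\bar y$ | $2p_1\bar x\bar y + p_2(r^2+2\bar y^2)$ |
| affinity | `a1,a2` | $a_1\bar x + a_2\bar y$ | 0 |
| sigmoid | `s1` | $-s_1\bar y r^2$ | $+s_1\bar x r^2$ |
| local | `l1..l4` | $l_1\bar x^2\bar y + l_2\bar x\bar y^2$ | $l_3\bar x^2\bar y + l_4\bar x\bar y^2$ |

The five family names are standard in intensifier calibration; the
functional forms above are the usual photogrammetric choices for each named
effect — the sigmoid term is the tangential spiral characteristic of
magnetic-field warping of intensifier tubes, and the "local" pool is the
bivariate cubic monomials that absorb low-order residual warps. Clinical
intensifier systems typically need five to eight significant coefficients
from this pool.

**Where the distortion is evaluated.** Both forward simulation and the
adjustment linearization evaluate $\Delta$ at the distortion-free projected
position, with the full chain rule through
$\partial\Delta/\partial(\bar x,\bar y)$ in the Jacobian. Evaluating at
observed coordinates instead differs only at second order, but the
forward-consistent choice makes the analytic Jacobian agree with numerical
differentiation of the projection to 1e-6 relative — which the test suite
checks — and makes the estimator a plain Gauss–Newton on the projection
model.

## The adjustment

All parameters — exterior orientations, object coordinates, and the interior
block — are estimated in one weighted least-squares adjustment
(`estimate()`). Weights are $1/\sigma^2$ per observed coordinate with a
homoscedastic default of $\sigma = 0.2$ px, the centroiding precision of the
detection stage; no variance components are re-estimated.

**Datum.** A single free network has a seven-parameter gauge freedom
(translation, rotation, scale). Seven inner constraints on the object points
— three translations, three differential rotations about the centroid, one
scale, built from the initial coordinates and held fixed — are appended to
the normal equations by bordering. The bordered system is solved densely
after column equilibration; at the largest study size (~510 unknowns) a
sparse or Schur-reduced solver buys nothing and the full inverse is needed
anyway for the significance and correlation gates. Parameter covariances are
the top-left block of the bordered inverse scaled by the a posteriori
variance factor $\hat\sigma_0^2 = v^T P v / r$, with redundancy
$r = 2m - (6\,n_{img} + 3\,n_{pts} + n_{iop}) + 7$.

**Iteration.** Gauss–Newton with backtracking step halving whenever the
residual quadratic form grows; divergence is declared after three
consecutive growths. Convergence requires the largest update per class to
fall below 1e-4 px (interior), 1e-6 mm (coordinates), 1e-8 rad (angles), and
1e-4 px of image-space effect for distortion coefficients. Observations are
sorted canonically (image, then point) before assembly so results are
bit-identical under input reordering. An optional stall criterion
(`stall_tol`) ends iteration once the quadratic form stops changing; it is
off by default.

**Initial values.** Nominal bead coordinates (drill-pattern accuracy,
emulated as truth + U(±0.5 mm)) initialize the object points. Exterior
orientations come from a closed-form plane-based resection
(`initialize_eops()`): the near-planar points are expressed in their
best-fit plane, a normalized DLT estimates the plane-to-image homography,
and the homography is decomposed into rotation and camera position using the
nominal principal distance. A 3D DLT would be degenerate here — the target
is a plane.

**Term selection.** `select_terms()` implements greedy forward selection
from the twelve-term pool. A candidate is retained only if (i) its estimate
is at least ten times its standard deviation — the "standard deviation an
order of magnitude smaller than the parameter" criterion taken literally —
and (ii) its absolute correlation with the other interior parameters stays
at or below 0.95. Among qualifying candidates the largest variance-factor
reduction wins, with ties broken in family order (radial, decentering,
affinity, sigmoid, local — the physically dominant effects first). Candidate
fits are scored with an early-stall tolerance because a badly misspecified
model converges only linearly and the gates are ratios far from their
bounds; each retained set is immediately refit at full tolerance, so the
returned model is fully converged. Selection is deterministic given the
data.

## The synthetic study conditions

Clinical calibration imagery is not redistributable, so the package carries
a generator that reproduces the capture protocol in kind and is itself
first-class, tested code.

* **Target field**: 11 × 11 = 121 beads on a plane, 25.4 mm spacing
  (default plate 254 mm). The printed plate size of 25.4 mm with 121 beads
  cannot cover a 512 px intensifier field at millimetre-scale 3D errors; we
  read it as a units slip and keep the printed value available as the
  `"printed"` preset. Every reported quantity is a ratio or an image-space
  measure, so the plate scale cancels.
* **Stations**: the `F1` preset gives 22 stations — 14 parallel-translated
  poses across the field of view with alternating landscape/portrait roll,
  one 30°-tilted pose per quadrant with the frame rotated 90° in its stand
  between quadrants, and the same quadrant sweep from the 180°-flipped back
  face (X-rays see through the plate). `C1`/`C2` give 18. Principal distance
  1100 px, field-of-view radius 240 px, standoff set so the flat plate
  spans ~80% of the field; these system constants are not dictated by the
  protocol and were chosen once to land the clipped observation counts in
  the 1500–2700 range reported for such networks.
* **Visibility**: beads project into a circular field of view; beads closer
  than 6 px to the collimation edge are dropped as unmeasurable (their blob
  overlaps the mask).
* **Noise**: Gaussian white, 0.2 px per axis, matching the post-fit residual
  scale of the reported systems. All randomness is seeded.
* **Distortion magnitude**: `calibrate_distortion_magnitude()` scales a
  five-term reference shape (k1, p1, p2, a1 dominant, s1) until a
  no-distortion-term fit of noiseless data leaves the requested
  pre-correction RMS (1.27 px for the headline condition). This pins the
  simulation to the published pre-correction row rather than to an arbitrary
  coefficient choice. A fit, not the raw shift, is the yardstick because a
  free network absorbs a large share of raw distortion into deformed point
  and pose estimates.

What the generator does **not** emulate: X-ray physics (scatter, blur, dose,
gain), intensifier vignetting, bead-size variation, or pose-dependent
distortion drift. Passing tests therefore demonstrate the estimator and
pipeline on geometrically faithful data, not robustness to radiometric
artifacts of real systems.

## Detection

Rendered (or captured) rasters are reduced to labeled sub-pixel centroids in
four steps: the border-connected collimation surround is flattened to the
field level (so the mask edge cannot bias nearby beads); a grayscale
morphological closing minus the original (disc radius 5 px) enhances the
small dark beads; Otsu's rule thresholds the response and connected
components within 4–200 px² are kept; each region's boundary is traced at
the threshold level with sub-pixel linear interpolation and its shoelace
polygon centroid — the "average geometric centre of the shape" — is the
measurement. On noise-free renders this round-trips to ≤ 0.05 px RMS.

Grid identifiers are assigned by recovering the integer lattice structure:
local lattice vectors are estimated from neighbour offsets, indices grow
outward from a central seed with locally propagated vectors (robust to the
scale drift of tilted views and to corner clipping), and the indexed set is
registered to the nominal grid over the eight square-lattice symmetries and
all feasible offsets, scored by a projective fit. A square bead grid carries
no orientation cue — every lattice symmetry yields an equally perfect
projective assignment — so absolute identifiers require a few operator seed
pairs (`seed_pairs`), exactly the "semi-automatic" role manual labeling
plays in practice; automatic mode resolves the tie deterministically.

## Correction and assessment

`distortion_field()` evaluates the fitted shift at every pixel;
`correct_image()` resamples by inverse mapping (output pixel sampled at its
distorted source position, bilinear by default, nearest-neighbour for label
imagery) with out-of-source pixels masked. `checkerboard_difference()`
reproduces the standard visualization: a virtual checkerboard minus its
field-warped self. Video volumes are stacked frame lists with y–t slicing
for motion profiles.

Accuracy is reported the way calibration reports tabulate it:
`image_rms()` per axis, the variance factor, integer percent improvements,
and a held-out 3D test — 25% of stations (seeded split) are reconstructed
with the interior model frozen (terms zeroed vs. calibrated), and inter-bead
distances are compared against the surveyed truth over all unique pairs.
Distances are datum-free, so this comparison needs no alignment step; using
all pairs rather than neighbours only maximizes the test surface.

## Numerical choices and limitations

* Projection denominators below 1e-9 mm raise a point-at-infinity condition.
* Undistortion is a fixed-point iteration with a 1e-6 px round-trip
  tolerance; it diverges only for fields far beyond intensifier magnitudes.
* The correlation gate is evaluated over the interior block only; exterior
  correlations are controlled by the convergent network design, not by
  selection.
* Problem sizes in the test suite: the full 22-station, 121-bead condition
  backs the headline checks; per-operation tests run on an 8-station, 7×7
  twin, and the hundred-replicate coverage check runs on a 12-station, 9×9
  twin. These sizes were chosen so the whole suite exercises every code
  path at full fidelity where it matters.
* Known limitations: no robust/outlier weighting (clean phantom imagery is
  assumed), no variance-component estimation, no pose-dependent distortion
  model (the fitted field is assumed stationary over the capture session),
  and no physics-based raster simulation.

## A worked run

```{r, eval = FALSE}
sc <- simulate_scenario("F1", target_pre_rms = 1.27, noise_sigma = 0.2,
                        seed = 1)
pre <- estimate(sc$network, character(0))
sel <- select_terms(sc$network)
glance(pre)       # pre-correction fit
glance(sel$fit)   # post-correction fit
tidy(sel$fit)     # interior estimates with significance
build_report(
  pre = c(image_rms(pre$residuals), vf = pre$variance_factor),
  post = c(image_rms(sel$fit$residuals), vf = sel$fit$variance_factor))
```

The same computation, end to end with the held-out 3D assessment, is what
`scripts/acceptance.R` runs.
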