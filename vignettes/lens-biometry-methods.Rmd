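---
title: "Measuring the crystalline lens in volumetric MRI: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the crystalline lens in volumetric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lensmetry` measures the crystalline lens in 3D volumetric images of fixed
eyes and provides a synthetic bench that makes every stage of the chain
verifiable against known ground truth. This vignette is the package's
account of its science: the models, the algorithms, the tunable parameters,
and the choices made where the design was genuinely open.

## 1. The lens model

A biconvex lens is modelled as the union of two spherical caps — anterior
radius of curvature $R_a$, posterior radius $R_p$ — sharing a base circle
of radius $r_e$ in the equatorial plane. With axial thickness $T$ the cap
heights satisfy

$$h_a + h_p = T, \qquad r_e^2 = h_a(2R_a - h_a) = h_p(2R_p - h_p),$$

with the closed form $h_a = T(2R_p - T) / (2(R_a + R_p - T))$ and volume
$V = \tfrac{\pi}{3}\left[h_a^2(3R_a - h_a) + h_p^2(3R_p - h_p)\right]$.
`solve_biconvex_geometry()` implements this, rejecting infeasible
combinations (caps that cannot close on a shared base circle) with a typed
condition. The degenerate case $R_a = R_p = T/2$ is a full sphere and is
handled by its symmetric limit.

**Fixation artifact.** Paraformaldehyde fixation dehydrates lens tissue,
most strongly in the central anterior cortex, which warps a fraction of
lenses into a "kidney" shape with a central concave anterior depression.
We model the artifact as a posterior displacement of the anterior surface by
$D\,e^{-\theta^2/(2\sigma_\theta^2)}$ — $\theta$ the angle from the
anterior axis measured at the equatorial-plane center — followed by an
optional global isotropic shrink $s \in (0, 1]$. The functional form is this
package's choice (the underlying biology only motivates *localized anterior*
shrinkage): it is smooth, one-parameter in depth, displaces the anterior
pole inward by exactly $D$, and leaves the axial extent $s(T - D)$ in closed
form. Depressions with $D \ge 0.8\,h_a s$ are flagged: beyond that the
surface stops being a simple closed star-shaped boundary, which the mesh
stage assumes.

*Width default.* $\sigma_\theta = 0.35$ rad. Two opposing constraints fix
this: the depression must be wide enough to be *resolvable* at the 0.115 mm
scanning resolution (its floor spans several voxels; much narrower pits
cannot be traced by any sub-voxel method because the partial-volume point
spread fills them in), yet narrow enough to read as a distinct local
concavity rather than whole-cap flattening. The value is a generator
default, deliberately user-tunable, not an estimate of the real artifact's
width — no quantitative measurement of the real depression geometry exists
to calibrate against.

## 2. The phantom bench

`voxelize_eye()` renders an eye (spheroidal scleral shell, humor, lens) onto
an isotropic grid by supersampled occupancy averaging: voxel centers are
classified, voxels on a tissue interface are averaged over $5^3$ subsamples
(interior voxels need no averaging, which keeps the render cheap). Rician
magnitude noise is added at a stated SNR (mean lens intensity over the
Gaussian channel sigma) — the correct noise family for magnitude MR images.
Supersampling at 3 was found to leave occupancy-quantization ripples
(~1/27 steps) that are phase-coherent where the surface runs parallel to
voxel layers, visibly distorting the curvature fits; 5 is the default for
that reason.

`assemble_array()` reproduces the scanning layout: four 2×2 layers in a
cylindrical agarose block, exactly one eye inverted as the identity anchor.
`crop_eyes()` undoes the layout automatically: global Otsu threshold,
26-connected labeling of the sixteen globe interiors, grid clustering,
per-eye orientation from the offset of the bright lens from the globe
centroid, and an in-plane rotation (plus optional upside-down flip) search
that places the inverted eye in its reference cell.

## 3. Segmentation

The volume is pre-smoothed with a Gaussian kernel of 0.1 mm. We read
"kernel size" as the Gaussian $\sigma$ (the conservative reading; a
`kernel_is_fwhm` switch gives the other). Smoothing is applied per-eye
after cropping; whether the original workflow smoothed before or after
cropping is not determinable, and the operation commutes with cropping up
to a boundary margin.

The lens is flood-filled as the 26-connected supra-threshold component
containing a seed (the operator's click, or automatically the brightest
centroid-proximal voxel of the main bright component). The threshold comes
from Otsu's method inside a spherical ROI around the seed (default radius
1.5× the expected lens equatorial radius), where the lens/humor histogram
is strongly bimodal; a global-Otsu mode exists. A degenerate (effectively
unimodal) ROI falls back to the midpoint with a warning. 26-connectivity
resists noise fragmentation; a component touching the volume border is
reported as a clipped lens rather than silently truncated.

Mask repair automates the manual slice-by-slice editing of the original
workflow: morphological closing with a 2-voxel ball (removes SNR-scale
pinholes without bridging lens to sclera), 2D hole filling in every slice,
3D cavity filling, and reduction to the largest component; the composite is
idempotent. **The hole-fill slices must not be perpendicular to the optical
axis**: in such slices a kidney depression is enclosed in-plane and would be
"repaired" away as if it were an unfilled region — the depression is only
open toward the anterior, i.e. along the axis. The default slice normal is
grid axis 1, orthogonal to the package's eyes-along-z convention.

## 4. Shrink-wrap meshing

The template is an octahedron subdivided six times and projected to the unit
sphere: $8 \cdot 4^6 = 32{,}768$ triangles, 16,386 vertices, 49,152 edges, a
closed consistently-oriented 2-manifold by construction (audited by
`check_mesh()`). Each template vertex direction is traced from the mask
centroid outward-in to the outermost 0.5-occupancy crossing of the softened
(1-voxel Gaussian) binary mask; rays crossing the boundary more than once
(non-star-shaped masks) are counted and reported. Kidney depressions within
the generator's feasible bound remain star-shaped about the centroid.

**Sub-voxel refinement.** A binary mask quantizes the surface to voxel
plateaus and rings; after softening, phase-coherent ripples of tens of
micrometres remain — harmless for volume, fatal for curvature, which needs
sagitta accuracy of a few micrometres over the fitting cap. When the
grayscale volume is available (the normal pipeline case), each vertex is
therefore refined against the partial-volume intensity profile: the profile
in a window along the ray is normalized to occupancy using the two class
plateau levels estimated from the ROI histogram, and the surface is placed
where the *integrated* occupancy is conserved. Unlike a level crossing on an
interpolated profile, the integral is unbiased for any symmetric transition
regardless of voxel phase. The window (±3.5 voxels) must cover the full
smoothed transition plus plateau bands and is recentered over two passes. A
final pass refines along each vertex *normal*: integrating obliquely to the
surface acquires an obliquity-dependent bias, and centroid rays are oblique
everywhere except at the poles. The binary-mask path (no grayscale volume)
remains available and is exact to the voxel scale.

Vertex smoothing is Taubin's $\lambda|\mu$ two-step
($\lambda = 0.33, \mu = -0.34$, 10 iterations), which removes polygonal
undulations without the volume shrinkage of plain Laplacian smoothing
(available via `method = "laplacian"`). On a sphere, vertices may slide
tangentially (mesh regularization) while the shape stays put.

## 5. Biometry

The optical axis runs from a user-supplied anterior-surface point through
the area-weighted surface centroid (the measurement must be definable from
the mesh alone). In automatic mode the lens' short principal axis is used,
oriented by a hint, and the anterior anchor is where that axis meets the
surface — deliberately *not* the farthest vertex, which for a kidney lens
sits on the depression rim and would tilt the axis.

* **Axial thickness**: distance between the two axis–mesh intersections
  (Möller–Trumbore over all faces; an axis crossing the surface more than
  twice, e.g. through a severely ragged depression, is an error, not a
  number).
* **Equatorial diameter**: maximum caliper width of the vertices projected
  onto the plane orthogonal to the axis — the plane-position-independent
  reading of "maximum width in a plane orthogonal to the axis".
* **Volume**: divergence theorem over the closed mesh (signed tetrahedra);
  an inward orientation is detected and corrected with a warning. The
  voxel-count volume of the mask is reported alongside.
* **Radii of curvature**: least squares over vertices in a cone about the
  axis, $\min \sum_i (\lVert v_i - c\rVert - r)^2$ with the center
  constrained to the axis line, minimized by Powell's direction-set method
  (no derivatives; Brent line searches; the center coordinate is scanned
  coarsely first, because the algebraic Kåsa start collapses on shallow
  noisy caps). "An area subtending 60° to the axis" is read as the
  *half*-angle (vertices within 60° of the axis, `cone_full_angle = 120`):
  at 0.115 mm voxels and SNR 15 the 30°-half-angle patch offers ~0.6 mm of
  lateral lever arm, and the spatially correlated few-µm surface noise then
  limits radius recovery to ~±0.4 mm — worse than the package's own
  accuracy targets; the wide cap fixes the lever arm, and the narrow
  reading remains available (`cone_full_angle = 60`). A free-center fit is
  provided for sensitivity analysis.
* **Kidney classification**: the depression depth is the maximum inward
  deviation of near-axis vertices (within 15°) from a *reference* sphere
  fitted to the outer anterior annulus (50–75° from the axis), with a
  robust re-fit that excludes any vertices still deviating inward. The
  reference must be anchored on clean surface: a depression's smooth
  shoulder extends far beyond its visually obvious core, and a sphere
  fitted through the shoulder tilts and extrapolates to a large error at
  the pole. The default decision threshold is 0.15 mm (≈1.3 voxels): above
  surface-localization noise, below visually obvious depressions. The
  threshold is a choice, not a discovered boundary — the artifact is
  continuous, and no objective split can be sharp.

## 6. The cohort simulator

`simulate_cohort()` draws nine in vivo traits (lens volume, equatorial
diameter, thickness; axial length, corneal radius, eye weight, eye
equatorial diameter, body mass, body length) from a Gaussian copula whose
target Spearman matrix is converted to latent Pearson correlations via
$2\sin(\pi\rho/6)$. Marginal means and SDs default to values plausible for
3-week-old chicks (e.g. thickness 2.35 ± 0.08 mm, volume 26.4 ± 1.2 mm³).
Non-positive-semi-definite targets are rejected, naming the offending
eigenvalue.

**Geometry closure.** Cap geometry nearly determines volume from diameter
and thickness, so the three lens traits cannot be specified independently.
The generator honors the sampled volume and thickness exactly and lets the
equatorial diameter absorb the (narrow) feasibility window: for anterior
cap heights $h_a \in [0.15\,T, 0.5\,T]$ (anterior surface flatter),
$r_e^2(h_a) = (6V/\pi - h_a^3 - (T-h_a)^3)/(3T)$, and the sampled radius is
clamped into that window before solving for $h_a$. Every bird's recorded
ground truth is therefore exactly cap-consistent. One visible consequence:
at fixed volume a thicker two-cap lens must be narrower, so the
diameter–thickness entry of the *realized* correlation structure is
negative. The default target matrix records the self-consistent
(model-implied) equatorial-diameter row, measured from the generator at
large n, so that the published default is recoverable from generated
cohorts; the surface curvatures, which derive from the residual
volume-vs-shape freedom, stay essentially uncorrelated with eye and body
size — the qualitative structure the simulator exists to emulate.

**Batch structure.** Birds hatch in blocks of about 20; each hatch draws a
mean depression depth from a two-component mixture (probability 0.35 of a
strongly affected hatch, mean 0.35 mm; otherwise a folded normal near
0.03 mm), and birds add N(0, 0.07 mm) noise, truncated at zero and at the
star-shape bound. This reproduces the all-or-mostly-affected hatch pattern
and an overall kidney prevalence near one third under defaults. Scan
groups are assigned by randomizing the scanning order into arrays of 16,
so they carry no artifact signal by construction. In vivo ultrasound
thickness is the pre-shrinkage $T$ plus N(0, 0.04 mm) measurement noise;
the model-implied ex vivo MRI thickness is $s(T - D)$ plus N(0, 0.02 mm) —
as the shrinkage variance grows, the MRI-vs-ultrasound correlation
degrades, the mean MRI thickness drops below the ultrasound mean, and the
hatch (but not scan-group) batch test lights up.

**What the simulator does not emulate:** pulse-sequence physics, bias
fields, susceptibility artifacts around agarose bubbles, scleral/retinal
layering, off-axis lens tilt within the globe, and any real-data joint
distribution beyond rank correlations. Passing tests on phantoms therefore
demonstrate the *measurement chain's* correctness on the modelled geometry
and noise, not performance on arbitrary real scans.

## 7. Statistics layer

Spearman's rho uses midranks; p-values come from exhaustive permutation
enumeration below n = 10 and the t approximation otherwise. Normality
screening defaults to the Lilliefors variant (parameters estimated from the
sample — the situation in trait screening); the fixed-parameter classical
KS test is available. Batch effects on the kidney outcome are tested by
the likelihood-ratio test of `outcome ~ factor` against intercept-only
(deviance difference on levels−1 df): well-defined for many-level factors
with sparse cells, unlike per-level Wald statistics; levels with complete
separation are reported with a warning (the LRT itself remains finite). No
multiplicity adjustment is applied by default, mirroring raw-p reporting
at 0.05; a Holm option exists. Missing data are handled by
pairwise-complete deletion.

The repeat-scan table correlates two scans' measurements per trait
(thickness, diameter, volume, both radii), overall and for eyes non-kidney
in both scans, with paired t tests alongside. The validation harness
mirrors the repeat-scan protocol: 19 eyes sampled from a full simulated
cohort, re-embedded between scans (small random tilt, sub-voxel shift) and
re-voxelized with independent noise. One caveat the harness makes explicit:
on phantoms all five traits are repeatable with r between roughly 0.90 and
0.99 at n = 19 — ties within Spearman sampling error — because the bench
renders the lens equator at clean contrast. On real scans the
diameter/volume repeatability is degraded by equatorial segmentation
ambiguity (the lens–zonule interface), a noise source outside the phantom
module's scope; phantom thickness noise is instead dominated by the kidney
dent floor. Rank orderings among the phantom r values should therefore not
be read as predictions about real data.

## 8. Problem sizes and numerical choices

The validation suite runs entirely on synthetic data at the study's imaging
conditions (0.115 mm isotropic voxels, SNR 15, 32,768-face meshes):
20-phantom recovery batches, 10+10 labeled kidney sets, a 6-point
depression sweep, 19-eye repeat-scan pairs, cohorts of 500 (25 hatches of
20) with 100 replicates for the batch tests, 10⁷-point Monte-Carlo volume
oracles, and 1000-replicate null calibrations — sizes chosen so the whole
bench completes on a single CPU in well under an hour while keeping
Monte-Carlo error far below the tolerances being checked. Convergence
tolerances: sphere-fit parameter step 10⁻⁶ mm; shared-base geometry
residual 10⁻¹⁰ mm²; ray-crossing sampling 0.4 voxel with linear
interpolation; refinement sampling 0.1 voxel. Degenerate inputs error
loudly (empty masks, constant volumes, unimodal ROIs fall back with a
warning, separated logistic levels warn).

## 9. Known limitations

* The radial wrap assumes the mask is star-shaped about its centroid;
  extreme depressions violate this and are reported, not silently wrapped.
* Depression depth is measured against a fitted reference sphere; for
  depths approaching the feasible bound the floor of the pit is
  PSF-limited and the estimate is biased low by a few hundredths of a mm.
* The equatorial diameter inherits the bias of a maximum statistic and a
  small inward bias (~0.1 mm) from corner rounding at the equator under
  smoothing; both are well inside its repeat-scan noise.
* Real-scan performance depends on contrast and artifacts the bench does
  not model; the automatic seed/threshold/layout steps are conveniences
  with manual overrides, not guarantees.
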