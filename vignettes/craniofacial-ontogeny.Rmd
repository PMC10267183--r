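---
title: "Modelling early craniofacial growth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling early craniofacial growth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Over the first 48 months of life the human cranium roughly doubles its
linear dimensions while changing shape: the neurocranium, inflated early by
the fast-growing brain, shrinks *relative* to a face that keeps expanding
with the nasal airway and the oral cavity. Quantifying this joint change in
size and shape — and relating it to the volumes of the cavities that house
brain, eyes, airway and tongue — is the domain of geometric morphometrics:
configurations of named 3D landmarks, surfaces parameterised by sliding
semilandmarks, Procrustes superimposition, and multivariate statistics on
the resulting shape variables.

Clinical CT cohorts of healthy infants cannot be redistributed, so this
package pairs the complete analysis machinery with a **synthetic skull
generator** whose ground truth is known in closed form. Every stage —
semilandmark templating and sliding, generalized Procrustes analysis (GPA),
form-space PCA, ontogenetic-trajectory regressions and angle tests,
two-block partial least squares (PLS), craniometric indices and cavity
volumetry — is exercised and validated end-to-end against that truth.

# The synthetic cohort model

## Geometry

A specimen is a closed triaxial-ellipsoid outer shell (subdivided icosphere,
vertices exactly on the ellipsoid) carrying five internal ellipsoid cavity
surfaces: intracranial (ICV), left and right orbital (LOV/ROV), nasal (NCV)
and upper intraoral (UIV). Each cavity is opened by a small polar aperture
(its anatomical communication — foramen magnum, orbital aperture, nares,
oral opening), so cavity volumetry must genuinely close the surface before
integrating. Every volume and area has a closed form, which supplies exact
oracles for the measurement code.

An earlier sketch fused a frontal prism onto the shell to model the face;
it was dropped in favour of a single ellipsoid with facial / calvarial /
lower-occipital *patch labels*, because boolean surface fusion cannot be
kept watertight without CSG machinery and a single quadric keeps the
shell-volume oracle closed-form. Anatomical realism (sutures, fontanelles,
sinuses, teeth) is explicitly out of scope; the generator's job is to give
the pipeline the right *structure*, not the right anatomy. One consequence
worth knowing: the cavity ellipsoids are allowed to interpenetrate slightly
at some ages. Only shell containment is asserted; cavity volumes are
defined per-cavity and all oracles remain exact.

The 88-landmark roster uses classical craniometric names (Glabella, Basion,
Euryon, Zygion, ...) placed at analytic features: shell poles and equator
points, and cavity aperture rims (orbital rim, nasal aperture, palate,
foramen magnum). The Euryon pair carries a `gpa_excluded` flag: maximum
cranial breadth remains measurable, but those two points do not enter
superimposition. The roster and the 47-entry dimension table ship as
editable CSVs under `inst/extdata/`, file names prefixed `synthetic_`
because they are stand-ins keyed to the dimension numbers and names the
source literature states (1 maximum cranial breadth, 2 maximum cranial
length, 3 circumference, 4 basion–bregma height, 14/15 foramen magnum,
16 upper facial height, 19 bizygomatic breadth, 24/26 nasal, 31/33 left
orbital, 45/47 palatal), with classical names filling the remainder.

## Growth

All curves are functions of age in months (1 month = 30.41 days):

* **Centroid size** `cs(t) = s0 + s1 (1 − e^{−t/τ})`, defaults
  `s0 = 550 mm`, `s1 = 210 mm`, `τ = 9 mo`: fast growth in the first year
  that then decelerates, a ~1.38-fold size increase from birth to 48
  months.
* **ICV, LOV**: logistic `V_max / (1 + e^{−k (t − t0)})` — rapid early
  expansion that saturates after ~18 months (defaults: ICV
  `V_max = 9·10^5 mm³, k = 0.15, t0 = 5`; LOV `2.6·10^4, 0.12, −2.6`).
* **NCV, UIV**: affine `a + b t` — steady linear growth throughout
  (defaults `10^4 + 450 t` and `2·10^4 + 600 t` mm³).

A specimen at age `t` and sex `g` is produced from the 12-month female
template by

`U(t) = normalise( U₀ + λ · v_g · (ln cs(t) sₘ(g) − ln cs₀) ) · cs(t) sₘ(g)`

where `U₀` is the template unit shape, `v_g` a unit-norm allometric
displacement field, `λ` the allometric scale, and `sₘ(M) = 1.05` the male
size-for-age offset (`sₘ(F) = 1`). The field `v` expands the anterior
(facial) region radially under a smooth logistic weight, so growing
specimens gain relative facial size — the canonical infant-to-child shape
change. Both sexes share `v` by default (**heterochrony by size only**); a
`trajectory_divergence_deg` knob rotates the male field toward an
orthogonalised superior-expansion field purely for power studies of the
angle test. Cavity semi-axes are set at every age so the analytic volumes
equal the growth curves *exactly* — the generator's `true_volumes` are the
curves themselves, which is what makes volume-recovery tests sharp.

Gaussian landmark noise (`landmark_noise_sd`, default 1.5 mm, landmarks
only — the mesh stays noise-free) stands in for digitisation error *plus*
individual biological variation; the generator has no separate
individual-shape term. The defaults were chosen to land the cohort in the
regime the source clinical literature describes, before any acceptance
checks were written: shape-on-size R² ≈ 0.15, form-on-size R² ≈ 0.85, form
PC1 carrying ≈ 85% of variance with a Ln(CS) loading ≈ 0.98, and
`allometric_scale = 0.28` is what places shape R² there given the noise.

## What the generator does not emulate

Real crania are asymmetric, have individual shape variation uncorrelated
with size, non-Gaussian digitisation error, sutures and fontanelles that
perforate the calvarium, and cavities that are nothing like ellipsoids.
Passing the recovery and calibration tests therefore shows the *pipeline*
is correct and calibrated under known truth; it does not validate any
biological claim about real growth, and effect sizes measured on synthetic
cohorts transfer to clinical data only qualitatively.

# Statistical conventions

* **GPA**: all configurations are scaled to unit centroid size (full
  Procrustes — size is removed and re-attached downstream as the Ln(CS)
  column of the form matrix). Rotations are proper; mirrored solutions are
  anatomically invalid. Convergence when the mean changes by < 1e-10
  (relative), at most 100 iterations. Because a Procrustes solution is only
  defined up to one global rotation, the converged sample is rotated into a
  canonical frame (principal axes of the mean, per-axis signs anchored to
  the lowest-index dominant landmark), making the output invariant to
  similarity transforms of the input — a property the tests assert
  directly.
* **Form matrix**: flattened shape coordinates with one appended `ln_cs`
  column, unweighted. PCA is covariance-based throughout.
* **Multivariate regression** of a matrix on one covariate reports the
  trace R²: `1 − tr(residual SSQ)/tr(total SSQ)`. Permutation p-values
  shuffle the covariate and use add-one smoothing
  `(1 + #{R²* ≥ R²})/(1 + n_perm)`, so 1000 permutations can report 0.001
  but never 0. Rows are sorted by covariate internally so p-values do not
  depend on specimen order.
* **Trajectory angles** between groups are the arc-cosines of dot products
  of unit coefficient vectors. The null ("shared trajectory") is built by
  reshuffling group labels **within covariate-rank strata** (default 8
  strata). Two simpler schemes were measured and rejected during
  development: plain label permutation is anticonservative once the sexes
  differ in size-for-age (the permuted groups mix the two size
  distributions, and in ~260 dimensions the angle statistic concentrates so
  sharply that even a few-percent scale mismatch pushes the observed angle
  into the tail — measured null rejection 0.17 at α = 0.05, and 0.85–0.96
  for residual-permutation variants, whose reduced-model slope leaks shared
  estimation noise into both permuted vectors). The stratified scheme is
  exchangeable under the null, respects each group's covariate
  distribution and any size-linked residual scale, and measures calibrated
  (null rejection 0.04–0.05; power 0.95–0.99 at a 45° divergence). The
  plain scheme remains available as `method = "labels"`.
* **Two-block PLS**: SVD of the cross-covariance of centred blocks; per
  axis the score correlation *r* and the percent of total squared
  cross-covariance. `%Var Block1` is not a standard quantity; here it
  defaults to the variance of Block 1 explained by its own axis-1 scores,
  with the alternative (prediction from Block 2 scores) selectable via
  `mode = "predicted"`. The permutation test shuffles Block 2 rows and
  compares the axis-1 score correlation.
* **Age groups**: the source literature's verbal enumeration of its
  pooled age bins yields ten intervals while stating nine groups; this
  package defaults to the nine-bin reading
  `0,1,3,6,9,12,18,24,36,48` months (merging the 1–3 month span into one
  bin) and leaves the edges fully configurable. Bins are `(lower, upper]`
  with the first bin closed at 0, so edge ages resolve deterministically
  downward.

# Numerical choices

* **TPS kernel**: `U(r) = r`, the standard 3D landmark kernel, entered
  with the negative sign convention so the bending-energy quadratic form is
  positive semidefinite (affine maps span its null space — asserted to
  1e-10). The interpolation system carries a Tikhonov jitter of 1e-10 on
  the kernel block for near-degenerate configurations, followed by one step
  of iterative refinement against the unjittered system, which restores
  interpolation exactness to ~1e-14 while keeping the regularised
  factorisation. Kernel distances are computed from per-coordinate
  differences, not the expanded inner-product formula, which loses half the
  significant digits exactly where the kernel must vanish.
* **Sliding**: semilandmarks move in local tangent planes (barycentric
  interpolation of area-weighted vertex normals at the closest surface
  point); the tangent coefficients solve the bending-energy normal
  equations restricted to tangent directions in closed form, then points
  are re-projected to the surface. An iteration that would raise the energy
  after re-projection is rejected and sliding stops, so the energy trace is
  non-increasing by construction. Defaults: 3 iterations, relative
  tolerance 1e-6. Anchor landmarks never move.
* **Cavity volumetry** is cap-and-enclose: split the mesh into connected
  components, cap every boundary loop with a triangle fan about the loop
  centroid, verify watertightness, test the seed point by ray-crossing
  parity (three fixed rays, majority vote), and report the smallest
  enclosing component's divergence-theorem volume. At subdivision 4 the
  worst recovery error across all four cavities and ages 0–48 months
  measures ≈ 0.8% against the closed forms (the fan cap under-sweeps the
  missing spherical cap; the inscribed triangulation under-estimates
  slightly) — comfortably within the 2% the validation asserts.
* **Circumference** (dimension 3) intersects the shell with the plane
  through Glabella and Opisthocranion perpendicular to the least-squares
  midsagittal plane of the midline landmarks, chains the per-triangle
  segments into loops via shared mesh edges, and reports the longest closed
  loop's perimeter.
* **Area-change maps** pair faces by index (meshes derive from a common
  template); percent change uses the reference as denominator. The map
  reports its raw min/max; display clipping is the caller's business.

# Problem sizes

The shipped tests and the acceptance script run everything at sizes chosen
to keep a full check under a few minutes on one core while leaving each
statistical check adequately powered: landmark-only cohorts of n = 200 for
recovery and form-space structure, n = 80 per replicate (100 replicates,
199 permutations) for the trajectory-test calibration and power arms,
200 null replicates at n = 50 with 200 permutations for the regression
type-I error, meshes at subdivision 3 (subdivision 4 for volume recovery),
and the full orchestrated battery at n = 40 with a thinned semilandmark
template (20/80/10 per side). The full-density template (100/1000/52 per
side, 2304 points) is built and validated at full size; sliding it over
large cohorts is supported but not exercised in the default suite.

# Known limitations

* The generator's allometric field is one global vector; there is no
  region-specific or nonlinear development term beyond what normalisation
  induces, so trajectory *curvature* in real data has no synthetic
  counterpart.
* Cavity ellipsoids may interpenetrate slightly; volumes are per-cavity
  definitions, not a partition of the endocranial space.
* Semilandmark homology is a modelling convention: bending-energy sliding
  standardises point placement but cannot certify biological
  correspondence, on synthetic crania as on real ones.
* The dimension table's endpoint assignments beyond the documented core
  entries are plausible classical pairings, not transcriptions of any
  clinical protocol; treat absolute values of those dimensions as
  synthetic-only.
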