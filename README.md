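# craniomorph

Geometric morphometrics of early craniofacial growth (0–48 months),
exercised end-to-end on synthetic skull cohorts with known ground truth.

Infant skulls change fast: the brain inflates the neurocranium in the first
year, then the face — driven by the growing airway and oral cavity — keeps
expanding long after the braincase slows. The standard way to quantify this
is a geometric-morphometrics pipeline: named 3D landmarks and slid surface
semilandmarks, generalized Procrustes analysis (GPA), and multivariate
statistics on the resulting shape variables, augmented with log centroid
size, Ln(CS), to form the **form matrix**. Because clinical CT cohorts of
healthy infants cannot be shared, `craniomorph` pairs the full pipeline with
a synthetic skull generator whose growth curves, allometric vector and
cavity volumes are known in closed form, so every stage is testable against
exact oracles.

What the package implements:

* **Mesh geometry** — watertight triangle meshes (ASCII PLY/OFF/STL I/O),
  divergence-theorem volumes, planar circumference sections, per-face
  area-change maps, closest-point projection.
* **Thin-plate splines** — exact 3D interpolation with kernel U(r) = r,
  bending-energy matrices (PSD, affine null space).
* **Semilandmarks** — farthest-point patch sampling (100/1000/52 per side
  → 2304 points), mirroring, TPS-guided projection, and sliding by
  bending-energy minimisation in surface tangent planes.
* **Procrustes** — centroid size, ordinary and generalized Procrustes
  analysis with an 86-of-88 flagged-landmark exclusion rule (the Euryon
  pair is measured but never superimposed on).
* **Craniometrics** — 47 linear dimensions, the cranial module and 7
  indices (CI, CFI, UFI, LOI, NI, PI, FMI), and cap-and-enclose cavity
  volumetry for intracranial, orbital, nasal and intraoral volumes, with
  cube-root (CVols) and proportional (CPVols) views.
* **Morphometric statistics** — covariance PCA (form space and volume
  space), multivariate regression with trace R² and permutation p-values,
  ontogenetic trajectory-angle permutation tests between sexes, two-block
  PLS of shape against cavity-volume proportions, age-group means, and
  mean-shape warps along regression vectors with size restored from
  Ln(CS).
* **Orchestration** — `run_config()` / `run_study()` execute the whole
  battery deterministically from one seed and write every report as CSV
  plus a provenance JSON.

The central quantities follow the field's conventions: centroid size
CS = √Σᵢ‖xᵢ − x̄‖², shape variables from unit-CS GPA, allometry as the
multivariate regression of shape on Ln(CS) with
R² = 1 − tr(E′E)/tr(Y′cYc), trajectory comparison as
θ = arccos(b̂_F·b̂_M) with a stratified label-permutation null, and PLS as
the SVD of the between-block cross-covariance.

## Worked example

A landmark cohort at full study size, superimposed and regressed
(`analysis/04_morphostats.R` runs exactly this):

```r
library(craniomorph)

tpl    <- make_template_skull(2, growth_params())
cohort <- generate_cohort(200, age_sampler = "paper_like",
                          sex_ratio = 123/217, seed = 20260929,
                          with_mesh = FALSE, template = tpl)
g  <- gpa(lapply(cohort$specimens, `[[`, "landmarks"))
fm <- form_matrix(g)

pf <- cm_pca(fm)
iF <- cohort$metadata$sex == "F"
multivariate_regression(g$shape_matrix[iF, ], g$ln_cs[iF], n_perm = 1000, seed = 1)
trajectory_angle_test(g$shape_matrix[iF, ], g$ln_cs[iF],
                      g$shape_matrix[!iF, ], g$ln_cs[!iF],
                      n_perm = 1000, seed = 3, labels = c("F", "M"))
```

printed by that driver on this cohort:

```
form PCA: PC1 88.4%, PC2 0.2%; Ln(CS) loading on PC1 = 0.984
      regression r2_female p_female r2_male   p_male angle_deg p_angle
1  shape_vs_lncs     0.196 0.000999   0.190 0.000999     18.30   0.877
3   form_vs_lncs     0.878 0.000999   0.880 0.000999      3.32   0.894
7 cpvols_vs_lncs     0.669 0.000999   0.711 0.000999      2.67   1.000
PLS shape vs CPVols: axis-1 r = 0.90 (p = 0.000999), %Var shape = 19.7
allometric vector recovered within 2.1 degrees of the generator truth
```

Read: size dominates form (form-on-size R² 0.88 vs shape-on-size 0.19; PC1
of form space is essentially Ln(CS)); both sexes travel the same
ontogenetic trajectory (angles of a few degrees, all permutation p-values
non-significant, as expected — the generator's sexes share their allometric
vector and differ only in size-for-age); shape covaries strongly with the
relative proportions of the four cranial cavities; and the regression
recovers the generating allometric vector to ~2°.

The numbered drivers under `analysis/` walk the same pipeline stepwise:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | simulate and write a meshed cohort (n = 60) |
| `02_template_and_slide.R` | build the 2304-point template; slide a thinned one over the cohort |
| `03_measurements.R` | 47 dimensions, indices, mesh cavity volumetry vs the closed forms |
| `04_morphostats.R` | GPA, form PCA, the eight sex-compared regressions, PLS, recovery |
| `05_full_battery.R` | the whole battery through `run_study()`, reports + warp meshes |

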