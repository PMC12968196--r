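---
title: "Connectivity-guided CED planning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-guided CED planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`cedplan` implements a simulation pipeline for planning convection-enhanced
drug delivery (CED) into the putamen: an AC-PC based quadrant parcellation,
deterministic single-tensor streamline tractography with cohort-level
connection counting, straight-trajectory safety classification against
critical-structure distance maps, a genetic-algorithm (GA) optimizer for
stepwise spherical infusion plans, and the paired statistics used to compare
a frontal with an occipital approach. This vignette explains the models, the
parameters that matter, and the choices made where the design was genuinely
open. Everything is exercisable end-to-end on synthetic phantoms with known
ground truth; no patient data are involved.

## Geometry conventions

All volumes are 3-D arrays with a 4x4 affine mapping 0-based voxel indices
to world mm, RAS+. A voxel's world position is its **center**, and mask
membership is decided by the voxel-center test: a voxel belongs to a sphere
or half-space iff its center satisfies the predicate. Every geometric
quantity — distances, margins, radii, streamline lengths — is computed in
world mm, so anisotropic grids need no special handling. Files stored in
other orientations are reoriented to RAS+ on load. Resampling and
registration are out of scope: all inputs of one study must share a grid.

The distance transform (`distance_to_mask`) is the exact separable
lower-envelope (parabola) algorithm with per-axis mm spacing, not a chamfer
approximation; tests compare it against an all-pairs brute-force scan.

## AC-PC quadrant parcellation

The putamen is split by two planes through the anterior commissure (AC):
the axial plane containing the AC-PC line separates superior from inferior,
and the coronal plane perpendicular to it separates anterior from
posterior. With unit axes $\hat y_{AP}$ (PC$\to$AC) and $\hat z_{SI}$
(superior, orthogonalized), a voxel center $p$ is superior iff
$(p - AC)\cdot\hat z_{SI} \ge 0$ and anterior iff
$(p - AC)\cdot\hat y_{AP} \ge 0$. Codes: 1 superior-anterior, 2
superior-posterior, 3 inferior-posterior, 4 inferior-anterior.

Open choices resolved here:

* **Plane anchor.** Both planes pass through AC (not the mid-commissural
  point); the segmentation is anchored to the AC, and the AC-based
  convention keeps the frame construction independent of the AC-PC
  distance. Sensitivity to the mid-commissural alternative can be probed by
  passing a shifted `ac` to `parcellate_putamen`.
* **Boundary voxels** (dot product exactly zero) go to superior/anterior —
  a deterministic tie-break on a measure-zero set.
* **Third landmark.** Two points fix only the AC-PC line, so a superior
  reference point (`ih`) is a required input; the phantom supplies one.

The four labels provably partition the mask (tested on 50 random
ellipsoid/frame combinations), and segment volumes in mm³ sum exactly to
the putamen volume.

## Tensor model, tracking and connection counting

Diffusion tensors are fitted per voxel by log-linear least squares,
$\ln S_i = \ln S_0 - b_i\, g_i^{\mathsf T} D\, g_i$, over all measurements
at once; negative eigenvalues are clamped to $\lambda_{\min} = 10^{-7}$
mm²/s, and voxels with non-positive signal are flagged invalid rather than
set to NaN. Fractional anisotropy uses the standard eigenvalue formula
$\mathrm{FA} = \sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert /
\lVert\lambda\rVert$ (defined as 0 for the zero tensor).

Tracking is deterministic fixed-step Euler integration along the principal
eigenvector, bidirectional from each seed, with the eigenvector sign
aligned to the incoming direction. Retention criteria follow clinical
deterministic DTI practice: minimum FA 0.2, minimum length 20 mm, maximum
per-step angulation 50°. Remaining numerical choices are declared, not
inferred from any reference implementation:

* seeding: one seed per voxel center of each putamen segment — exhaustive
  and deterministic at 2 mm resolution;
* step size 1.0 mm (half the smallest default voxel dimension), capped at
  200 steps per direction;
* trilinear interpolation of the six tensor components followed by
  eigen-decomposition at each step;
* the 50° criterion is applied per step at the default step size.

A connection between a cortical ROI and a putamen segment is **present**
iff at least one retained streamline has a point in both masks (traversal
semantics, matching the idea of streamlines "observed between" two
regions; an endpoint-only mode is available as a flag). Per-hemisphere
boolean matrices are summed into cohort count matrices on a fixed
0–2·n_subjects heat-map scale.

## Trajectories, safety and valid centers

Straight trajectories are sampled as **100 points including both
endpoints** (spacing $\lVert t - e\rVert/99$). The alternative
101-point/100-interval reading is available through the `n` argument; the
100-point reading matches the uniform-linspace idiom the sampling is
defined by. Sample points whose containing voxel lies in the target
segment are the *valid centers* — the only admissible infusion-sphere
positions. A trajectory is **safe** iff the trilinearly interpolated
distance-map value at every sample point is at least the margin (default
2 mm) for every critical structure; interpolation matters because sample
points are sub-voxel on a 2 mm grid. Safety is monotone in the margin, and
an empty valid-center set ("misses the segment") is reported distinctly
from "unsafe". Entry and target points are inputs (from the phantom
manifest or user JSON); automated entry-point search is deliberately out
of scope.

## Infusion spheres and the genetic algorithm

An infusion plan is a variable-length list of spheres (center from the
valid-center set, radius on a discrete grid). Containment is enforced by
*phenotypic repair*: at evaluation time each requested radius is reduced in
`radius_step_mm` decrements until the sphere's voxel mask lies inside the
allowed ROI — this shrinkage is the penalty for violating anatomical
boundaries. Because a sphere's mask is contained iff no outside-voxel
center lies within its radius, the repair is computed in closed form from
one bounding-box scan; the result is identical to the literal
shrink-and-retest loop (unit-tested equivalence). Fitness is the fraction
of target-segment voxels covered by the union of the repaired spheres.

The GA evolves the plans with tournament selection (size 3), one-point
crossover with independent cut positions per parent (so sphere counts can
change within 1..`n_spheres_max` while the pair's sphere multiset is
conserved), and a mutation that re-draws one sphere's center uniformly
from the valid centers. One elite individual is preserved, so the
best-so-far fitness log is non-decreasing. The generation count (20) is
part of the published protocol; the remaining hyperparameters are package
defaults, all exposed in `ga_config()`: population 50, crossover 0.7,
mutation 0.3, `n_spheres_max` 4, radius grid 0.5 mm up to 6 mm.

Two containment modes exist because the boundary the spheres must respect
can be read as either the target segment or the whole brain: the default
confines spheres to the segment (conservative); `containment = "brain"`
relaxes this. Neither is asserted as the original study's setting.

On oracle-checkable instances (≤6 centers, ≤2 spheres, 3 radius levels)
the GA is required never to exceed, and in ≥90% of seeded runs to match,
the exhaustive-enumeration optimum; both properties are tested over 20
seeded instances.

## Paired statistics

Safety outcomes are paired per hemisphere (0 = unsafe, 1 = safe) into the
2x2 table $(a, b, c, d)$. The mid-p McNemar test uses the exact
conditional binomial form: with $n_d = b + c$, $m = \max(b, c)$ and
$X \sim \mathrm{Bin}(n_d, 1/2)$,
$$p_{\text{mid}} = 2\,P(X \ge m) - P(X = m),$$
capped at 1 and defined as 1 when $n_d = 0$. This is the standard
two-sided "exact minus point probability" variant; software implementations
of mid-p corrections differ, and no particular variant is canonical, so the
formula above is fixed and documented. It is validated against exhaustive
enumeration of all $2^{n_d}$ discordant orderings for $n_d \le 12$. For
$(b, c) = (7, 6)$ this formula gives $1 - \binom{13}{7}/2^{13} = 0.79053$.
Coverage is compared with a standard paired t-test (two-sided, 95% CI);
zero-variance differences return a flagged degenerate result rather than
NaN.

## The synthetic phantom

The phantom emulates the study conditions the pipeline expects:
2 mm isotropic label volumes (64³ default), a 64-direction b = 1000 s/mm²
protocol (the shipped gradient table was generated once by electrostatic
repulsion with antipodal symmetry), an ellipsoidal brain, one putamen
ellipsoid per hemisphere straddling all four AC-PC quadrants,
ventricle-slab and vessel-cylinder critical structures, and per-hemisphere
frontal (anterior-superior) and occipital (posterior) entry points.

Fiber bundles are swept tubes along quadratic Bézier centerlines; tensors
inside a tube are axially symmetric with the principal eigenvector along
the local tangent, giving analytic control of FA (bundle FA 0.7,
background 0.05, mean diffusivity 7·10⁻⁴ mm²/s — typical white-matter /
deep gray values). Two bundles are planted per hemisphere: an SMA-like
motor ROI connected to the superior-posterior quadrant and an
amygdala-like ROI connected to the inferior-posterior quadrant, mirroring
the motor/limbic split the pipeline is meant to detect. The generator
validates its own ground truth (a bundle that never enters its stated
quadrant is a configuration error). DWI synthesis uses the monoexponential
tensor model with optional Rician noise (two Gaussian channels, matching
magnitude MRI); the default is noise-free so that fit∘synthesize is the
identity and recovery tests are exact.

What the phantom does **not** emulate — and hence what passing tests do
not show about real data: cortical folding, partial-volume and
susceptibility effects, crossing fibers, subject-to-subject anatomical
variability (cohort members share anatomy and differ only through
seed-driven noise), realistic sulci as critical structures, and realistic
putamen shape. In particular, GA coverage on the phantom's smooth
ellipsoidal segment (~50%) is far higher than would be expected for the
curved, tapering segment of a real putamen; phantom coverage values are
relative measures for comparing trajectories, not clinical estimates.

## Problem sizes and determinism

The test suite runs the full pipeline on 64³ phantoms: connectivity
recovery uses a 4-subject noise-free cohort, and the end-to-end
reproducibility check uses the default 2-subject study, sizes chosen so
the whole suite completes in a few minutes while still seeding every
putamen-segment voxel. All randomness flows through explicit seeds
(`phantom_spec(seed=)`, `ga_config(seed=)`, `study_config(seed=)`; stage
seeds are derived deterministically from the study seed), and repeated
runs are bit-identical. The package never touches the global RNG state
outside its own calls (the previous `.Random.seed` is restored).

## Known limitations

* Spheres model instantaneous isotropic distribution: no tissue
  anisotropy, backflow, pharmacokinetics, or PDE-based
  convection–diffusion.
* Single-tensor DTI only; crossing-fiber configurations will be averaged
  into a single principal direction.
* No registration: inputs must be co-registered upstream.
* The mid-p variant reported by other software may differ from the fixed
  formula above; comparisons across tools should verify the variant.
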