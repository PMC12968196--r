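# cedplan

Simulation-based planning of **convection-enhanced drug delivery (CED)**
into the putamen, for researchers exploring connectivity-guided targeting
in Parkinson's disease. Instead of infusing the whole putamen, the pipeline
asks: *which putamen quadrant carries the motor connectivity, can a frontal
or occipital catheter trajectory reach it safely, and how much of it can a
small set of stepwise spherical infusions cover?*

The package implements, end to end and fully testable on synthetic
phantoms:

1. **AC-PC quadrant parcellation** — the putamen is cut by the axial plane
   containing the AC-PC line and the coronal plane perpendicular to it
   (both through AC) into superior-anterior, superior-posterior,
   inferior-posterior and inferior-anterior segments.
2. **Deterministic DTI tractography** — per-voxel log-linear tensor fits
   (ln *S* = ln *S₀* − *b·gᵀDg*), streamline tracking along the principal
   eigenvector with FA ≥ 0.2, length ≥ 20 mm, angulation ≤ 50°, and
   cohort-level *connection presence* counts per (region, segment) pair.
3. **Trajectory safety** — straight entry→target lines sampled at 100
   equidistant points, classified against exact Euclidean distance maps of
   critical structures with a 2 mm margin.
4. **GA infusion optimization** — variable-length plans of spheres
   (centers restricted to the trajectory's in-segment sample points, radii
   shrunk until each sphere fits inside the target) evolved for 20
   generations to maximize coverage = |∪ spheres ∩ segment| / |segment|.
5. **Paired statistics** — the 2×2 safety table (a, b, c, d), safe
   proportions, the mid-p McNemar test
   *p* = 2·P(X ≥ max(b,c)) − P(X = max(b,c)), X ~ Bin(b+c, ½),
   and a paired t-test on coverage.
6. **Synthetic phantoms** — seeded 2 mm digital phantoms with planted
   anisotropic fiber bundles (known ground-truth connections), ventricle-
   and vessel-like critical structures, and per-hemisphere frontal and
   occipital entry points, so every stage is verifiable without patient
   data.

## Worked example

```r
library(cedplan)

## a fully ground-truthed phantom at the default 64^3 / 2 mm resolution
spec <- phantom_spec()
ph   <- generate_phantom(spec)
frame <- acpc_frame(spec$ac, spec$pc, spec$ih)

parc <- parcellate_putamen(ph$putamen_mask$right, frame, "right")
parc$counts
#>  superior-anterior superior-posterior inferior-posterior  inferior-anterior
#>                 98                298                178                 50

## track from the motor-dominant segment and check the planted connection
seg <- segment_mask(parc, "superior-posterior")
streams <- track_from_mask(ph$tensor_field, seg, tracking_criteria(),
                           ph$brain_mask)
connection_present(streams, ph$roi_masks$right$SMA, seg)
#> [1] TRUE

## frontal trajectory: safety, valid centers, GA infusion plan
e <- subset(ph$entries, hemisphere == "right" & approach == "frontal")
traj <- trajectory(c(e$entry_x, e$entry_y, e$entry_z),
                   c(e$target_x, e$target_y, e$target_z),
                   "frontal", "right")
classify_safety(traj, safety_config(2, ph$critical_masks))$safe
#> [1] TRUE
vc <- valid_centers(traj, seg)
plan <- optimize_injection(vc$centers, seg, cfg = ga_config(seed = 7))
plan
#> <injection_plan> 4 sphere(s), coverage 54.36%
```

The parcellation counts show the four quadrants of the phantom putamen
(the AC-based cut intentionally yields unequal segments). `TRUE` for the
SMA/superior-posterior pair is the recovery of the planted bundle; the
infusion plan covers 54% of the segment with four contained spheres —
high relative to real anatomy because the phantom segment is a smooth
ellipsoid wedge fully traversed by the trajectory.

The published paired safety outcomes (27 both-safe, 7 frontal-only,
6 occipital-only, 0 neither) reproduce as:

```r
ct <- build_contingency(c(rep(1, 34), rep(0, 6)),
                        c(rep(1, 27), rep(0, 7), rep(1, 6)))
unlist(safety_proportions(ct)[1:3])
#>  p_frontal_safe p_occipital_safe     n_discordant
#>           0.850            0.825           13.000
midp_mcnemar(ct)
#> [1] 0.7905273
```

An entire cohort study — phantom → parcellation → tractography →
trajectories → GA → statistics, with every artifact written to disk — is
one call:

```r
summary <- run_study(study_config(seed = 5))
```

or from a shell: `inst/cli/cedplan run-all --out study --seed 5`.

## Scope

No registration/normalization, no probabilistic or crossing-fiber
tractography, no PDE-based infusion modelling, no DICOM — inputs are
co-registered NIfTI volumes plus landmark/trajectory JSON. See the
methods vignette (`vignettes/ced-planning.Rmd`) for the models,
parameter defaults and design decisions.
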