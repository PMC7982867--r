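---
title: "Methods: simulating and evaluating ultrasound-based spine navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating ultrasound-based spine navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Image-guided spine surgery needs a rigid map between the patient on the
table (the *reference* space defined by a tracked dynamic reference object,
DRO) and the preoperative CT. One way to establish it intraoperatively is a
tracked freehand ultrasound (iUS) sweep over the exposed vertebra: the
hyperechoic response of the bone surface in the ultrasound frames is
aligned with the posterior vertebral surface extracted from CT. `spinenav`
implements a complete desk-scale evaluation of such a system: because no
cadaver is available to a software package, every input is synthesised by a
tested generator, and every metric of the evaluation — target registration
error (TRE), success/mismatch robustness rates, error propagation across
vertebral levels, anatomical coverage of the sweeps, and the mixed-model
analyses linking coverage to accuracy — is computed by package code.

All coordinates are millimetres in right-handed LPS (+x left, +y posterior,
+z superior, so caudo-cranial travel is +z and the probe looks along −y).
Transforms are 4×4 homogeneous matrices validated to be rigid
(orthonormal rotation, det +1, tolerance 1e−9); `compose()`, `invert()`,
`apply_transform()` and the closed-form Horn/SVD landmark fit
`fit_rigid_landmarks()` (reflection corrected by flipping the smallest
singular vector; FRE reported as an RMS) underpin everything else.

## The spine phantom

`generate_phantom()` voxelises six vertebrae (L1 most cranial) at a 0.5 mm
base spacing. Each vertebra is built from five labelled primitives —
spinous process (SP), laminae (L), articular processes (AP), transverse
processes (TP), pedicles-plus-body (VB) — stacked posterior-to-anterior so
that a posterior ray meets them in anatomical order. Successive spinous
processes sit at the measured inter-level distances 69.36, 35.33, 38.21,
39.38 and 39.46 mm (caudal pair first), so L1 and L6 are 221.74 mm apart
and lever-arm analyses operate at matched distances.

Every primitive surface is curved: a parabolic crest on the spinous fin,
lamina roofs sloping laterally and curving axially, ellipsoidal articular
knobs, transverse bars with elliptical cross-sections drooping toward their
tips, and a barrel-shaped body. This matters beyond looks. Axis-aligned
boxes voxelise into flat lattice-aligned plateaus, and a point cloud
registered to such a surface has exactly self-consistent alignments shifted
by one voxel (we observed ICP "converging" with near-zero RMS at a √2 mm
translation error). Curved surfaces price every shifted alignment visibly
and make surface registration well conditioned — as real bone does.

Four fiducial spheres (radius 5.5 mm, very bright at 3200 HU-like units
versus 700 for bone and 40 for soft tissue) are rendered on the frame,
deliberately far from the anatomy. CT volumes add seeded Gaussian noise
(SD 6); `resample_ct()` produces the 1 mm and 2 mm reconstructions by
trilinear interpolation over the same physical extent, and labelmaps are
resampled nearest-neighbour. Seven landmarks per vertebra (spinous apex,
left/right laminae, left/right superior articular processes, left/right
transverse tips) are placed analytically and snapped to the nearest voxel
labelled with their own level, which guarantees they lie on the anatomy at
any spacing.

## Tracked sweep simulation

A sweep is an ordered list of frames, each a rows×columns image plus a
rigid pose mapping image-plane millimetres to the reference space (the
pose already includes the probe calibration; estimating calibration is out
of scope). The image grid has a fixed 128 rows, so the pixel spacing is
`depth/128` — 0.39 mm at 5 cm and 0.55 mm at 7 cm — and the column count
follows from the fixed 14 mm probe contact width. Frames travel
caudo-cranially across the level with a 56 mm span: the sweep deliberately
overshoots the vertebra so that, as in practice, it can graze the
neighbouring levels. The frame count (default 24) is a free parameter; no
frame rate is implied.

Image formation is deliberately geometric, not wave-physical: per column,
the first bone-labelled voxel along the beam receives a Gaussian echo whose
axial σ is `7.2/f` mm (narrower at 12 MHz than 6 MHz) and whose amplitude
decays as `exp(−8e−4 · f · depth)`; deeper pixels are shadowed (×0.05) and
everything else is uniform speckle below a 0.18 ceiling. That suffices to
exercise everything downstream — echo localisation, shadow confirmation,
coverage — while making no claim about speckle statistics, refraction or
soft-tissue layers.

Randomness is split per sweep into two documented streams derived from one
seed: a *pose* stream (`seed`) drives the per-repetition left-right rocking
about the travel axis (SD 2°, which fans the beam laterally at depth, the
way an operator varies left-right orientation), a lateral offset (SD 1 mm)
and tiny per-frame pose noise (0.1 mm / 0.05°); a *speckle* stream
(`seed + 500009`) drives image texture. Poses and texture are therefore
independently reproducible.

## Ground truth

`detect_fiducials()` thresholds the CT (default 2000, calibrated to sit
between bone and sphere intensities), labels 26-connected components,
discards components smaller than a half-radius sphere, and localises each
sphere by an intensity-weighted centroid — sub-voxel even at 2 mm. Centres
are ordered canonically (lexicographic on coordinates rounded to 1 mm, so
sub-voxel noise cannot permute spheres that tie on an axis), and tracked
positions must arrive in the same order. `ground_truth_transform()` then
delegates to the landmark fit. On noiseless volumes the scene's true
reference-to-CT transform is recovered to ~1e−3 mm, and an injected angular
ground-truth error produces TRE growing linearly with the lever arm at
slope `2 sin(ε/2)` — the caveat that motivates placing the DRO near the
treated level.

## The registration stand-in

The production CT-to-iUS algorithm of a clinical system is not public;
`spinenav` substitutes a documented point-based pipeline whose role is to
be a *reasonable* registration so that the evaluation machinery around it
is fully exercised. Per frame, `extract_bone_points_frame()` takes each
column's deepest local maximum above an echo threshold (0.45), confirms it
by the shadow criterion (mean intensity deeper than the peak below half the
peak; peaks within 3 rows of the image bottom cannot be confirmed and are
rejected), and refines the position by a parabolic fit. `sweep_to_cloud()`
maps these points through the frame poses into a reference-space cloud.
`extract_ct_surface()` emits, per posterior-to-anterior voxel column, the
first voxel of the level's labels (optionally including the adjacent
levels, which is what lets a registration lock onto the wrong vertebra);
thinning for speed uses a dithered stride, because raster-order striding
aliases along x and measurably biases the surface centroid.

Initialisation uses the acquisition protocol as a prior: the sweep's travel
direction is aligned to CT +z and the mean beam direction to −y; the
translation matches the cloud to the level's posterior surface — medians
laterally and axially, and the posterior extreme (the spinous crest, which
both sets see at the same physical place) along the beam, with a second
pass windowed to the level's axial extent so overshoot cannot bias the
match. A plain centroid-to-centroid rule was rejected: the labelmap
centroid sits ~10 mm anterior of anything the probe sees, and even a
cloud-to-surface centroid match is biased several millimetres by the narrow
footprint. The implemented rule initialises within ~1.5 mm and 1° on
identity scenes.

`icp_register()` is trimmed point-to-point ICP: exact nearest neighbours
(kd-tree when RANN is present, chunked brute force otherwise), keep the
closest 80% of pairs, closed-form rigid update, accept an iteration only if
the trimmed RMS does not increase (so the reported trace is monotone), stop
when the change falls below 1e−3 mm or at 40 iterations. Because
point-to-point ICP on sampled surfaces can settle in a shallow basin about
one sample spacing from the best alignment by sliding tangentially, the
solver is multi-start: five deterministic starts (the init and four
±1.5 mm lateral/axial offsets), keeping the lowest-RMS result and exiting
early once a start lands below tolerance.
On exact subsampled clouds it recovers injected perturbations of up to
5°/3 mm to machine precision.

## Metrics and their conventions

TRE is the RMS over landmarks of the distance between a point's images
under the evaluated and the ground-truth transform; with 7 landmarks per
vertebra this is the study convention, and it is computed at *all* levels
for every acquisition so errors can be traced as they propagate. Closed
forms pin the implementation: a pure relative translation gives exactly its
norm, and a single landmark under a pure rotation gives the chord
`2 d sin(θ/2)`.

Classification is `success` iff TRE < 2.0 mm (strictly — "below 2 mm"
is a strict bound, so 2.0 itself is a failure) and `level_mismatch` iff
TRE ≥ 10.0 mm; rates are percentages on 0–100, rounded only for
presentation. The propagation matrix aggregates with the median (the
robust summary used throughout), distances between levels come from the
cumulative spinous-process gaps, and `fit_tre_vs_distance()` is ordinary
least squares of matrix cells on distance. Quantiles everywhere (median,
IQR, profile ensembles) use the linear-interpolation definition (R type 7),
stated because quantile conventions differ between environments.
Wall-clock effectiveness is logged in run records but never asserted —
it is hardware, not science.

## The coverage model

Coverage asks *what part of the vertebra the sweep actually imaged*.
Assuming no ultrasound penetration beyond bone, a ray is marched along each
image column (mapped to CT through the ground-truth transform) and only the
first labelled voxel counts. Counts are *unique voxels* — a set, not a
per-ray tally — so re-scanning the same surface cannot inflate coverage;
the brute-force oracle in the tests uses the same rule. Own-level hits bin
by region; hits on the adjacent levels pool into `Inf`/`Sup` (the adjacent
vertebra is treated as a single label); a hit two or more levels away
terminates the ray but is not counted, which in centred sweeps essentially
never occurs. The marching step defaults to a tenth of the voxel spacing:
a coarser step can hop over a grazing ray-voxel intersection and then
disagrees with the model's own fine-step definition of "first voxel".

Two models link coverage to outcome, both delegated to lme4 (the design
and response construction, grouping structure and reporting are the
package's contract). The accuracy model removes level-mismatch outliers,
then fits TRE on the five label counts and all 10 pairwise products —
pairwise only, because every higher-order interaction is combinatorially
hopeless at n = 120 — with random intercepts for level, level×frequency
and level×depth (the nesting is implemented as stated; the exact
crossed-versus-nested structure is a documented choice, not an inferred
one), with Satterthwaite p-values via lmerTest. The misalignment model is
binomial with a single covariate, the own-level coverage sum. Degenerate
cases are flagged rather than raised: constant responses return zero
slopes, singular and non-converged fits carry flags, and complete
separation is detected from fitted probabilities pinning to the labels.
`simulate_coverage_design()` and `simulate_mismatch_data()` generate
study-shaped datasets (count scales follow the reported histogram: AP
highest, then L and SP; TP and VB only at 7 cm) used to show the pipeline
recovers a planted laminae effect in sign and magnitude and holds its
type-I rate at the nominal level.

## The full experiment and reproducibility

`run_experiment()` chains everything: phantom → scene transform (a seeded
5–20° / ≤40 mm rigid offset between tracker and CT, plus 0.1 mm tracking
noise) → fiducial ground truth → 120 sweeps → cloud, init and ICP per CT
resolution → TRE at all levels → classification and stratified rates →
propagation and distance regression → coverage and both models. Every
random draw descends from the master seed; each acquisition's seed is the
documented affine-mod-2³¹ hash of (master, level, depth index, frequency
index, repetition), so any single acquisition can be re-simulated in
isolation. Per-acquisition failures are recorded and skipped, not fatal.
`write_report()` emits CSVs (including a Table-1-style summary with
resolution rows and depth×frequency rows) plus the ground-truth transform
and a provenance block.

Problem sizes are chosen for a desk machine: 24 frames per sweep, surfaces
thinned ×2 at 0.5 mm, ICP clouds capped at 600 points, model checks at
100–200 replicate designs. The full three-resolution study runs in a few
minutes; the registration-recovery, coverage-oracle and statistical suites
each run in well under their stated budgets.

## What passing tests do and do not show

The generator reproduces the *structure* of the study — its geometry grid,
label scheme, acquisition protocol and noise scales — not the cadaver. The
synthetic images have no true speckle statistics, refraction, soft-tissue
layering, intervertebral motion or transducer artefacts; the registration
is a stand-in, not the production algorithm; and mismatch rates, per-label
coverage magnitudes and model p-values in a simulated run are properties of
the simulation, not estimates of the published ones. What the suite does
establish: the geometric core is exact (Horn fit, transform algebra,
TRE closed forms, lever-arm law to within 1%), the coverage counter
matches an independent brute-force definition, the statistical pipeline is
calibrated and recovers planted effects, and the end-to-end simulated
system achieves a clinically-styled success rate (well above the 60%
sanity floor at 2 mm) with level mismatch as a reproducible failure mode.
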