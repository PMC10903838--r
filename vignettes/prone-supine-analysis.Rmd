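---
title: "Quantifying lung volume redistribution and movement between supine and prone CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lung volume redistribution and movement between supine and prone CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a patient turns from supine to prone, the dependent (dorsal) lung is
relieved of the weight of the mediastinum and the pleural pressure gradient
flattens: dorsal and basal lung re-aerates, the lower lobes expand, and the
parenchyma physically moves. In fibrotic interstitial lung disease the
fibrosis is typically subpleural and basal — exactly the tissue that would
otherwise be recruited — so fibrotic lungs are expected to expand and move
less. Registration of paired supine/prone CT makes both effects measurable:
lobar volumetry gives the prone-minus-supine volume change per lobe, and a
dense deformable-registration displacement field gives per-voxel movement,
summarised as whole-lung maxima along each anatomical axis and in 3D.

`pronelung` implements this analysis end to end: domain types and NIfTI I/O
under a fixed patient-anatomy axis convention, preprocessing, lung
segmentation with lobar assignment and QC, shear-free affine registration of
lung masks, multi-resolution demons deformable registration, the
quantification layer, cohort statistics, and HSV/quiver visualisation of the
displacement field. Because no patient scans ship with the package, a
digital thoracic phantom generator produces paired supine/prone volumes with
known ground truth for every stage; all tests and the acceptance study run
on these phantoms.

## Coordinate conventions

Every image lives on a `grid3d`: voxel counts, spacing (mm), origin (mm),
and the fixed axis convention +x right→left, +y anterior→posterior,
+z inferior→superior (LPS, 0-based voxel indices; physical position of voxel
`(i,j,k)` is `origin + (i,j,k)·spacing`). NIfTI files in any axis-aligned
storage order are permuted/flipped into this convention on read; oblique
acquisitions (direction cosines more than `1e-3` from axis-aligned) are
rejected rather than silently resliced, because a resliced mask would change
the registration semantics. All internal quantities are mm and mL;
centimetres appear only in reported movement summaries.

A `displacement_field` lives on the fixed (supine) grid and maps fixed-space
points to moving-space points: the tissue at supine voxel `p` is found at
`pos(p) + field(p)` in the (affine-registered) prone image. Both the phantom
ground truth and the demons output follow this convention, so they are
directly comparable.

## The pipeline

1. **Preprocess** (`resample_to_cube`, `scale_attenuation`): each scan is
   resampled to a fixed cubic voxel grid — 192³ in production, preserving
   the physical extent per axis (spacing may become anisotropic) — and
   attenuation is clipped to [−1024, 600] HU and divided by 3000. The clip
   bounds the influence of dense structures and interpolation overshoot;
   the division puts intensities and their gradients at O(1) for the
   registration. Resampling happens before scaling; the two nearly commute
   for linear operations. Tests run at 32–96 voxels per axis for speed; the
   grid side is a single configuration field.
2. **Segment** (`segment_lungs`, `assign_lobes`, `qc_segmentation`): a
   deterministic classical segmenter — threshold at −320 HU, removal of
   components touching the x/y border (exterior air), minimum component
   volume 100 mL, morphological closing with a 3 mm ball, left/right split
   by the two largest components (mid-sagittal cut if fused). Lobes come
   either from geometric fissure planes (the phantom exports its true
   planes) or from an externally supplied lobe mask, which is adopted only
   if it agrees with the lung mask on ≥ 95% of the lung extent. QC fails a
   subject whose whole-lung volume falls outside 1000–9000 mL (physiologic
   total-lung-capacity bounds), whose expected lobes are empty, or whose
   left/right volume ratio is outside [0.2, 5]. On real CT, lobar masks
   should come from an external segmenter; fissure detection is out of
   scope.
3. **Affine** (`estimate_affine`, `apply_affine`, `qc_affine`): shear-free
   (translation + rotation + per-axis scale) registration of the prone
   whole-lung mask onto the supine one, driven by the masks alone.
   Initialisation is closed-form — centroid difference, principal axes of
   the second-moment tensors (the 180° eigenvector ambiguity resolved by
   taking the proper rotation nearest the identity, justified because
   inputs are already in patient-anatomy coordinates), isotropic scale from
   the mask volume ratio — followed by a gradient-free pattern search on
   the mean squared mismatch of Gaussian-softened masks, evaluated on a
   ≤ 48³ downsampled grid for speed (step sizes 2 mm / 2° / 0.02, halved on
   failure, stopping at 1e-3 or 200 iterations). If refinement does not
   improve the mask Dice the initialisation is returned. Registration
   failure (whole-lung Dice below 0.80 after affine) is a flagged QC state,
   not an exception, so cohort runs continue.
4. **Deformable** (`register_deformable`): additive demons with dual
   Gaussian regularisation over a 3-level pyramid (×2 downsampling;
   iteration caps 100/60/30 coarse→fine). Per iteration the moving image is
   warped by the current field and the update
   `u = −(m∘φ − f)·∇(m∘φ) / (‖∇(m∘φ)‖² + (m∘φ − f)²/κ)` (κ = mean voxel
   spacing squared) is capped at 2 mm, smoothed with σ = 2 mm, added to the
   field, and the field re-smoothed with σ = 3 mm. Two numerical choices
   matter in practice and are defaults here: each level's images are
   presmoothed by one voxel before force computation (otherwise
   uncorrelated acquisition noise dominates the intensity gradients at the
   finest level and the recovered field magnitude collapses), and an update
   that increases the level MSE is rejected — the field reverts and the
   level stops — so the per-level energy trace is non-increasing by
   construction. Registration uses the scaled (1/3000) volumes.
   Externally computed fields (e.g. from a learning-based tool) can be
   imported from 4D NIfTI with explicit units via `import_field`.
5. **Quantify** (`region_volumes`, `volume_change`, `movement_summary`,
   `dice`, `analyze_subject`): volumes are voxel count × voxel volume,
   measured on each position's *own* pre-registration masks — the affine
   includes scale, which would otherwise distort prone volumes. Movement is
   summarised over whole-lung voxels as the maximum absolute displacement
   per axis and the maximum 3D Euclidean norm, reported in cm; a percentile
   option (default 100) is available because a strict voxel maximum is
   noise-sensitive. Dice of the fully registered masks is the registration
   QC readout; two empty masks have Dice 1 by convention.
6. **Cohort statistics** (`paired_t`, `welch_t`, `oneway_anova`,
   `spearman`, `cohort_tables`): paired t for per-region volume deltas;
   Welch's t (safer than pooled Student under unequal variances; pooled
   available) for the <30% vs ≥30% fibrosis dichotomy, with exactly 30%
   assigned to the severe group; one-way ANOVA for three-level fibrosis and
   CT-pattern groupings (the choice of test for three groups is this
   package's, documented rather than inherited); tie-corrected (mid-rank)
   Spearman correlation with the t-approximation p-value for FVC and
   fibrosis-extent associations. P-values are reported raw; a Holm option
   exists but is off by default, which is a documented limitation.
   Subjects failing any QC gate are excluded from the tables by default.

`run_cohort` orchestrates all of this over a simulated or on-disk cohort,
writing per-subject JSON, a cohort CSV, report tables, and a manifest with
the seed, a config hash, and QC disposition counts satisfying
`subjects_in = passed + registration_failures + segmentation_failures +
errored`. The package's command surface is its R functions together with
`scripts/acceptance.R`; no shell subcommand wrapper is shipped.

## The phantom generator

`generate_phantom_pair` builds the supine anatomy from ellipsoids laid out
in fractions of the grid extent (two lungs at −850 HU inside a body at
+40 HU, exterior air −1000 HU), partitioned into five lobes by one oblique
fissure plane per lung plus a right horizontal fissure. Lung voxels carry a
smooth correlated texture (sd 60 HU, correlation length 12 mm) standing in
for the vascular/parenchymal structure that intensity-driven registration
tracks in real CT — a uniform lung interior is unregistrable in principle
(the aperture problem), so this texture is what makes deformable-recovery
testing meaningful. Optional fibrosis-like attenuation (−300 HU) is placed
on the top fraction of lung voxels ranked by a dorsal + basal + subpleural
score, mirroring the distribution of fibrotic ILD.

The prone scan is produced by warping the supine anatomy through the
composition of:

* a **pose**: a modest residual affine (defaults drawn uniformly within
  ±10 mm, ±8°, isotropic scale 0.97–1.03) about the lung centroid. This is
  deliberately *not* a 180° flip — patient-anatomy coordinates already
  absorb the scanner-frame rotation, which is declared upstream conversion
  work — matching a workflow whose affine stage merely re-centres the
  patient; and
* a **ground-truth displacement field**: per lung, one constant-direction
  dorsal-caudal Gaussian bump (σ = 0.14 of the grid extent, centred
  dorsal-caudal of the lower-lobe centroid) plus one outward radial bump in
  the lower lobe (σ = 0.16) whose positive divergence expands the mapped
  lobe. The two weights are solved so that, before damping, the peak
  whole-lung magnitude equals `deformation_amplitude_mm` (default 15) and
  the prone-minus-supine lower-lobe volume gain equals
  `lower_lobe_expansion_ml` (default 80 mL) — first analytically through
  the Jacobian-determinant integral, then refined against the actually
  warped label map to within 2%. The field is then multiplied by
  `1 − damping` (default 0.8) at fibrotic voxels, with a linear ramp back
  to 1 over 48 mm so the map cannot fold (the discrete Jacobian is checked
  to stay positive on the lung). With fibrosis present the realised peak
  movement and volume gain therefore fall below their nominal values —
  deliberately so, since restricted expansion is exactly what fibrosis
  does; the bump geometry places peak motion inside the dorsal-basal cap so
  that damping genuinely attenuates the whole-lung maximum.

Since the field maps supine points to prone points while resampling needs
the inverse map, the generator inverts the field numerically (fixed-point
iteration, valid because the field is diffeomorphic) and composes it with
the inverse pose; acquisition noise (sd 20 HU) is then added independently
to each scan so registration cannot exploit shared noise. All randomness
comes from R's default Mersenne-Twister generator under a single integer
seed; the same seed reproduces the pair bit for bit.

`generate_cohort` adds the covariate structure of a fibrotic-ILD study
population: fibrosis extent drawn from a decreasing distribution over
{0, 10, …, 70}%, deformation amplitude `20 − 0.15·extent + N(0, 2)` mm
(floored at 2 mm), FVC `1.5 + 0.08·amplitude + N(0, 0.3)` L, and a
lower-lobe expansion target scaled with amplitude (80 mL at 15 mm). Higher
fibrosis therefore means less movement, and higher FVC more movement, with
realistic scatter. Cohort phantoms default to 64³ at 4.5 mm — the same
288 mm physical extent as the 96³/3 mm single-phantom default, at a
resolution where a 50-subject end-to-end run stays cheap.

What the phantom does **not** emulate: airway and vessel trees, cardiac and
breathing motion, scanner/kernel texture, attenuation change with aeration
(the study design itself precludes attenuation comparison because prone
scans use a lower dose), or anatomically realistic fissure geometry.
Passing phantom tests therefore demonstrates that the algorithms recover
known geometry and known covariate structure under CT-like contrast and
noise — not that they meet clinical accuracy on patient data.

## Numerical choices and degenerate inputs

* Trilinear interpolation for volumes, nearest-neighbour for labels
  everywhere; out-of-volume samples take −1024 HU (air) for HU volumes, 0
  otherwise; the demons warp clamps to the volume edge instead, to avoid
  spurious boundary forces.
* The shear-free transform type is closed under composition and inversion
  via polar decomposition, asserting a < 1e-6 shear residual (exact for
  isotropic scale, the default).
* Mask-quantisation limit: a grid-aligned pure translation is identifiable
  from nearest-resampled masks only to half a voxel; tests assert that
  bound inclusively.
* Degenerate statistics inputs raise errors rather than returning p = 0:
  zero-variance paired deltas, single-observation groups, constant inputs
  to the rank correlation.
* Problem sizes: unit tests use 32–48³ phantoms, recovery studies 64³, and
  the registration-quality study 96³ with 20 pairs; these sizes were chosen
  so the full suite completes on a single CPU in well under half an hour
  while keeping ≥ 30 voxels across each lung.

## Known limitations

* The classical threshold segmenter assumes air-like lung surrounded by
  soft tissue; severe consolidation or pleural effusion would defeat it —
  on real data, supply external masks.
* The demons implementation is the additive, non-diffeomorphic flavour;
  large-amplitude recovery is biased low by the field smoothing (maxima
  more than means), so recovered movement maxima are conservative.
* Lobar volumes are computed on the resampled grid and inherit its voxel
  size; at 192³ over a thorax this is ~2 mm resolution.
* The three-group P-values use one-way ANOVA by this package's choice; no
  multiple-testing correction is applied by default.
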