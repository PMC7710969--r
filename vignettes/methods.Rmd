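---
title: "Methods: connectivity metrics and tDCS field modelling in tdcsfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity metrics and tDCS field modelling in tdcsfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcsfc)
```

# Scope

`tdcsfc` implements a desk-scale analysis pipeline for pre/post resting-state
fMRI connectivity studies of anodal transcranial direct current stimulation
(tDCS) over the left primary motor cortex (M1), together with a finite-element
model of the stimulation electric field on labelled head phantoms. All data
are synthetic: the package ships generators whose defaults mirror typical
study conditions, so every stage can be exercised and validated end to end on
a single CPU.

This vignette records the model, the main parameter choices and their
rationale, the numerical decisions, and the known limits of the synthetic
generators.

# Data model

A BOLD run is a 4-D array (`bold_image`) with a TR in seconds and a 4x4
voxel-to-mm affine. Grids are centred on the mm origin; voxel indices are
1-based in R but the affine follows the usual 0-based NIfTI convention
(`voxel_to_mm`/`mm_to_voxel` handle the shift). Label volumes
(`label_volume`) carry a named tissue-to-integer map drawn from a fixed
vocabulary of 12 tissues (skin, bone, CSF, GM, WM, air, gel, electrode,
edema, non-enhancing and enhancing tumor, necrosis).

# Synthetic generators

The defaults of every generator are the study conditions, not tuned values:

* **Resting runs** (`make_rest_bold`): two M1 region centres at
  (±28, −16, 24) mm, 6-mm regions, TR 2 s, 150 volumes per run, baseline 100,
  unit signal amplitude and unit iid voxel noise. Region signals are latent
  Gaussian sources mixed through a Cholesky factor to give a target
  inter-regional correlation (0.5 pre, +0.15 on the left–right pair post).
  Because iid voxel noise attenuates ROI-mean correlations, the latent
  correlation is analytically inflated by the attenuation factor
  λ = 1/√(1 + σ²/(a²k)) (k = voxels per region), so the *region-mean*
  correlation is unbiased at the planted value. The construction errors out
  when the required latent correlation would leave (−1, 1).
* **Task runs** (`make_task_bold`): 20-s alternating block design convolved
  with a canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6),
  normalised to unit peak; Gaussian activation blob (6-mm FWHM) at the
  stimulated-M1 coordinate.
* **Motion** (`make_motion_trace`): small Gaussian jitter on six rigid-body
  parameters plus optional single-volume spikes; rotations are scaled so the
  framewise-displacement convention (rotations × 50 mm) makes a spike of
  s mm produce FD = s exactly.
* **Head phantoms** (`make_head_phantom`): five nested spherical shells
  (skin 92, bone 86, CSF 80, GM 76, WM 60 mm by default) with optional nested
  tumor compartments (edema ⊃ non-enhancing ⊃ enhancing ⊃ necrosis), all
  validated for strict nesting.

Every generator saves and restores `.Random.seed`, and derives stage seeds
from a master seed with a string-labelled hash (`derive_seed`), so studies
are exactly reproducible and generators do not perturb the caller's RNG.

**Realism limits.** The BOLD model has no hemodynamic autocorrelation, no
physiological noise spectra, no spatial noise correlation outside the planted
regions, and motion affects only the confound model (the images themselves
are not resampled). Phantoms are concentric spheres, not anatomy. These
simplifications are deliberate: they keep ground truth analytic so that
calibration (planted correlations, GLM nulls, cluster false-positive rates)
can be tested sharply.

# Preprocessing

`preprocess_run` chains:

1. **Outlier detection** (`detect_outliers`): volumes with global-signal
   z > 5 or framewise displacement > 0.9 mm (FD = sum of absolute parameter
   deltas, rotations scaled by a 50-mm head radius). Flagged volumes become
   one-hot spike regressors.
2. **aCompCor** (`compute_acompcor`): principal components of the
   noise-mask voxels (voxels untouched by regional signal in the synthetic
   pipeline), 5 components by default.
3. **High-pass** (`build_highpass_basis`): discrete cosine basis with
   K = ⌊2·n·TR·f_c⌋ columns at f_c = 0.009 Hz.
4. **Joint OLS regression** (`regress_confounds`) of motion, aCompCor,
   spike and DCT regressors plus intercept — a single orthogonal projection,
   so residuals are exactly orthogonal to every confound and re-applying the
   same confounds is a no-op.
5. Per-voxel standardisation, then run concatenation (`concat_runs`).

# Seeds

Seeds are 6-mm-radius spheres (`roi_sphere`; a voxel belongs to the sphere
when its centre is within the radius). By default the pipeline derives each
subject's seed from a block-design task GLM (`run_block_glm`: optional 6-mm
smoothing, DCT high-pass, HRF-convolved boxcar regressor, per-voxel t), takes
the peak voxel inside an anatomical mask (left or right half-space), and
falls back to the in-mask maximum when the global peak lies outside. Ties
break to the lowest linear index, making selection deterministic.

# Connectivity metrics

* **Interhemispheric connectivity**: Fisher-z (atanh) of the Pearson
  correlation between left and right seed-mean residual series.
* **Intrinsic connectivity (IC)**: IC(x) = √(Σ_y r(x,y)²/N) over all in-mask
  voxels (self term included), a global centrality measure. Computed through
  a truncated SVD: with standardised voxel series Z, the time × time Gram
  matrix Z'Z is eigendecomposed and IC²(x) = Σ_k λ_k (z_x·v_k)²/N using the
  top K = 64 components (or the matrix rank if smaller). With K ≥ rank this
  is exact (tested to 1e-10 against the brute-force N×N computation); K = 64
  matches common practice and is the package default. Maps are z-scored
  across in-mask voxels by default (the raw map is kept as an attribute),
  since only relative levels are meaningful for a centrality score.
* **Integrated local correlation (LCOR)**: Gaussian-weighted (8-mm FWHM,
  truncated at 3σ, weights evaluated on voxel offsets in mm so anisotropic
  voxels are handled) average of a voxel's correlations with its neighbours,
  self term included. Two-voxel configurations have closed forms used in the
  tests, e.g. perfectly anti-correlated voxels at distance d give
  (1 − w)/(1 + w) with w = exp(−d²/2σ²).
* **Seed-to-voxel maps**: Fisher-z of seed-mean-to-voxel correlations;
  |r| = 1 (e.g. a single-voxel seed with itself) is clamped to 1 − 1e-7
  before atanh, with the clamp count reported as an attribute.

# Group statistics

* One-tailed paired t (post > pre) with n−1 SD; `paired_t_from_summary`
  reconstructs a difference vector with an exact mean and SD so published
  summary statistics can be pushed through the same code path.
* Shapiro–Wilk normality screen (wrapping `stats::shapiro.test`).
* Simple regression with r²-based inference (t = r√((n−2)/(1−r²)),
  two-tailed), used for the field-vs-connectivity-change regressions.
* **Voxel-wise inference**: per-voxel paired t across subjects, then
  sign-flip permutation cluster inference: two-tailed voxel threshold
  p < 0.005, 26-connectivity clustering (positive and negative tails
  separately), null distribution of the maximum cluster size over sign
  flips (exact under the symmetric paired null), cluster p = (1 + #{null ≥
  observed})/(n_perm + 1), Benjamini–Hochberg across clusters at q < 0.05.
  The t map returned by `voxelwise_paired_contrast` carries the subject
  difference matrix as an attribute because the permutation needs the
  per-subject maps, not just the t values.

# Electric-field model

`voxels_to_tetmesh` splits each labelled voxel into five tetrahedra with
parity mirroring so neighbouring voxels share diagonal faces (conformity is
tested by checking every face is shared by exactly one or two elements).
P1 (linear) elements discretise ∇·(σ∇V) = 0 with piecewise-constant
conductivities (defaults: WM 0.126, GM 0.276, CSF 1.65, bone 0.01, skin
0.465 S/m; tumor compartments 0.170/0.332/1.0/1.185 S/m; air 2.5e-14, gel
0.3, electrode 5.9e7). Element gradients are computed vectorised via the
adjugate, with node coordinates converted to metres so |E| comes out in V/m.

Electrodes are geodesic rectangles (default 70 × 50 mm, i.e. 35 cm² pads at
scalp positions corresponding to C3 and FP1) selected on the boundary faces;
the reported pad area projects each face normal onto the local radial
direction, correcting the staircase inflation of a voxelised sphere. The
anode injects a uniform current density (2 mA total) as a Neumann load; the
cathode is clamped to V = 0 (Dirichlet).

**Numerical choices.** The reduced symmetric system is solved with a sparse
Cholesky factorisation (`Matrix::Cholesky`, LLT, fill-reducing permutation);
on the default 254k-element phantom this takes ~20 s, versus minutes for
iterative or LU alternatives in R, and the relative residual (checked, must
be ≤ 1e-8) is ~1e-12. Per-element fields are volume-averaged back to voxels
(`efield_to_voxels`). Two audits back the solver: an analytic
Legendre-series oracle for the insulated homogeneous sphere with surface
point electrodes (`analytic_sphere_potential`, term-ratio truncation at
1e-10 with a 5-term stability window), compared after removing the constant
gauge offset between the Dirichlet and analytic conventions; and a discrete
current-conservation audit (`flux_through_plane`) summing σE·n over a
separating plane, averaging the one-sided estimates from both adjacent
element layers.

**Problem sizes** (grid extents, phantom radii, mesh densities) are package
defaults chosen for desk-scale runtimes, not physical claims; all of them are
configurable.

# Pipeline

`run_study` chains the stages per subject (generation → preprocessing →
seeds → pre/post metrics), then group statistics, optional voxel-wise
cluster inference on the IC maps, the per-subject phantom field solve (with
a jittered skull size), and the field-vs-Δconnectivity regressions. The
report is a JSON-serialisable list validated against the schema in
`inst/schema/`; provenance records the configuration, its hash, the master
seed and package/R versions (no timestamps, so identical configurations give
byte-identical reports). A `metrics` config field restricts which
connectivity metrics are computed, which matters for large replication
studies. The `exec/tdcsfc` script exposes `simulate`, `preprocess`, `seeds`,
`connectivity`, `efield`, `stats` and `run-all` subcommands over files.

```{r example, eval = FALSE}
cfg <- study_config(n_subjects = 4, grid_shape = c(16, 16, 14),
                    n_volumes_per_run = 60, n_runs = 1,
                    seed_source = "ground_truth",
                    do_voxelwise = FALSE, do_efield = FALSE)
report <- run_study(cfg)
report$group$interhemispheric_z$t
```

# Known limitations

* The synthetic BOLD noise model is white in time and space; calibration
  results (e.g. cluster false-positive rates) hold for this model and are
  not a claim about real autocorrelated fMRI noise.
* The phantom is spherical; electrode positions are parameterised by polar
  angles rather than measured 10–20 coordinates.
* `interpolate_potential` uses the owning voxel's tetrahedra only, so probes
  outside the labelled volume return NA rather than extrapolating.
* Voxel-wise cluster inference is implemented for the paired (sign-flip)
  design only.
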