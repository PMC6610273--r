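# tenoquant

Automatic quantification of tenosynovitis on contrast-enhanced MRI of the
wrist.

Tenosynovitis — inflammation of the synovial sheath surrounding a tendon —
is an early and independently predictive sign of rheumatoid arthritis on
T1-weighted, gadolinium-enhanced, fat-saturated (T1-Gd) MRI. The clinical
reference is ordinal visual scoring: ten tendon regions (extensor
compartments I–VI, flexor regions 1–4) each graded 0–3 by the maximum width
of enhancing peritendinous tissue (grade 1 < 2 mm, grade 2 2–5 mm, grade 3
≥ 5 mm). `tenoquant` computes a continuous, fully automatic counterpart for
researchers working on quantitative inflammation imaging, and ships a
synthetic wrist phantom so the whole pipeline is testable without patient
data.

## The measurement

Three stages:

1. **Super-resolution reconstruction (SRR).** The coronal (2 mm slices,
   0.2 mm gap) and axial (3 mm, 0.3 mm) scans are fused into one isotropic
   volume by regularized least squares,

       x* = argmin_x  Σ_k ‖A_k x − y_k‖² + λ‖Lx‖²,   λ = 0.05,

   with A_k the slice-window averaging model of scan k and L the discrete
   3D Laplacian, solved matrix-free by conjugate gradients.

2. **Segmentation and measurement ROI.** Bones and tendon landmarks come
   from multi-atlas registration with per-voxel majority-vote fusion;
   tendons are refined by marker-based watershed and filtered (mean
   intensity > 75 or volume < 0.01 ml rejected). The measurement ROI is the
   set of unlabeled voxels within D mm of a segmented tendon, inside the
   skin-bounded hand, between the axial slice where radius and ulna are
   closest (proximal) and the slice with the most hamate voxels (distal).

3. **Quantification.** Two-cluster fuzzy C-means on all image intensities
   adapts to the acquisition's intensity scale; memberships in the high
   cluster C2 are zeroed below the C2 center (one-sided C2 map `p_C2`), and
   the measurement is the fraction of ROI voxels with
   `T_L ≤ p_C2 < T_H`. The default operating point is
   `(D, T_L, T_H) = (3 mm, 0.82, 0.94)`; `grid_search()` re-derives it from
   a stratified training set by exhaustively maximizing the Pearson
   correlation with total visual scores.

## Worked example

Generate a synthetic wrist with a grade-2 sheath around flexor region 2,
simulate the two clinical acquisitions, and run the full measurement chain
(the phantom's ground-truth labels serve as a one-case atlas):

```r
library(tenoquant)

spec <- phantom_spec(dim = c(64, 64, 48), spacing = c(0.5, 0.5, 0.5),
                     sheath_mm = setNames(c(0,0,0,0,0,0,0,3,0,0), region_names()),
                     seed = 42)
truth <- generate_phantom(spec)
simulate_visual_scores(truth)$grades[8]   # flexor_2 grade
#> flexor_2
#>        2

axial   <- simulate_acquisition(truth, "axial")    # 0.5 x 0.5 x 3.3 mm
coronal <- simulate_acquisition(truth, "coronal")  # 0.5 x 2.2 x 0.5 mm
atlas   <- atlas_set(list(list(image = truth$image, labels = truth$labels)))

cfg <- pipeline_config(registration = "identity", srr_spacing = 0.5,
                       srr_max_iter = 60, srr_tol = 1e-5)
fit <- quantify_wrist(axial, coronal, atlas, cfg)
fit$result
#> <quant_result> fraction 0.0572 (2042 of 35692 ROI voxels in [0.82, 0.94))
fit$model
#> <fcm2_model> centers c1 = 10.473, c2 = 100.812 (m = 2, 11 iterations)
```

The fraction (about 0.06 here) is the per-patient measurement: the share of
the peritendinous shell whose one-sided C2 membership falls in the
calibrated window. A phantom with no inflammation measures near zero (not
exactly zero — bright vessels inside the shell contribute a small baseline,
the same false-detection mechanism seen clinically), and the fraction grows
with sheath thickness.

A full in-silico study — 30-phantom cohort over three severity categories,
stratified 5-per-category training split, exhaustive `(D, T_L, T_H)` grid
search, validation on the held-out phantoms:

```r
study <- run_phantom_study(pipeline_config(
  registration = "identity", n_phantoms = 30, n_per_category = 5,
  srr_max_iter = 30, srr_tol = 1e-5, seed = 7))
study
#> <phantom_study> 30 phantoms
#> <parameter_set> D = 2 mm, T_L = 0.01, T_H = 0.97 (training r = 0.9663)
#>   training   r = 0.9663 (n = 15)
#>   validation r = 0.9441 (n = 15)
```

A thin command-line front end over the same functions is installed at
`inst/cli/tenoquant` (subcommands `phantom`, `srr`, `segment`, `tendons`,
`roi`, `quantify`, `run-all`).

## Vocabulary

Label codes: 0 background; 1–6 extensor I–VI; 7–10 flexor 1–4; 11 carpal
block; 12 hamate; 13 radius; 14 ulna (`label_vocabulary()`).

See `vignettes/tenoquant-methods.Rmd` for the models, parameter rationale,
numerical choices, and what the phantom does and does not emulate.
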