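# radssm

Statistical shape modelling and neural-network classification of distal
radius point clouds.

## What this is for

Distal radius fractures come in distinct morphological patterns —
Colles'-type (dorsal angulation of the distal fragment), Smith's-type
(volar angulation) and Barton's-type (articular surface displacement) —
and the diagnostic criteria are quantitative: angulation beyond 20°,
displacement beyond 2 mm. `radssm` is a toolkit for analysts working
with 3-D bone surfaces reconstructed from CT who want to (a) build a
point-distribution statistical shape model (SSM) of the distal radius
and (b) train an intelligent classifier that discriminates normal bones
from the three fracture patterns using the shape-model coefficients as
features.

The pipeline is the classic SSM construction chain plus a small neural
network:

1. **Registration** — voxel-grid downsampling (1 mm) to ~2000 points,
   principal-axis pre-alignment with optional mirroring (right wrists
   onto a left-sided reference), point-to-plane ICP (convergence 1e-6,
   ≤ 100 iterations, 2.5 mm pair rejection) with a 0.5 mm RMSE quality
   gate, anchored on the proximal radius so a deformed distal end cannot
   drag the pose.
2. **Correspondence** — each registered cloud is reordered so point *j*
   matches the nearest neighbour of reference point *j*.
3. **Shape model** — PCA of the corresponded shape vectors:
   mean `T̄`, eigenmodes `φ_k`, eigenvalues `λ_k` (1/(N−1) covariance),
   cumulative contribution `Σ_{k≤t} λ_k / λ_T`, synthesis
   `T̃ = T̄ + Σ b_k φ_k` bounded by `|b_k| ≤ 3·√λ_k`.
4. **Classifier** — three-layer sigmoid network
   `H = sigmoid(WᵀΦ + B)`, `P = sigmoid(VᵀH + C)` trained by per-sample
   SGD on cross-entropy; per-class decision thresholds selected by
   Youden's J on training-fold ROC curves.
5. **Evaluation** — stratified 4-fold cross-validation at feature counts
   F = 5, 10, 15: per-class AUC, thresholds, confusion matrices,
   accuracy.
6. **Morphometrics** — the six anatomical indicators (distances AB, bc,
   AC, CD; angles ALF, ASR) from the four landmarks (sigmoid notch
   volar/dorsal lips, styloid vertex, Lister's tubercle), rule-based
   classification, and ANOVA/Tukey group comparison with Shapiro–Wilk
   and Levene assumption checks.

Because no imaging data ships with the package, a synthetic cohort
generator produces bone-like populations with a clinical case mix
(43 normal / 17 Colles' / 12 Barton's / 8 Smith's), known deformation
magnitudes, additive noise, random misalignment and point permutation —
with full ground truth, so every stage is testable end to end.

## Worked example

```r
library(radssm)

cohort <- generate_population(population_spec(seed = 1))
print(cohort)
result <- run_pipeline(cohort, pipeline_config(F_counts = c(5, 10, 15), seed = 1))
print(result)
print(result$group_variance)
```

Output (as printed by the code above):

```
synthetic_cohort: 80 subjects (barton 12, colles 17, normal 43, smith 8), 2000 points each
pipeline_result: 80 subjects, 32/80 passed the RMSE gate
pooled SSM rank 79, t = 5 (alpha = 0.75)
F = 5: mean accuracy 0.975, mean AUC 1.000
  per-class mean AUC: normal 1.000, barton 1.000, colles 1.000, smith 1.000
F = 10: mean accuracy 0.988, mean AUC 1.000
  per-class mean AUC: normal 1.000, barton 1.000, colles 1.000, smith 1.000
F = 15: mean accuracy 0.975, mean AUC 1.000
  per-class mean AUC: normal 1.000, barton 1.000, colles 1.000, smith 1.000
   group  n       F5       F10       F15
1 normal 43 80.83616  85.70862  90.01085
2 colles 17 80.37731  92.02774  99.18545
3 barton 12 86.35978  98.76539 100.00000
4  smith  8 84.93334 100.00000 100.00000
```

Reading this: the cross-validated classifier separates the four groups
essentially perfectly on the synthetic cohort (mean held-out accuracy
0.975–0.988 depending on the feature count; all per-class training AUCs
1.0), and the per-group cumulative-variance table shows the rank
saturation inherent to PCA — a group of 8 subjects has at most 7 shape
modes, so its cumulative contribution is exactly 100% at 10 or 15
components, and a 12-subject group saturates at 15.

The confusion matrix for F = 15 (`result$cv$reports$F15$confusion$total`):

```
        predicted
truth    normal barton colles smith
  normal     43      0      0     0
  barton      0     12      0     0
  colles      0      1     16     0
  smith       0      1      0     7
```

Each component is usable on its own: `read_point_cloud()` /
`write_point_cloud()` (XYZ, PLY, OBJ, ASCII STL), `estimate_normals()`,
`voxel_downsample()`, `initial_align()`, `icp_point_to_plane()`,
`reorder_to_reference()`, `fit_ssm()` / `project_shape()` /
`synthesize_shape()`, `measure_profile()` / `classify_by_rule()` /
`group_compare()`, `init_classifier()` / `train_sgd()` / `predict()`,
`roc_auc()` / `youden_threshold()` / `cross_validate()`. A thin
command-line front end with subcommands (`simulate`, `register`,
`correspond`, `build-ssm`, `measure`, `compare`, `train`, `predict`,
`cross-validate`, `run`) is installed at `inst/cli/radssm`.

See the vignette in `vignettes/distal-radius-shape-classification.Rmd`
for the model details, parameter conventions and design decisions.

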