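# voxrfe

Voxel-wise classification of two-group cohorts of co-registered 3D
functional brain volumes — perfusion SPECT or PET maps, or any modality
where each subject contributes one positive-valued image on a common grid
and the question is *which spatially coherent regions separate patients
from controls, and how well*.

The package is aimed at neuroimaging researchers who want a multivariate,
classifier-driven alternative to massunivariate voxel statistics: instead
of testing each voxel, it treats every in-mask voxel as a feature of a
support-vector machine and searches for the smallest spatially connected
voxel set that still classifies the cohort well.

## The method

Given a subjects × voxels matrix **X** (rows normalized to their
whole-brain mean) with labels *y* ∈ {control, positive}:

1. **Information-gain screen.** For every voxel *v*, compute
   IG(*v*) = H(*y*) − Σ_b (n_b/N) · H(*y* | b), where the bins *b* come
   from supervised recursive binary splitting of the sorted voxel values
   with the Fayyad–Irani MDL stopping rule. Voxels with IG(*v*) = 0 —
   the vast majority — are discarded. The MDL rule is what makes the
   screen sparse: a split is accepted only when its information gain pays
   for its own description length.
2. **Spatial clustering.** Surviving voxels are clustered on the integer
   lattice with a single-pass DBSCAN (ε = √2, MinPts = 2), under which a
   cluster is exactly a connected component of the 18-adjacency graph
   (faces + edges, not corners). Clusters smaller than 20 voxels are
   dropped; the 20 can be recalibrated for any grid by the package's
   Monte-Carlo cluster-extent simulation.
3. **Grid-searched SVM + recursive feature elimination.** On the active
   voxels, every kernel/parameter combination of the search grid (linear,
   RBF, polynomial, sigmoid × C-SVM, ν-SVM) is scored by stratified
   k-fold cross-validated F-measure (recall breaks ties). A linear C-SVM
   is then fit on all active voxels and the R = 100 features with the
   smallest |w_j| are eliminated; the loop returns to step 2 until ≤ R
   voxels remain.
4. **Model selection and evaluation.** The iteration with the best
   cross-validated F-measure wins; the selected voxel set and parameters
   are then evaluated by 10-fold CV and leave-one-out, and summarized per
   cluster (size, centroid, direction of the group difference, rank-sum
   p-values, optional atlas labels).

A synthetic cohort generator (smooth positive volumes, planted
ball-shaped effect clusters, configurable effect size/noise/smoothness)
makes the whole pipeline testable without clinical data, including a null
(effect-free) calibration mode and ground-truth recovery checks. A
leakage-free `nested_cv()` variant re-runs the entire selection inside
every training fold; the default protocol deliberately mirrors the
classical (optimistic) practice of selecting features on all subjects.

## Worked example

```r
library(voxrfe)

cfg    <- synth_config(n_pos = 20, n_ctrl = 20, effect_size = 0.3,
                       cluster_radius_vox = 4, seed = 1)
cohort <- generate_cohort(cfg)               # 40 subjects, 3 planted clusters
m      <- whole_brain_normalize(cohort$matrix)

fit <- voxrfe(m, grid = svm_param_grid(kernels = "linear",
                                       svm_types = "C_SVM"), seed = 101)
fit
#> Spatially constrained SVM-RFE fit
#>   input: 40 subjects x 30220 voxels
#>   information-gain survivors: 1719
#>   iterations: 11; best iteration 1 with 1155 voxels in 3 cluster(s)
#>   best parameters: linear/C_SVM cost=2
#>   selection CV F-measure: 1.000 (recall 1.000)

voxrfe_evaluate(fit, m, cv_folds = 10, seed = 2)$loo
#> <metrics_report> n=40 (positive: positive)
#>   tp=20 fp=0 tn=20 fn=0
#>   F=1.000 precision=1.000 recall=1.000 sensitivity=1.000 specificity=1.000

cluster_report(m, fit$best_labeling, fit$best_columns)[, c(1:5, 9:10)]
#>   cluster_id n_voxels centroid_x centroid_y centroid_z direction   min_p
#> 1          1      403       10.3       17.0       9.34 increased 6.8e-08
#> 2          2      385       22.2       11.1      19.19 decreased 6.8e-08
#> 3          3      367       19.4       31.3      23.97 increased 6.8e-08
```

Reading the output: the information-gain screen kept 1,719 of 30,220
in-mask voxels; the elimination loop ran 11 iterations; the selected model
uses 1,155 voxels in 3 spatially connected clusters (the 3 planted ones,
each surrounded by a thin halo of smoothed-in signal) and classifies every
held-out subject correctly under leave-one-out. The cluster report gives
each cluster's centroid, whether the positive group's perfusion is
increased or decreased there, and the best within-cluster rank-sum
p-value.

The same workflow runs from the shell via the thin CLI
(`inst/cli/voxrfe`): `simulate`, `fit`, `evaluate`, `report` and
`threshold_sim` subcommands driven by a YAML config (see `?voxrfe_cli`).

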