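# dcetrack

Voxel-wise analysis of longitudinal DCE-MRI for early prediction of
neoadjuvant treatment response in locally advanced breast cancer.

When a breast tumour is imaged with dynamic contrast-enhanced MRI before
treatment and again early during chemotherapy, two kinds of voxel-level
change carry prognostic information that tumour-wide averages wash out:

1. **How the tumour deforms.** A deformable registration supplies a
   transform `T(x) = x + u(x)` from pre-treatment to early-treatment
   coordinates. From the principal stretches `λ1 ≥ λ2 ≥ λ3` of `∇T` (its
   singular values), three per-voxel deformation features are computed:

   - the **Jacobian** `J = λ1·λ2·λ3`, the local volume ratio
     (contraction < 1 < expansion);
   - the **anisotropic deformation index**
     `ADI = sqrt(((λ1−λ2)/λ2)² + ((λ2−λ3)/λ3)²)`, zero for
     shape-preserving deformation;
   - the **slab–rod index**
     `SRI = atan(λ3(λ1−λ2) / (λ2(λ2−λ3))) / (π/2)` in [0, 1],
     distinguishing one-directional (rod, ≈1) from two-directional
     (slab, ≈0) anisotropy.

2. **How enhancement kinetics change.** From the three-timepoint curve
   `I(t0), I(t1), I(t2)` each visit yields peak enhancement (PE), wash-in
   slope (WIS), wash-out slope (WOS) and signal enhancement ratio (SER)
   per voxel, and each feature `F` gives a Jacobian-scaled **parametric
   response map** `PRM(x) = J(x)·F_early(T(x)) − F_pre(x)` over the
   pre-treatment functional tumour volume (FTV₁).

Each tumour is then summarised by seven voxel-wise heterogeneity indices
(fraction of expanding voxels for the Jacobian, fraction of increasing
voxels for the four PRMs, histogram entropy of ADI and SRI) plus five
aggregate analogues (FTV₂/FTV₁ and the relative change of each kinetic
feature's tumour mean). The modeling layer evaluates these features as
additions to a clinical baseline (age, race, hormone-receptor status,
FTV₂) with five-fold cross-validation: univariable ranking on the training
folds, nested best-subset selection by AIC, consensus refit of features
selected in ≥ 4 of 5 folds, likelihood-ratio comparison against the
baseline, and median-split risk-signature stratification with
Kaplan–Meier/log-rank analysis (logistic regression + AUC for pathologic
complete response; Cox regression + Harrell's C for recurrence-free
survival).

Because clinical trial images cannot be redistributed, the package ships a
synthetic phantom and cohort generator with analytic ground truth
(deformation, stretches, kinetic change, outcome models), so every stage —
registration included — is validated against known answers.

## Worked example

Generate a paired-visit phantom (a mildly responding tumour: 0.92 linear
contraction plus a small deformation bump, enhancement reduced ~10%),
segment the functional tumour volumes, and compute all eleven feature maps
and the per-tumour summary:

```r
library(dcetrack)

spec <- phantom_spec(grid_shape = c(32, 32, 32), seed = 7)
pair <- make_study_pair(spec)

ftv1 <- segment_ftv(pair$pre)
ftv2 <- segment_ftv(pair$early)
mask <- ftv1$values > 0.5

field <- pair$truth$true_displacement   # or register_baseline(...)
gT <- displacement_gradient(field)
stretches <- principal_stretches(gT)
J <- jacobian_map(stretches, mask, gT)
maps <- list(Jacobian = J,
             ADI = adi_map(stretches, mask),
             SRI = sri_map(stretches, mask))
kin_pre <- kinetic_maps(pair$pre, mask)
kin_early <- kinetic_maps(pair$early)
for (f in c("PE", "WIS", "WOS", "SER"))
  maps[[paste0("PRM_", f)]] <- prm_map(kin_pre[[f]], kin_early[[f]], field, J)

agg <- aggregate_features(kin_pre, kinetic_maps(pair$early, ftv2$values > 0.5),
                          attr(ftv1, "volume_cm3"), attr(ftv2, "volume_cm3"))
summarize_tumor(maps, agg, attr(ftv1, "volume_cm3"), attr(ftv2, "volume_cm3"))
```

```
<tumor_summary>
  voxel-wise indices:
frac_jacobian   frac_PRM_PE  frac_PRM_WIS  frac_PRM_WOS  frac_PRM_SER
       0.0000        0.0000        0.0000        1.0000        0.0005
  entropy_ADI   entropy_SRI
      -4.1216       -4.7108
  aggregate features:
ftv_ratio      d_PE     d_WIS     d_WOS     d_SER
   0.5242   -0.1488   -0.1488   -0.2904    0.0362
  FTV1 2.00 cm^3, FTV2 1.05 cm^3
```

Reading this: every tumour voxel contracted (`frac_jacobian = 0`, the
phantom's true volume ratio is 0.92³ ≈ 0.78) and lost peak enhancement
(`frac_PRM_PE = 0`), while the wash-out slope became less negative
everywhere (`frac_PRM_WOS = 1`) — the signature of a responding tumour.
The functional tumour volume roughly halved (`ftv_ratio 0.52`) because
shrinkage and reduced enhancement compound at the segmentation threshold.
The entropies are histogram-dispersion summaries of the ADI/SRI maps in
the printed (sign-kept) convention, bounded in `[-log2(32), 0]`.

For outcome modeling on a simulated cohort:

```r
tab <- simulate_cohort(cohort_spec(n_patients = 400,
                                   pcr_coefficients = c(frac_jacobian = log(3)),
                                   seed = 21))
rep_cv <- cv_select(tab, c("age", "race", "hormone_status", "ftv2_cm3"),
                    feature_names()[1:7], "logistic", k = 5, seed = 5)
consensus_refit(rep_cv, tab, c("age", "race", "hormone_status", "ftv2_cm3"),
                "logistic")$consensus
#> [1] "frac_jacobian"
```

A single-call orchestration (`run_pipeline(run_config(...))`) runs
phantom → preprocessing → registration → maps → summaries → models and
writes NIfTI maps, a summaries CSV, model reports and a provenance log to
a run directory.

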