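# filtrad

Filtration-histogram CT texture analysis with survival biomarker
evaluation, in R.

## What this is for

Quantitative CT texture parameters are studied as prognostic imaging
biomarkers in oncology — for example to ask whether the pre-treatment
heterogeneity of an advanced lung tumour predicts overall survival (OS) and
progression-free survival (PFS) under immunotherapy. The dominant
single-software workflow in that literature is the *filtration-histogram*
method: each axial slice of the CT volume is band-pass filtered with a
Laplacian-of-Gaussian (LoG) kernel at a spatial scale filter (SSF) of 0
(unfiltered) and 2–6 mm, and six first-order statistics are computed over
the histogram of the lesion's volume of interest (VOI) at each scale —
mean, standard deviation (SD), entropy, kurtosis, skewness, and the mean of
positive pixels (MPP):

```
MPP = mean( x : x > 0 ),   x = filtered (or raw, at SSF 0) VOI intensities
```

That yields 36 features per lesion (6 parameters × 6 SSFs). Their
prognostic value is then judged with the standard chain: ROC curves and AUC
against a binary progression label, Kaplan–Meier curves split at an optimal
threshold with a log-rank test for OS and PFS, and univariate Cox
proportional-hazards regression (Efron tie handling), with cut-point
p-values explicitly labelled exploratory.

`filtrad` implements that whole pipeline — imaging I/O (NIfTI, uncompressed
DICOM series, CSV tables), the LoG filtration and features, the statistics
chain, and an end-to-end reproducible runner — plus a synthetic cohort
generator that produces textured 3D lesion phantoms and survival outcomes
whose hazard depends on the lesion's true MPP, so every stage is testable
without patient data. It is aimed at methodologists who want an open,
tested reference for filtration-histogram radiomics and at anyone needing a
simulation bed for cut-point and screening statistics.

## Worked example

```r
library(filtrad)

# a 60-patient synthetic cohort: hazard ratio 0.89 per unit of true MPP
cfg <- run_config(
  cohort = cohort_spec(
    n_patients = 60, beta_mpp = -0.117, seed = 42,
    phantom = phantom_spec(grid_shape = c(14, 40, 40),
                           spacing_mm = c(2.5, 1, 1))
  ),
  out_dir = "run60"
)
report <- run_all(cfg)
print(report)
```

```
<analysis_report> 36 feature x SSF pairs screened, 18 passed (p < 0.05) to KM/Cox; 60 patients
 feature ssf       auc      p_value
     mpp   5 0.7732080 0.0004078447
     mpp   6 0.7720329 0.0004319524
     mpp   4 0.7638073 0.0006417605
      sd   2 0.7555817 0.0009433681
     mpp   3 0.7532315 0.0010510785
```

The table lists the top feature × scale pairs whose ROC analysis against
the progression label screened in (p < 0.05): here MPP at medium-to-coarse
filters separates progressors best (AUC ≈ 0.77). For each screened-in pair the
report also carries the optimal-threshold Kaplan–Meier split with its
log-rank test for OS and PFS (flagged exploratory — the threshold is
searched to minimise p) and the univariate Cox fit on OS; with a negative
`beta_mpp` the fitted MPP hazard ratios come out below 1 (0.947 per HU for
unfiltered MPP here, log-rank p = 0.00037 at its optimal split), i.e.
brighter texture is protective. `run60/` holds `features.csv` (one row per
patient × SSF, 36 feature values per patient), `report.json` and `run.log`;
rerunning the same config reproduces both files byte-identically.

Single-lesion use without the pipeline:

```r
ph  <- generate_phantom(phantom_spec(), seed = 1)
tab <- extract_feature_table(ph$volume, ph$mask)   # 6 rows x 6 features
roc <- roc_analysis(scores, labels)                # rank AUC, Youden cut-off
cox <- cox_univariate(feature, os_days, os_event)  # HR per unit, Wald CI
```

A thin CLI wraps the same functions
(`inst/cli/filtrad run --config cfg.yaml --seed 7 --out dir`), with
subcommands `simulate`, `extract`, `analyze`, `run`, `report`.

## Layout

```
R/                  implementation (imaging I/O, DICOM, filtration,
                    features, ROC/KM/log-rank/Cox, phantom/cohort, pipeline)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/          methods vignette: conventions, calibrations, limitations
inst/cli/filtrad    command-line entry point
inst/extdata/       packaged demo configuration
```
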