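# ufdce — ultrafast DCE-MRI kinetics and scan-duration analysis

Ultrafast dynamic contrast-enhanced (DCE) breast MRI samples the first
minute or two after contrast injection at a few seconds per phase and
summarises each lesion's wash-in with two semi-quantitative parameters
computed from the tissue concentration-time curve C(t):

* **maximum slope** — MS = max over consecutive samples of
  (C[i+1] − C[i]) / (t[i+1] − t[i]), including the segment from the
  injection-time anchor (0, 0);
* **initial area under the curve** — iAUC = ∫₀^60s C(t) dt (trapezoidal;
  shortened to the last timepoint when the series ends before 60 s).

Both are larger in malignant than in benign lesions. Because they use only
the early enhancement, the dynamic scan can in principle be truncated;
`ufdce` is a toolkit for asking *how short the scan may be* before
benign/malignant discrimination degrades. It is aimed at imaging
scientists prototyping ultrafast protocols and at statisticians who want a
fully reproducible, synthetic testbed for the analysis chain.

The package provides:

* a **cohort simulator** — extended Tofts curves
  (C(t) = vp·Cp(t−d) + Ktrans·∫Cp(τ)·e^{−Ktrans(t−d−τ)/ve}dτ) driven by a
  population arterial input function, with log-normal per-group kinetic
  distributions (default: 55 benign, 96 malignant lesions), optional voxel
  rendering through the spoiled-gradient-echo signal equation with Rician
  noise, and NIfTI/CSV export;
* a **relaxometry chain** — two-point variable-flip-angle T1 mapping and
  per-timepoint inversion of the SPGR equation to concentration via
  C(t) = (1/r1)(1/T1(t) − 1/T10);
* a **kinetics module** — eight nested dynamic sets (scan durations 40.5 s
  to 135 s at 4.5 s/phase) and per-lesion MS/iAUC on each, with the
  short-duration iAUC truncation handled explicitly;
* a **diagnostics module** — normality-gated group tests, Bonferroni-
  corrected paired cross-duration tests, DeLong AUCs and paired AUC
  comparisons, Youden cutoffs with exact Clopper–Pearson confusion-metric
  CIs, and ICC(A,1) observer agreement;
* an **end-to-end pipeline** returning a classed result with `print`,
  `summary` and `plot` methods, plus a thin CLI (`inst/cli/ufdce`).

## Worked example

```r
library(ufdce)
run <- run_end_to_end(ufdce_config(seed = 42))
summary(run)
#> Scan-duration analysis summary
#>   cohort: 55 benign, 96 malignant
#>   MS   best AUC 0.906 at SD_54s; shortest non-inferior duration: SD_40.5s
#>   IAUC best AUC 0.982 at SD_67.5s; shortest non-inferior duration: SD_54s

subset(run$roc_panel, parameter == "ms",
       select = c(duration_label, auc, sensitivity, specificity, accuracy))
#>  duration_label   auc sensitivity specificity accuracy
#>        SD_40.5s 0.892        81.2        89.1     84.1
#>          SD_54s 0.906        83.3        89.1     85.4
#>        SD_67.5s 0.906        83.3        89.1     85.4
#>          ...
#>         SD_135s 0.906        83.3        89.1     85.4
```

The summary reports, per parameter, the best AUC across the eight scan
durations and the shortest duration whose AUC is not significantly below
any longer one (Bonferroni-adjusted paired DeLong tests). In this seeded
synthetic cohort the maximum slope stabilises from the 54 s set onward —
the simulated bolus arrives around 15 s, so the 40.5 s set captures most
but not all of the wash-in. AUCs on synthetic cohorts are optimistic
relative to clinical data; the simulator targets the group *ordering*, not
vendor-scale absolute values.

Individual pieces work standalone, e.g. the confusion panel for a
published count table:

```r
confusion_metrics(tp = 47, fn = 49, tn = 41, fp = 14)
#>   sensitivity  48.96% (47/96) [38.61, 59.37]
#>   specificity  74.55% (41/55) [61.00, 85.33]
#>   ppv          77.05% (47/61) [64.50, 86.85]
#>   npv          45.56% (41/90) [35.02, 56.40]
#>   accuracy     58.28% (88/151) [49.98, 66.24]
```

See `vignettes/scan-duration-analysis.Rmd` for the model, conventions
(time origin, AIF anchoring, truncation rules) and numerical choices.

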