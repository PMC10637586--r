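# habitomics

Habitat radiomics for tumour sub-region analysis in R.

Solid tumours are heterogeneous: the biology driving a clinical endpoint
often lives in a sub-region ("habitat") rather than in the tumour as a
whole. `habitomics` implements the habitat-radiomics pipeline for a single
contrast-enhanced T1-weighted MR volume per patient, built around the
preoperative prediction of lymphovascular space invasion (LVSI) in cervical
cancer:

1. **Voxel maps** — per-voxel grayscale intensity and slice-wise local
   entropy `H = -Σ p_i log2(p_i + ε)` over a 5×5 in-plane window
   (32 bins).
2. **Habitat clustering** — k-means (k-means++/Lloyd) on the z-scored
   (intensity, entropy) features; the number of habitats k\* is selected by
   consensus clustering (1000 resamples at 80% by default, candidates
   2–10), summarised by the consensus-CDF area / delta-area curve and
   decided by PAC (proportion of ambiguous clustering); per-patient
   segmentation at k\*, habitats labelled by ascending mean intensity.
3. **Radiomics** — a native IBSI-style engine (first-order, shape, GLCM,
   GLRLM, GLSZM, NGTDM, GLDM; single-level stationary Haar wavelet and
   Laplacian-of-Gaussian filters) extracted from the whole tumour and from
   each habitat.
4. **Selection** — inter-reader ICC(2,1) ≥ 0.75, training-cohort
   z-scoring, greedy Pearson pruning at |r| > 0.9, LASSO logistic
   regression (5-fold CV, minimum-deviance λ).
5. **Models** — one RBF-SVM per region with cross-validated (C, γ),
   evaluated by AUC with DeLong 95% CI, paired DeLong tests against the
   whole-tumour reference, threshold metrics, calibration and
   decision-curve analysis.
6. **Clinical statistics** — the characteristics-table battery
   (Yates-corrected 2×2 and plain r×c chi-square, Fisher's exact test,
   pooled/Welch t from raw data or printed summaries, Mann–Whitney U,
   pooled stage-wise positivity).

Because the patient MRI data behind the published study are not deposited,
the package ships a **synthetic phantom cohort generator** with known
habitat ground truth (concentric-shell tumours with per-habitat intensity
and texture, two cohorts, a label signal planted in a designated habitat,
second-reader masks), so every stage is validated against planted truth.

## Worked example

```r
library(habitomics)

## statistics of the published two-centre clinical table
stats_report()[1:3, ]
#>   cohort          variable        test statistic            p
#> 1  train histological_type       chisq  3.650954 0.1611407934
#> 2  train   differentiation       chisq 17.986014 0.0001242758
#> 3  train               hpv chisq_yates  1.190151 0.2752991011

## pooled stage-wise LVSI positivity (exact)
counts <- lvsi_clinical_counts()
stagewise_proportions(t(counts$train$categorical$figo_stage),
                      t(counts$test$categorical$figo_stage))
#>   stage positive total  percent
#> 1     I       69   161 42.85714
#> 2    II       61   105 58.09524
#> 3   III       28    34 82.35294

## a small end-to-end synthetic run (every stage, seconds)
cfg <- default_config(seed = 7)
cfg$input$synthetic$cohort <- cohort_spec(n_train = 12, n_test = 6, seed = 3)
cfg$habitat$k_range <- 2:5
cfg$habitat$reps <- 50
cfg$habitat$max_items <- 600
cfg$radiomics$families <- c("firstorder", "glcm", "shape")
cfg$radiomics$filters <- "original"
rep <- run_pipeline(cfg)
rep
#> <run_report> k* = 3, 12 train / 6 test patients
#>   whole     train AUC ... | test AUC ... | features ...
#>   habitat1  ...
```

The run report carries k\*, the per-region feature funnel
(all → ICC → Pearson → LASSO), per-model train/test AUC with CI, DeLong
p-values against the whole-tumour reference, and the echoed configuration;
with `cfg$outdir` set it is also written as JSON.

A thin command-line front end lives at `inst/cli/habitomics.R`
(`generate`, `stats`, `run-all` subcommands).

## Scope

The published patient-level AUCs are not reproducible without the original
images and are not asserted anywhere; phantom experiments validate the
machinery, not clinical performance. See the methods vignette
(`vignettes/habitat-radiomics.Rmd`) for the models, every tunable default,
the generator's design and its limitations.
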