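# dectrod

Predicting axillary lymph node metastasis in breast cancer from the
*similarity* of quantitative dual-energy CT (DECT) parameters between the
primary lesion and the node — for radiologists and imaging researchers who
want a scanner-independent alternative to raw nodal enhancement values, and
for methodologists who want the full diagnostic workflow reproducible on
synthetic data.

## The statistic

For each of the DECT parameters measured in a circular ROI — attenuation at
40 and 70 keV, the spectral slope λHU = (att40 − att70)/30 keV, iodine and
water concentration, and effective atomic number — the **rate of difference
(ROD)** between the axillary node and the primary lesion is

```
ROD = |node − lesion| / |lesion|
```

ROD = 0 means the node looks exactly like the tumour on that parameter; a
metastatic node, whose tissue is being replaced by tumour, is expected to
have small RODs.  Because the ROD compares two ROIs from the *same* scan it
cancels scanner, protocol and contrast-timing effects that confound the raw
values.  For logistic modelling the ROD is rescaled to a similarity score
10·(1 − ROD), so greater similarity gives an odds ratio above 1.

Around the statistic the package provides: aorta normalisation of IC/WC/
Eff-Z, a calibrated synthetic cohort generator (latent-Gaussian copula with
group-specific lesion-node rank correlation: ~0.65 with metastasis, ~0.14
without), circular-ROI extraction from 2-D parameter maps with exclusion
masks, nonparametric group comparisons (Mann-Whitney, Fisher, chi-squared,
Spearman), univariable screening plus forward logistic regression, and
ROC/Youden threshold analysis in the full cohort and the small-node
(< 5 mm) subgroup.

## Worked example

The published metastatic example pair — node 288/108 HU, IC 31.8, WC 1039,
Eff-Z 9.34 against lesion 284/112 HU, IC 30.6, WC 1030, Eff-Z 9.28, with
printed slopes 6.0 and 5.7 HU/keV:

```r
library(dectrod)
lesion <- list(att40 = 284, att70 = 112, ic = 30.6, wc = 1030, effz = 9.28,
               lambda_hu = 5.7)
node <- list(att40 = 288, att70 = 108, ic = 31.8, wc = 1039, effz = 9.34,
             lambda_hu = 6.0)
similarity_profile(lesion, node)
#> Lesion-node ROD similarity profile (0 = identical):
#>  rod_att40  rod_att70 rod_lambda     rod_ic     rod_wc   rod_effz
#>     0.0140     0.0360     0.0530     0.0390     0.0087     0.0065
```

Every ROD is small — the node resembles its primary, as expected for a
metastasis.  The full pipeline on a synthetic cohort:

```r
rep <- run_pipeline(config = cohort_config(n_patients = 2000L, seed = 7L))
rep
#> DECT lesion-node similarity analysis report
#>   cohort: 2000 patients (586 metastasis / 1414 non-metastasis)
#>   seed 7, config 2702c77ea1b1acea3f58e12131522d05
#>   full-cohort AUCs:
#>     node_att40_hu   0.77
#>     node_att70_hu   0.81
#>     node_lambda_hu  0.72
#>     node_ic_mgcm3   0.73
#>     node_effz       0.71
#>     rod_att40       0.80
#>     rod_att70       0.81
#>     rod_lambda      0.79
#>     rod_ic          0.75
#>     rod_effz        0.75
```

Each similarity (ROD) marker matches or beats its raw-parameter
counterpart.  The combined logistic model shows the two independent
predictors — node size and lesion-node similarity — with the raw 40-keV
attenuation contributing almost nothing beyond them:

```r
rep$models$dect_with_shortest_diameter$coefficients
#>            term       OR       lo       hi       p
#>   node_short_mm 2.45e+00 2.21e+00 2.70e+00 2.2e-68
#>   node_att40_hu 1.01e+00 1.01e+00 1.02e+00 4.7e-06
#>   rod_att40_sim 2.25e+00 1.85e+00 2.72e+00 1.4e-16
```

(`rod_att40_sim` is the similarity score 10·(1 − ROD of 40-keV
attenuation); its OR is per unit score, i.e. per 0.1 of ROD.)

See `vignettes/dect-node-similarity.Rmd` for the model, the generator's
calibration and the numerical conventions.

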