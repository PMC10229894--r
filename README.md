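# restDC

Degree-centrality analysis and classification of resting-state fMRI
cohorts.

## What this package is for

Visual expertise studies ask whether intensive perceptual training (for
example, radiology interns reading thousands of X-ray films) leaves a
trace in the brain's intrinsic functional organization. A common way to
quantify that trace is **degree centrality (DC)**: treat every voxel (or
atlas region) as a node of a graph, connect nodes whose resting-state
BOLD time courses correlate positively above a threshold, and score each
node by the summed strength of its connections. Group differences in DC,
a classifier built on region-wise DC, and correlations between DC and
behavioral expertise scores together make up the analysis this package
implements end to end:

1. **Temporal preprocessing** — drop the first volumes, expand six
   rigid-body motion parameters to the Friston-24 regressor set, regress
   nuisance signals (global / white matter / CSF), remove linear trends,
   and band-pass filter (0.01–0.08 Hz ideal DFT filter). Optional 6 mm
   FWHM Gaussian smoothing.
2. **Degree centrality** — for node *i*,
   `DC(i) = sum_{j != i} w(r_ij) * [r_ij > 0.2]`, with Fisher
   `z = atanh(r)` edge weights by default (`binary` and raw-`r` weights
   available), normalized by the whole-brain mean, then averaged within
   atlas parcels (Brainnetome-style, 246 regions by default).
3. **Classification** — two-stage feature selection inside an outer
   leave-one-out loop: a two-sample t-test filter (p < 0.05), then
   recursive feature elimination where each feature's *contribution* to
   leave-one-out SVM accuracy decides removal; final evaluation with a
   linear soft-margin SVM (hinge loss, C = 1), reporting accuracy,
   sensitivity, specificity, the ROC staircase and the pair-counting
   AUC.
4. **Brain–behavior statistics** — Mann–Whitney U group comparisons for
   behavioral scores, and per-ROI Pearson correlation between DC and
   behavior with Benjamini–Hochberg FDR control.
5. **Synthetic cohorts** — because scanner data of this kind are rarely
   shareable, a generator simulates two groups of subjects as modular
   multivariate AR(1) processes with signed "degree" perturbations
   planted on selected ROIs and behavioral scores coupled to a
   designated region's DC. Every stage above is tested against it.

## Worked example

Simulate a 22 + 22 cohort with seven planted degree effects (the two
positive ones on the fusiform- and superior-frontal-analog regions),
compute region-wise DC after preprocessing, and run the nested
classifier:

```r
library(restDC)

cfg    <- simConfig(nPerGroup = 22, nRois = 50, nVolumes = 190, seed = 42)
cohort <- simulateCohort(cfg)
feats  <- t(vapply(cohort$series, function(s)
  roiDC(preprocessSeries(t(s), tr = 2)), numeric(50)))
fx     <- dcExperiment(feats, cohort$groundTruth@groupLabels[rownames(feats)])

report <- nestedEvaluate(fx)
report
#> ClassificationReport (nested)
#>   confusion: TP=22 FN=0 TN=22 FP=0
#>   accuracy 100.00%  sensitivity 100.00%  specificity 100.00%  AUC 1.0000

sort(report@consensusWeights, decreasing = TRUE)
#>   FuG_L_3_3   SFG_L_7_7     ROI_006     ROI_021   PhG_R_6_4   MFG_L_7_7
#>  0.28636601  0.27883174  0.12324741  0.01971915 -0.08053775 -0.14208031
#>   OrG_R_6_4   PhG_L_6_1   SFG_R_7_6
#> -0.14938141 -0.23345743 -0.32762661
```

The planted effects are cleanly separable at this effect size
(accuracy 100%), and the descriptive pooled-model weights recover every
planted region with the correct sign: positive weight = higher DC in the
expertise group. The brain–behavior correlation for the designated
region is strong but, at n = 22 against 50 regions, does not survive
FDR in this draw — a realistic power limitation:

```r
cors <- dcBehaviorCorrelation(fx, cohort$behavior)
cors[cors$roi == "FuG_L_3_3" & cors$measure == "ret", ]
#>        roi measure         r           p     p_fdr significant
#>  FuG_L_3_3     ret 0.6207625 0.002050793 0.1025397       FALSE
```

A command-line wrapper with `simulate`, `preprocess`, `dc`, `classify`,
`stats` and `run-all` subcommands lives at `inst/cli/dcx.R`; see the
header of that file for usage, and `vignettes/` for the methods
write-up.

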