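# gliomaOCT

Intraoperative optical coherence tomography (OCT) can tell glioma from white
matter at the resection margin: tumor attenuates the probing beam faster and
scatters it more heterogeneously. **gliomaOCT** implements the complete
inference stack around that physics, for researchers building or evaluating
OCT-based tissue-typing pipelines:

* **Parametric maps** — depth-resolved optical attenuation coefficient
  (OAC) per A-scan,
  `μs(j) = I(j) / (2Δ Σ_{i≥j} I(i))` in mm⁻¹, and refined speckle contrast
  (RSC), the sd/mean of the OAC field in a 10 × 20 px sliding window, with
  15 dB SNR masking.
* **Blockwise segmentation** — blocks of 20 adjacent A-scans summarised by
  (mean OAC, mean RSC) in a depth 20–40 px region of interest, classified
  by a standardized linear one-vs-rest SVM into normal white matter
  (green), damaged white matter (yellow) or tumor (red); grouped
  leave-one-out cross-validation with fold-contained scaling, one-vs-rest
  ROC/AUC, and rendered overlay maps.
* **Contextual override filter** — a deterministic rule engine modelling
  human-in-the-loop review of a segmentation map: scattered green-flanked
  red singletons are suppressed as noise, dense runs (especially with
  damaged-matter margins) are amplified, shallow evidence is discounted,
  and a scan-level tumor probability with a strict >50 % call comes out.
* **Reader-study evaluation** — pooled confusion counts,
  sensitivity/specificity/accuracy with half-up percent rounding,
  inter-rater consistency (pairwise agreement or Fleiss' kappa), 10,000
  iteration scan-level percentile bootstrap CIs, and CI-overlap modality
  comparison.
* **Synthetic data** — seed-deterministic B-scans (Beer–Lambert decay,
  2-D lognormal texture, fully developed exponential speckle, noise
  floor), cohorts with manifest files, and reader panels with known
  operating points, so everything above is testable with no patient data.

## Worked example

Train on a simulated cohort of 23 homogeneous 400-A-scan B-scans, segment a
scan with a tumor infiltration front, and review it with the contextual
filter:

```r
library(gliomaOCT)

coh <- simulateCohort(23, classMix = c(Normal = 8, DamagedMatter = 7, Tumor = 8),
                      width = 400L, seed = 11L)
blocks <- do.call(rbind, lapply(coh$scans, function(s)
  extractBlocks(computeParametricMaps(s), labels = scanLabel(s))))
nrow(blocks)
#> [1] 460

cv <- loocvPredict(blocks)                       # 23 scan-level folds
mean(cv$predicted == cv$label)
#> [1] 0.926
sc <- as.matrix(cv[, paste0("score_", tissueClasses())])
colnames(sc) <- tissueClasses()
round(multiclassROC(sc, cv$label)$auc, 3)
#>        Normal DamagedMatter         Tumor
#>         1.000         0.501         0.998

model <- trainTissueSVM(blocks)
scan  <- simulateBScan(layoutInfiltration(400, 200, 100), seed = 7)
maps  <- computeParametricMaps(scan)
seg   <- segmentScan(maps, model)
table(blockLabels(seg))
#>        Normal DamagedMatter         Tumor
#>            13             0             7

scoreScan(seg, depthExtent = blockDepthExtent(maps))
#> ScanVerdict 'sim': P(tumor) = 0.900 -> Tumor [no rules fired]
```

The 460 blocks are the 23 × 400/20 partition; out-of-fold accuracy is 0.93
with tumor-vs-rest separation near-perfect and damaged matter (the
intermediate class) hardest, as expected. The infiltration scan's 100
tumor A-scans plus margins light up 7 red blocks, and the filter confirms
the call with probability 0.9 (dense contiguous evidence, nothing to
suppress).

The filter earns its keep on tumor-free scans carrying algorithmic false
positives:

```r
fp <- simulateFalsePositiveMaps(nScattered = 9, nClustered = 4, seed = 2)
bv <- batchVerdicts(fp$segmaps, truth = fp$truth)
attr(bv, "overrides")
#> $n_overridden     : 9      # scattered maps, called WM against the machine
#> $n_fp_confirmed   : 4      # clustered maps that fool the reviewer too
#> $override_rate    : 0.692
```

`renderSegmentation(seg, scan, "map.png")` writes the green/yellow/red
overlay; `writeBScan()`, `writeFeatureTable()`, `writeAssessments()` and
`writeModel()` persist every stage in plain TIFF/CSV/JSON formats.

## Documentation

The methods vignette (`vignettes/gliomaOCT-methods.Rmd`) documents the
estimators and their bias characterisation, the masking policy, the filter
rules and their defaults, the bootstrap design, what the simulator does and
does not emulate, and known limitations.
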