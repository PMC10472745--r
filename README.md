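# pcleomics

Quantitative image analysis and transcriptomics for predicting response to
biologic therapy in inflammatory bowel disease (IBD), built around
probe-based confocal laser endomicroscopy (pCLE).

Predicting which IBD patients will reach endoscopic remission on a biologic
(anti-TNF or vedolizumab) is an open clinical problem. Two imaging readouts
carry signal: the *in vivo* microarchitecture of the colonic mucosa seen by
pCLE after intravenous fluorescein (crypt size and shape, vessel tortuosity,
fluorescein leakage), and the *ex vivo* binding of fluorescently labeled
drug to fresh biopsies. `pcleomics` implements the full computational side
of such a study for analysts working with annotated pCLE mosaics, biopsy
image stacks, endoscopic score tables and bulk RNA-seq: it is not an image
segmentation tool — crypt and vessel outlines are inputs, as they are drawn
by human readers.

## What it computes

**In vivo morphometry** (per annotated mosaic, aggregated per patient):

- vessel tortuosity τ = L_arc / L_chord (arc–chord ratio, ≥ 1);
- crypt area by the shoelace formula, eccentricity e = √(1 − (b/a)²) from
  the polygon's second central moments, equivalent circular diameter
  2√(A/π);
- wall thickness as the mean radial gap between lumen and outer outline
  over 72 rays from the centroid;
- intercrypt distance (ICD) as the nearest-neighbour boundary gap;
- fluorescein leakage (FLCM) as mean intensity in a pericryptic annulus
  versus "elsewhere" (outside all crypts and annuli).

**Ex vivo drug-binding quantification** (per specimen stack): pixels with
temporal SD < ϑ_σ (default 0.01) across the stacked frames are discarded as
acquisition artifacts; on the retained pixels the pooled mean μ and SD σ
give a conservative threshold ϑ_con = μ + 2σ and a relaxed threshold
ϑ_rel = μ; each frame is read out as hyperfluorescent area and mean
intensity above each threshold, summarized as mean/max per specimen.

**Response prediction**: endoscopic response labeling (UC: Mayo ≤ 1 &
UCEIS ≤ 1 & PICaSSO ≤ 3 for remission, Mayo 3 / UCEIS ≥ 7 / PICaSSO ≥ 8 for
nonresponse, partial otherwise; CD: SES-CD reduction ≥ 50% for remission,
post > 75% of baseline for nonresponse), Wilcoxon signed-rank pre/post
testing, and leave-one-out cross-validated univariate logistic regression
reporting AUROC, accuracy, PPV and NPV per feature.

**Transcriptomics**: log2(TPM+1) transform, empirical-Bayes moderated-t
differential expression (prior df and variance fitted by the log-variance /
trigamma method of moments), Benjamini–Hochberg FDR, the adjusted p < .05
and fold-change > 2 DEG filter, PLS-DA (NIPALS PLS1) with variable
importance in projection (VIP > 1 gene selection, mean VIP² = 1 identity),
and a combined-panel ROC with stratified bootstrap CI.

**Synthetic data**: seeded generators for every input — annotated mosaics
with known crypt/vessel geometry, ex vivo stacks with known artifact/blob
masks, responder/nonresponder cohorts, and TPM matrices with planted fold
changes — so the entire pipeline is testable against ground truth.

## Worked example

```r
library(pcleomics)

## in vivo arm: generate an annotated mosaic, measure it, aggregate
out <- generate_mosaic_scene(scene_config(n_crypts = 5, n_vessels = 2, seed = 42))
rec <- measure_scene(out$scene)
aggregate_patient(list(rec))
#>   mean_vessel_tortuosity max_crypt_area mean_crypt_eccentricity
#> 1                    1.3       2815.593                   0.483
#>   max_crypt_diameter mean_icd mean_wt max_flcm_pericrypt mean_flcm_elsewhere
#> 1             59.874   82.468   6.041              20000               12000

## ex vivo arm: dual-threshold quantification of a drug-binding stack
st <- generate_exvivo_stack(stack_config(n_images = 12, image_size = c(96, 96),
                                         artifact_fraction = 0.05,
                                         blob_fraction = 0.1, seed = 7))
q <- quantify_stack(st$stack)
q$thresholds
#> <exvivo_thresholds mu=0.3329 sd=0.1061 con=0.5450 rel=0.3329>
round(q$specimen$mean_frac_con, 4)
#> [1] 0.0945        # ~9% of retained tissue is hyperfluorescent at mu + 2*sigma

## response arm: LOOCV logistic evaluation of each patient-level feature
coh <- generate_cohort(cohort_config(seed = 1))   # 20 responders, 9 nonresponders
rep <- evaluate_features(coh$features, coh$labels)
head(rep[order(-rep$auroc), c("feature", "auroc", "accuracy", "ppv", "npv")], 3)
#>             feature     auroc  accuracy ppv       npv
#>      max_crypt_area 0.9666667 0.9310345   1 0.8181818
#>  max_crypt_diameter 0.9222222 0.8620690   1 0.6923077
#>  max_flcm_pericrypt 0.9222222 0.8275862   1 0.6428571

## transcriptomic arm: DE -> DEG filter -> PLS-DA/VIP -> panel ROC
ex <- generate_expression(expr_config(n_genes = 1000, planted_de_count = 50,
                                      planted_log2fc = 2, seed = 3))
lg <- log_transform(ex$tpm)
de <- moderated_de(lg, ex$groups)
degs <- de_filter(de)                      # adj p < .05 and |log2FC| > 1
sprintf("DEGs: %d (%d up, %d down)", nrow(degs$genes), degs$n_up, degs$n_down)
#> "DEGs: 50 (25 up, 25 down)"
pls <- plsda_fit(lg[degs$genes$gene_id, ], as.integer(ex$groups == "responder"))
panel <- names(sort(vip_scores(pls), decreasing = TRUE))[1:7]
pa <- panel_auc(lg, panel, as.integer(ex$groups == "responder"), seed = 4)
sprintf("panel AUROC %.3f (95%% CI %.3f-%.3f)", pa$auroc, pa$ci[1], pa$ci[2])
#> "panel AUROC 1.000 (95% CI 1.000-1.000)"
```

The AUROC table reads exactly like a per-feature biomarker report: each row
is one imaging feature evaluated as a univariate predictor of responder
status, with the AUROC over held-out LOOCV probabilities and the confusion
metrics at the Youden-optimal cutoff. On this synthetic cohort the planted
class differences make crypt area the strongest discriminant; the 50
planted genes are recovered exactly and the 7-gene VIP panel separates the
groups completely.

## File formats

- **Scenes**: grayscale TIFF/PNG (8/16-bit) plus a GeoJSON
  FeatureCollection; crypt outlines are `Polygon` features with properties
  `role` (`"outer"`/`"inner"`) and `crypt_id`, vessels are `LineString`
  features with `vessel_id`. Coordinates are 0-based, origin top-left,
  x = column, y = row, in pixels; micrometre conversion happens only at
  measurement time via `pixel_size`.
- **Stacks**: multi-page TIFF, intensities normalized to [0, 1] on load.
- **Clinical scores**: CSV with header
  `patient_id,disease,timepoint,Mayo,UCEIS,PICaSSO,SES_CD`.
- **Expression**: TSV, genes as rows, first column `gene_id`, values on
  the TPM scale.

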