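---
title: "Models and methods in pcleomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pcleomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pcleomics)
```

`pcleomics` quantifies mucosal architecture and drug binding from
probe-based confocal laser endomicroscopy (pCLE) in IBD patients starting a
biologic, and evaluates imaging features and gene panels as predictors of
endoscopic response. This vignette records the models, the operational
definitions behind each measurement, the parameter defaults, and the design
choices that were genuinely open — together with what the synthetic-data
checks do and do not establish about real data.

## In vivo morphometry

Crypt and vessel outlines are manual annotations (polygons and polylines in
pixel coordinates); the package measures them, it does not segment. All
geometry stays in pixels until measurement time, when `pixel_size` (µm/px)
converts it once — so every length scales linearly and every area
quadratically with pixel size, and dimensionless quantities (tortuosity,
eccentricity) are unaffected. No pCLE vendor states a canonical pixel size;
1 µm/px and a 16-bit dynamic range are configuration defaults, not claims
about any instrument.

Several features of this panel circulate in the endoscopy literature
without an agreed mathematical definition. The conventions adopted here
are the ones a morphometrist would reach for, and each is validated
against closed forms and generator truth:

- **Vessel tortuosity** is the arc–chord ratio, total centerline length
  over endpoint distance. It is the standard distance-factor index: 1 for
  straight vessels, invariant to rigid motion and scale, and undefined for
  closed loops (an explicit error).
- **Crypt area** uses the shoelace formula on the vertices — a vector
  measurement independent of rasterization. The pixel-counting alternative
  exists only as a test oracle.
- **Eccentricity** comes from the polygon's second central moments,
  computed continuously by Green's-theorem line integrals, as
  `e = sqrt(1 - (b/a)^2)` of the ellipse of inertia — the regionprops
  convention, but resolution-independent.
- **Diameter** defaults to the equivalent circular diameter `2*sqrt(A/pi)`,
  which is unambiguous for non-elliptical outlines; a maximum-Feret variant
  is available (`diameter_method = "feret"`).
- **Wall thickness** needs a lumen outline; it is the mean over 72 radial
  rays from the shared centroid of the outer-minus-inner crossing
  distances. Rays that miss a boundary are excluded with a warning, and
  crypts without a lumen annotation yield a *missing* value — imputing 0
  would bias the patient aggregate. 72 rays keep the discretization error
  of the mean gap well below 1% for crypt-like shapes.
- **Intercrypt distance (ICD)** is the nearest-neighbour boundary gap —
  the stromal space between glands, which is what "distance between
  crypts" means at histology scale — not the center distance (available
  via `mode = "center"`). Outlines are treated as densely sampled, so the
  gap is the minimum vertex-to-vertex distance; with the ~100-vertex
  outlines produced by annotation tools the sampling error is far below a
  pixel. "Crypt distribution along the mucosal surface" is realized as the
  ICD summary statistics rather than as a separate feature, since no
  independent definition exists for it.
- **FLCM** (fluorescein leakage through the colonic mucosa) is the mean
  intensity in a pericryptic annulus — the morphological dilation of each
  crypt's outer outline by `annulus_width` (default 10 µm), minus every
  crypt interior — contrasted with "elsewhere", the image outside all
  crypts and all annuli. Overlapping annuli are handled by set semantics:
  each crypt reads its own annulus; "elsewhere" excludes the union.

Per-patient aggregation pools structures across all the patient's mosaics
(ten per patient in the intended protocol) and then takes the summary each
feature is reported with (mean tortuosity, maximal crypt area, mean
eccentricity, maximal diameter, mean ICD, mean WT, maximal pericryptic
FLCM, mean elsewhere FLCM). Pooling structures rather than averaging
per-mosaic means keeps mosaics with a single crypt from carrying the same
weight as mosaics with twenty; the mean-of-means variant is available via
`pooling = "mosaic_means"`.

## Ex vivo drug-binding quantification

Biopsies incubated with fluorescein-conjugated drug (or an isotype
control) are imaged as a stack of aligned frames per specimen. The
quantification is deliberately simple and fully reproducible:

1. **Artifact masking.** Pixels whose intensity SD across the stack's
   frames is below `theta_sigma = 0.01` are discarded: tissue flickers
   frame to frame, optical artifacts do not. The SD is the *sample* SD
   (N−1 denominator) — with the small frame counts typical per specimen
   the convention matters, so it is fixed and documented. Stacks need at
   least 2 frames for the SD to exist.
2. **Threshold construction.** The retained pixels of *all* frames of the
   specimen are pooled; their mean and SD give the conservative threshold
   `theta_con = mu + 2*sigma` (fewer pixels selected) and the relaxed
   threshold `theta_rel = mu`. Pooling across frames (rather than
   per-frame thresholds) makes the two cuts commensurable across the
   stack.
3. **Readout.** Per frame: pixel count and retained-fraction above each
   threshold (selection is strict `>`, so ties at the threshold are
   excluded), mean intensity of the selected pixels (missing, not zero,
   when nothing is selected), and the whole-frame retained mean. Per
   specimen: mean and max of each across frames.

Intensities are normalized to [0, 1] on load; the 0.01 SD cut is unitless
only on a fixed scale, and normalizing makes it meaningful across bit
depths. Whether the original analysis normalized before or after
estimating µ and σ is unknowable from the outside; the [0, 1] convention
here is declared, not inferred. Isotype-control stacks are quantified
identically and compared, not subtracted.

By construction `theta_con >= theta_rel`, so the conservative area can
never exceed the relaxed area, and adding constant (artifact) pixels to a
stack changes no readout — both are enforced as tested invariants.

## Response labeling and prediction

**Labeling.** UC response is read from the post-treatment endoscopy:
remission (responder) requires Mayo ≤ 1 *and* UCEIS ≤ 1 *and* PICaSSO ≤ 3;
nonresponse is Mayo 3 *or* UCEIS ≥ 7 *or* PICaSSO ≥ 8; partial response is
everything else. The published clinical bands overlap (PICaSSO 8 appears
in both the partial and nonresponse bands) and leave gaps (UCEIS 5–6):
the package resolves this with the precedence remission > nonresponse >
partial and assigns the unassigned middle band to partial, the clinically
conservative reading. CD uses the SES-CD ratio: remission at a reduction
of ≥ 50% (boundary inclusive, per the "≥"), nonresponse when the
post-treatment score exceeds 75% of baseline, partial between — so
exactly 75% is partial. The binary label treats partial responders as
responders by default (`policy = "partial_as_nonresponder"` gives the
sensitivity analysis); the category and the rule inputs are retained for
audit.

**Paired testing** of pre/post change uses the Wilcoxon signed rank
(exact for ≤ 25 informative pairs without ties, normal approximation with
continuity correction otherwise, zeros dropped). The original analysis
names no test; the signed rank is the conservative default for skewed
imaging features, and a paired t-test is available via `method = "ttest"`.

**LOOCV logistic evaluation.** Each feature is assessed as a univariate
predictor: for each patient, an intercept-plus-feature logistic model is
fitted on the remaining n−1 and the held-out probability recorded; AUROC
(Mann–Whitney form, half-credit for ties) is computed over the held-out
probabilities, the cutoff maximizes Youden's J on them (max-accuracy
selection via `cutoff_rule = "accuracy"`), and accuracy/PPV/NPV follow.
Undefined ratios (empty predicted class) are reported missing, never 0.

Two numerical points deserve note. First, with ~29 patients a separating
feature makes the ML fit diverge; such folds (detected by a near-zero
training deviance or non-convergence) fall back to a Newton fit with a
small ridge penalty (λ = 1e-4 on the slope), keeping the held-out
probability defined without materially changing well-posed fits; the fold
count is flagged in the report. Second, LOOCV has a known pessimistic
bias under the null: leaving out a responder lowers the training
prevalence, so with an uninformative feature the held-out probabilities
rank *against* the labels, and a single null AUROC can fall far below
0.5 — occasionally to 0 when the slope draw is near zero. The package
reports what the procedure yields; users comparing a feature against
"chance" should permute labels rather than assume 0.5.

## Transcriptomic arm

Expression arrives as TPM (genes × samples); the analysis operates on
`log2(TPM + 1)`. The base is 2 so that the conventional "greater than
2-fold change" filter is exactly |log2FC| > 1 and fold changes read
naturally; the pseudo-count keeps zeros finite.

**Moderated differential expression.** Per gene, a two-group linear model
(the group means) yields a residual variance on n−2 df. Variances are
shrunk toward a common prior by the standard empirical-Bayes scheme: the
prior df `d0` and prior variance `s0²` are estimated by the
method of moments on the scaled-F distribution of the sample variances,
working on log variances via digamma/trigamma identities (the trigamma
inverse is a Newton iteration), and the posterior variance is
`(d0·s0² + dg·sg²)/(d0 + dg)`. The moderated t uses `d0 + dg` df. Forcing
`d0 = 0` recovers the ordinary t-test exactly and `d0 = Inf` the fully
pooled statistic — both are exposed (`d0_override`) and tested, and the
default fit is cross-checked against an independent reference
implementation in the test suite. The published pipeline also mentions a
robust M-estimation fit and a library-size re-estimation step; with a
two-group design OLS is exact, so robustness is offered only as a
winsorized-variance prior fit (`robust = TRUE`, clipping log-variances at
the 5th/95th percentiles before moment fitting), and library-size
re-estimation is deliberately not implemented — TPM input is already
within-sample normalized, and re-estimating sizes from it would be
incoherent.

**Filtering.** Benjamini–Hochberg adjusted p < 0.05 *and* fold change
strictly greater than 2, both boundaries exclusive, with the up/down split
by the sign of log2FC.

**PLS-DA and VIP.** Discriminant PLS is NIPALS PLS1 against the centered
0/1 class vector, on column-centered, unit-variance-scaled genes
(scaling is conventional for expression PLS and is toggleable), with
X-deflation per component; scores are orthogonal and the fit is
deterministic. Two components are the default — enough to draw the usual
score plot and stable at small n. VIP scores use the explained
class-variance weighting; the identity mean(VIP²) = 1 holds exactly by
algebra and is asserted on every fitted model, which makes the
conventional VIP > 1 selection rule a statement about
"more-than-average" contribution.

**Panel ROC.** A gene panel is summarized by its first PLS component
score, oriented toward the responder class; the AUROC of that composite
is reported with a stratified percentile bootstrap CI (2000 resamples,
seeded — the CI method behind the published panel AUCs is unstated, so
this one is declared).

## The synthetic-data module

Every input has a seeded generator with recorded ground truth, which is
what makes the downstream arms testable without patient data. All
randomness flows through one seed per call (`withr::with_seed`), so every
generator is byte-reproducible.

- **Scenes**: crypts are ellipses with log-normal areas (default
  meanlog = log(2000 µm²), sdlog 0.25 — colonic crypt scale), uniform
  eccentricities (0.2–0.7), a fixed lumen offset (6 µm wall), placed by
  rejection sampling under a minimum boundary gap (10 µm) with an
  explicit "scene infeasible" error after a retry cap — never a silent
  overlap. Vessels are smoothed random walks whose perpendicular
  amplitude is bisected until the arc–chord ratio hits the target
  (±1e-3). The intensity image is background + a constant leakage halo in
  the pericryptic annulus + optional Gaussian noise; the halo uses the
  same annulus construction as the FLCM measurement, which makes the
  leakage readout exactly checkable at zero noise. Truth records the
  generating parameters, with wall thickness stored as the *realized*
  mean radial gap of the two ellipses (the offset construction does not
  produce a constant-width wall, so the generating offset alone would be
  the wrong reference) and ICD from densely resampled outlines.
- **Stacks**: artifact pixels constant across frames (temporal SD exactly
  0), tissue i.i.d. Normal(0.3, 0.05) per frame, hyperfluorescent blobs as
  discs fixed in place with Normal(0.6, 0.05) intensities, clipped to
  [0, 1]; truth masks returned.
- **Cohorts**: per-patient features from class-conditional normals. The
  default design is 20 responders vs 9 nonresponders — the binary split
  of a 29-patient cohort once partial responders are counted with
  responders — with effect sizes of roughly 1–3 within-class SDs
  (responders: lower tortuosity, smaller rounder crypts, less leakage),
  plausible magnitudes for treatment-responsive mucosa. An endoscopic
  score table consistent with each patient's class is emitted so the
  labeling rules can run end to end.
- **Expression**: gene abundances on the log2 scale (baseline
  N(5, 1.5), within-group SD 0.5), planted genes shifted by ±log2FC in
  the responder group (alternating signs), columns rescaled to the TPM
  convention (sum 1e6).

What the generators *do not* emulate: pCLE texture (honeycomb epithelium,
mosaicking seams), optical blur, annotation error, within-patient feature
correlation, count-based expression noise (mean–variance coupling), or
batch structure. Passing the round-trip and recovery checks therefore
shows the measurements and statistics are correct *as specified*, not that
the pipeline is robust to every property of clinical data.

## Problem sizes and numerical conventions

The verification suite uses sizes chosen to make the statistical checks
sharp while remaining quick on a single CPU: 50 seeded scenes for the
morphometry round trip (tolerances: area 3%, eccentricity 0.02,
tortuosity 0.05, wall thickness 5%, ICD 1 px at zero noise), 20 scenes
against the brute-force ICD oracle (agreement to 1e-9), 10⁴ random stacks
for the threshold-ordering invariant, LOOCV at n = 500 against the
closed-form AUROC `pnorm(delta/(sigma*sqrt(2)))` (within 0.03), 10⁴
replicates for signed-rank type-I calibration, 1000 random vectors for
the BH oracle, 100 null replicates for end-to-end FDR control, and a
500-sample cohort for the 7-gene panel against its closed-form composite
AUC. `scripts/acceptance.R` re-runs the pipeline at comparable sizes and
writes every quantity it computes to JSON.

Smaller conventions, fixed so results are bit-reproducible: ray–edge
intersection accepts a 1e-9 tolerance at shared vertices (a ray grazing a
polygon corner hits both adjacent edges at equal distance, so the minimum
is unaffected); polygon orientation is normalized counterclockwise on
construction; images are (row = y, col = x) matrices with 0-based
top-left-origin coordinates declared in every annotation file; scenes
written at 8 or 16 bit store `intensity / (2^depth − 1)` so integer
images round-trip exactly.

## Known limitations

- The four imaging features without published definitions (tortuosity,
  WT, ICD, FLCM) are validated against their own declared conventions and
  synthetic truth; agreement with any in-house implementation of the same
  names cannot be established from the outside.
- LOOCV AUROC at n ≈ 29 has high variance and a pessimistic null bias
  (see above); reported AUROCs for weak features should be read
  accordingly.
- The ex vivo scheme assumes aligned frames; no registration is applied.
- PLS-DA flavor (PLS1, unit-variance scaling, 2 components) is a declared
  choice among defensible variants; VIP rankings can differ between
  flavors even when the identity mean(VIP²) = 1 holds in each.
- The transcriptomic arm takes TPM as given; no attempt is made to model
  counts, length bias, or batch effects.
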