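---
title: "Quantifying NAFLD histology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NAFLD histology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaquant)
```

## The measurement problem

NASH CRN scoring compresses each histologic feature of nonalcoholic fatty
liver disease into a handful of ordinal levels assigned by eye. `hepaquant`
instead measures each feature as a proportional area: the percentage of tissue
pixels occupied by fat vacuoles, inflammatory infiltrate and ballooned
hepatocytes on H&E, and by fibrillar collagen on picrosirius red (the collagen
proportionate area, CPA, after structural-collagen exclusion). Proportional
areas are continuous, reproducible, and sensitive to changes that an ordinal
scale cannot resolve — but they measure something related to, not identical
with, the ordinal scores: the inflammation score counts foci while the
pipeline measures infiltrated area, so the two correlate without mapping
one-to-one.

Every percentage uses the same denominator: the tissue mask. A pixel is
background iff `min(R,G,B) >= 220` and saturation `< 0.08` (near-white slide
glass in both stains); fragments smaller than `min_component_px` (default 256
at 1 µm/px, rescaled by `pixel_size_um^-2` when physical size is known) are
debris; interior holes up to `max_hole_px` are filled so that fat vacuoles —
which are optically empty — still count as tissue. Physical pixel size is
optional metadata throughout: scan resolution varies between sites, so all
defaults are expressed in pixels with an optional µm rescale.

## H&E segmentation

**Stain separation.** RGB is converted to optical density
(`OD = -log10((I+1)/256)`) and projected onto fixed hematoxylin
`(0.65, 0.70, 0.29)` and eosin `(0.07, 0.99, 0.11)` unit vectors
(Ruifrok–Johnston convention), negative projections clipped at zero. The
vectors are config keys (`[stains]`) so a different colour model can be
swapped in; automatic stain-vector estimation is out of scope.

**Fat.** Candidates are bright low-saturation pixels inside tissue
(`min(R,G,B) >= 200`, saturation `< 0.15`). Components are kept iff their area
lies in `[30, 15000]` px and their circularity `4πA/P²` is at least 0.55. The
perimeter is EBImage's boundary-pixel estimate, under which a rasterized disc
scores ≈ 1.3 and thin or ragged shapes (sinusoids, tears, vessel lumina) fall
well below 0.5, so 0.55 is a wide margin on both sides.

**Inflammation.** Without a trained model, nuclear pixels are hematoxylin
density above a threshold; components survive if they are at least
`min_focus_px` = 150 px and carry at least 20 nuclear local maxima per 10⁴ px
(dense small-nucleus clusters), after morphological closing (radius 2 px) to
bridge nuclei within a focus. Isolated nuclei fail the size test; ballooned
cells contribute a single maximum and fail too.

**Ballooning.** Pale-cytoplasm pixels are eosin density below a threshold,
excluding fat and bright pixels; components survive if hepatocyte-scale
(area in `[400, 5000]` px) and retaining a nucleus (≥ 1 hematoxylin local
maximum inside).

**Threshold choice.** The nuclear and pale thresholds default to an Otsu split
of the tissue stain-density histogram, guarded by absolute bounds (nuclear
threshold never below 0.30 OD, pale threshold never above 0.45 OD). A fixed
percentile is available (`threshold_method = "percentile"`, constants 97/30),
but a fixed percentile pins the selected area to a fixed share of tissue,
which cannot track lesion burdens that legitimately range over 0.5–30% of
tissue across disease severity; the bimodal split adapts, and the guards keep
it from hallucinating lesions in unimodal (blank or lesion-free) tissue.
Degenerate inputs are handled explicitly: blank tissue yields empty masks, an
empty tissue mask is a precondition error rather than a downstream
division by zero.

**Quantitation.** Masks are made pairwise disjoint with priority
fat > inflammation > ballooning before percentages are computed — vacuole
identity is the most optically certain of the three. Percentages are exact
ratios kept at full precision; reports round to 2 decimals (statistics to 3)
with a full-precision JSON sidecar.

## The region classifier

The machine-learning path is a seeded random forest (`ranger`, 200 trees,
depth ≤ 12) over windowed features: mean/sd of R, G, B; mean/sd of
hematoxylin and eosin OD; bright-pixel fraction; local entropy of a 16-bin
gray histogram; nuclear-maxima count; plus a larger-window (25 px) hematoxylin
mean and maxima count for context (a single nucleus and a focus look alike up
close). Training tiles take the majority ground-truth label at ≥ 60% purity,
impure tiles are dropped. The tile edge defaults to 8 px: prediction evaluates
the same window statistics centred at every pixel, so train and inference
features share definitions, and the misclassification band around lesion
boundaries stays within a few pixels — with 16 px windows the blur around the
many small vacuoles would dominate the error budget. Feature extraction is
versioned (`hqfeat-1`) and models refuse to predict under a mismatched
extractor version. Training is bit-reproducible for a fixed seed
(single-threaded, seeded ranger).

## Sirius red and the CPA

Collagen signal is membership of the pixel's HSV colour in the red band: hue
in `[-30°, +25°]` (wrapping through red), saturation ≥ 0.35, value ≥ 0.2,
each with a linear ramp (10° / 0.1) at the band edge; the signal is the
product of the three memberships, so the definition is library-free and
bit-exact. Pixels at signal ≥ 0.5 inside tissue, despeckled at 16 px, form the
collagen mask.

Structural collagen is excluded automatically, in rule order:

1. **capsule** — the component overlaps the tissue-boundary band (within
   `capsule_band_px` = 20 of the edge) by ≥ 25% of its area and is thin:
   elongation `P²/(4πA)` ≥ 4. Thinness is used instead of a moment-based
   major/minor axis ratio deliberately: a capsule hugging a curved boundary is
   nearly circularly symmetric in moments (axis ratio ≈ 1) while `P²/(4πA)`
   grows with arc length over width.
2. **vessel wall** — the component encloses a lumen of ≥ `lumen_min_px` = 300.
3. **large tract** — component area ≥ `tract_min_px` = 20000.

`cpa_pct = 100 · area((collagen \ structural) ∩ tissue) / area(tissue)`;
growing the structural mask can only decrease it. The automatic exclusion can
be overridden by a user-supplied structural mask, preserving manual-override
semantics as an option rather than a requirement. Whether the tissue
denominator should exclude fat-vacuole area is genuinely open; vacuole holes
are included here (they are tissue in the H&E denominator, and consistency
between the two denominators matters more than either convention).

## Scoring

The combined NASH score is the published logistic combination
`0.058·fat% + 0.079·ballooning% + 0.485·inflammation% − 3.882`, called
positive at 0.31; CPA maps to `<F2 / F2 / F3 / F4` at 2.05 / 3.1 / 8.1%.
These are fixed published constants — the package does not re-derive them.
Boundary handling is not stated where the constants were published, so all
cutoffs here are inclusive (`score ≥ cutoff`, `CPA ≥ band cutoff`) and
documented as such. Quartiles in the per-grade summary tables use linear
interpolation between order statistics (R type 7), again a documented
convention rather than a published one.

## Validation statistics

* **ICC** is fixed to ICC(2,1) — two-way random effects, absolute agreement,
  single measure — because absolute agreement is the right question when an
  algorithm should reproduce an annotator's value, not merely correlate with
  it; the variant is recorded in every report. CIs use the standard F-bounds;
  when the residual mean square is zero the interval collapses onto the
  estimate.
* **Jonckheere–Terpstra**: the statistic is the sum of pairwise Mann–Whitney
  counts over ordered group pairs (ties count ½). For tie-free samples of
  n ≤ 20 the exact null is computed by convolving Mann–Whitney U
  distributions (the statistic decomposes into independent U's of each group
  against all earlier groups combined); otherwise a tie-corrected normal
  approximation with continuity correction is used. The `method` field
  records which. Constant data return z = 0, p = 1, flagged degenerate.
* **ROC**: AUROC by trapezoidal integration over all midpoint thresholds
  (identical to the Mann–Whitney identity, ties as half-counts, which the
  tests verify on every random input), DeLong 95% CI, and the Youden-optimal
  cutoff at the lowest midpoint maximizing J on ties.
* **Kappa** is quadratic-weighted for ordinal CRN scales (unweighted reported
  alongside); constant ratings are a degenerate-input error.
* **Paired deltas** use Wilcoxon signed-rank (exact for small tie-free
  samples, standard zero-discard rule; all-zero differences give p = 1 by
  convention). P-values are two-sided unless the one-sided ordered
  alternative is requested, and no multiple-testing correction is applied.

## The synthetic generator

The generator exists so that segmentation, training and statistics are
testable against exact ground truth. H&E images are built from the configured
stain vectors themselves — cytoplasm (H 0.10, E 0.60), inflammatory focus
plateau (0.80, 0.55) with dense nucleus dots, ballooned cells (0.08, 0.22)
with one retained nucleus, vacuoles near zero density, nuclei (1.20, 0.15) —
then converted to RGB and degraded with Gaussian noise (sd 4 on the 8-bit
scale). Sirius-red images use a yellow counterstain with red random-walk
septa, an optional capsule arc and vessel rings flagged structural in the
truth. Vacuoles and ballooned cells are placed on a jittered hexagonal grid
(pitch 28 px), which guarantees non-overlap while reaching the ~50% packing
that severe-disease targets require; objects are added until the running area
meets the target, so realized fractions land within a fraction of a percent
of the target, and the generator resamples (up to 50 deterministic re-seeds)
until every realized fraction is within 0.03 of its target.

Default study conditions mirror the published derivation-cohort medians:
per-grade fat 2.6 / 15.1 / 28.4%, inflammation 0.9 / 1.1 / 3.8%, ballooning
4.9 / 17.8 / 23%, CPA 1.3 / 2.4 / 13%. `generate_cohort()` draws per-case
targets lognormally (log-sd 0.2, a realistic within-grade spread) around the
stratum medians, capped so that combined lesion burden stays within the
generator's packing capacity, and assigns the pseudo-CRN score of the
generating stratum. Cohort-level checks run at 768² px, 30 cases; unit tests
use 256–512² images — sizes chosen as representative desk-scale
photomicrographs.

What the generator does **not** emulate matters for interpreting green tests:
lesions are near-circular with clean edges, stain colours match the
configured vectors exactly, there is no scanner variation, no out-of-focus
blur, no overlapping or partially confluent lesions, no micro/macrovesicular
distinction, and inflammation is a homogeneous plateau rather than a mixed
cell population. Passing the synthetic concordance checks therefore
demonstrates that the pipeline's logic is correct and self-consistent — that
it recovers known truth under its own stated appearance model — not that it
reaches any particular accuracy on clinical slides. The published
clinical-cohort agreement values cannot be reproduced here because the biopsy
images are not public; validating on real material requires annotated slides
and the `train`/`compare` path.

## Known limitations

* Whole-slide pyramidal formats, stain normalization across scanners and
  serial-section registration are out of scope; inputs are single 8-bit RGB
  fields.
* The rule-based ballooning fallback measures pale nucleated hepatocyte-scale
  area, which has a nonzero baseline in benign tissue; on clinical material
  the classifier path should be preferred once annotations exist.
* Fibrosis *pattern* (pericellular vs bridging) and architectural staging are
  not assessed — only the collagen proportionate area.
* The exact Jonckheere–Terpstra null requires tie-free data; heavily tied
  ordinal inputs fall back to the normal approximation.
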