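---
title: "Connectivity-based parcellation of the callosal midsagittal section: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation of the callosal midsagittal section: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callosum)
```

## The model

The corpus callosum (CC) crosses the interhemispheric plane as a compact
midsagittal structure whose cross-sectional area is the usual morphometric
proxy for the whole bundle. Because transcallosal fibers are largely
*hemispherotopic* — neighbouring fibers connect neighbouring homologous
cortical sites — a parcellation of the cortex can be carried onto the
section by the fibers themselves rather than by arbitrary geometric cuts.
`callosum` implements this projection for a fixed seven-parcel
anterior–posterior cortical scheme (frontopolar, anterior prefrontal,
posterior prefrontal, precentral, postcentral, parietal, occipital; label 1
is the most anterior and ties resolve toward lower labels).

The pipeline assumes: (i) a binary white-matter or CC mask and a
seven-label cortical parcellation are supplied (the sulcal modelling that
produces them is upstream and out of scope); (ii) the tractogram is in
world millimetres, optionally with SIFT2-style per-streamline weights that
make streamline count proportional to fiber density; (iii) the midsagittal
plane is axis-aligned with the voxel grid. The last assumption is a real
restriction: slab selection is computed from signed plane distances and
would work for oblique planes, but the in-plane 8-neighbourhood that the
vote and the connected-component logic need is only well defined on a voxel
axis, so oblique normals are rejected with an explicit error rather than
silently mis-gridded.

Given the section grid $V$ (in-plane voxels of area $a$) and the seven
homotopic sub-bundles, the per-bundle density is

$$d_l(v) = \sum_{\text{streamline } s \in l,\ v \in \text{cross}(s)} w_s,$$

where $\mathrm{cross}(s)$ is the *set* of section voxels whose in-plane
extent contains an interpolated plane-crossing point of $s$ — each
streamline contributes at most once per voxel, so loops do not
double-count, while a streamline genuinely crossing twice deposits density
at both sites. The label map is the regularized majority vote

$$\ell(v) = \arg\max_l \tfrac12 d_l(v) + \tfrac1{12}\sum_{n \in N_8(v) \cap V} d_l(n),$$

with the kernel left unnormalised (it sums to 7/6; the argmax is
scale-free, and the whole map is invariant to rescaling all weights by any
positive constant). Parcel areas are voxel counts times $a$, so the seven
callosal parcel surfaces (CcPS) sum to the total CC area exactly.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `oversample` | 2 | — | nearest-neighbour mask subdivision; 1 mm input → 0.5 mm section voxels, area 0.25 mm² |
| plane | `x = x0` | mm | midsagittal plane; left hemisphere is the negative signed side |
| `radius` | 3 | mm | endpoint-to-parcel search: tractography endpoints stop at the grey-matter interface, so an endpoint not inside a labelled voxel adopts the nearest labelled voxel centre (or mesh vertex) within this radius |
| `vote_config()` | 1/2, 1/12 | — | self and neighbour weights of the vote kernel, exactly as specified |
| `clean` | `TRUE` | — | keep the largest 8-connected section component (automated stand-in for manual mask checking) |
| `percentile` | 10 | % | normative flagging threshold on control residues |
| `qtype` | 7 | — | quantile convention: linear interpolation on order statistics, $q(p) = x_{(1+(n-1)p)}$ |
| QC band | 0.10–0.25 | — | per-parcel area fractions outside this band only *warn*; healthy parcellations sit inside it |

## Numerical conventions

Several choices are underdetermined by the method description; they are
fixed here once, deterministically:

* **"On the plane"** means signed distance in the half-open interval
  $[-h/2, h/2)$ of the oversampled voxel size $h$, so a plane lying exactly
  between two voxel layers still produces a one-voxel-thick slab.
* **Crossing points** lie exactly on the plane, i.e. on the slab boundary,
  so their membership is tested against the in-plane voxel extent only.
  A point exactly on the plane counts as a crossing by itself; an endpoint
  exactly on the plane has no hemisphere and discards its fiber (tallied in
  QC).
* **Vote ties** go to the label with the larger whole-section bundle mass,
  then the lower (more anterior) label index.
* **Zero-density voxels** are unassigned by the vote and filled afterwards:
  iterated modal label of assigned 8-neighbours (synchronous passes, ties
  to the lower label), then nearest assigned voxel by in-plane Euclidean
  distance for anything still open. Filled voxels carry a provenance flag
  and their fraction is reported in QC. With $k$ bundles deleted
  (agenesis), exactly the $7-k$ remaining labels appear — absent parcels
  report zero area rather than breaking the partition.
* **Component ties** in `clean_section` keep the component reaching
  furthest anterior, then the larger anterior–posterior extent.
* **Cortical areas** distribute each triangle's area in thirds to its
  vertex labels; unlabelled (label-0) area is excluded from both CxPS and
  TCxS by default so that the conservation $\sum_l \mathrm{CxPS}_l =
  \mathrm{TCxS}$ is exact.

## Statistical layer

Models 1–3 are ordinary least squares with DIAG (0 control / 1 affected),
SEX (0 female / 1 male), AGE (years) and TCxS (cm²) as covariates; model 2
uses the percent cortical share %CxPS as response and model 3 adds the
matching parcel's %CxPS as covariate. Conventions forced by the printed
worked examples the implementation is validated against:

* **DIAG is tested one-tailed (lower)** — the printed pairs
  $t(98) = -2.75 \to p = 0.004$ and $-1.72 \to 0.044$ match lower-tail, not
  two-tail, probabilities. All other coefficients are two-tailed.
* **η² is the single-df type-III sum of squares of DIAG over the total sum
  of squares**, computed as $t^2(1-R^2)/\mathrm{df}_{res}$. Printed effect
  sizes cannot fully disambiguate the η² variant; this is the nearest
  internally consistent convention and is documented rather than hidden.
* **Welch (unpooled) t-tests** for descriptive comparisons — the printed
  age comparison ($p = 0.098$) matches Welch, not the pooled test
  ($\approx 0.084$).
* **Yates continuity correction** for the 2×2 χ² — the printed sex
  comparison ($p = 0.813$) requires it (uncorrected ≈ 0.66).
* **Degrees of freedom are always those of the fitted subset.** Fitting an
  affected subgroup against controls reports the true residual df of that
  subset, even where a source table header suggests otherwise.
* **Benjamini–Hochberg** is the step-up rule
  $q_{(k)} = \min_{k' \ge k} p_{(k')} m / k'$, clamped at 1. Note that BH
  is *not* idempotent — $(0.01, 0.5) \to (0.02, 0.5) \to (0.04, 0.5)$ — so
  the package's property tests assert order preservation, $q \ge p$, and
  that reapplication never shrinks a q-value, not idempotence.

The normative layer (model 4) refits SEX + AGE + TCxS on controls only,
derives residues (observed − predicted) for everyone, and flags residues
*strictly below* the control 10th percentile ("below" read literally;
values equal to the threshold are not flagged). Controls are flagged from
their in-sample residues, matching how control distributions are plotted
alongside patients. A callosal area of zero (partial agenesis) simply
yields a large negative residue and is counted like any other flag. Excess
flags per patient group are tested with two-sided Fisher exact tests and
BH-adjusted across the eight surfaces within each group.

## The synthetic world

The generators are first-class, tested code; their defaults are the stated
world of the test-suite and are not tuned against test outcomes.

The **phantom** is a flat 70 × 10 mm callosal strip (700 mm², in the range
of real midsagittal CC areas) at 1 mm native resolution, crossed at
$x = 19.5$ mm by the midsagittal plane, with two labelled cortical ribbons
22 mm lateral on each side. Band fractions default to
(0.13, 0.17, 0.20, 0.12, 0.10, 0.13, 0.15) — seven one-piece bands between
10% and 20% of the section, the range reported for healthy parcellations.
Each homotopic bundle gets 1.2× its band's section voxel count in
streamlines, cycled so every voxel is crossed at least once; weights are
log-normal(0, 0.5) multipliers around 1 (SIFT2-like); 10% extra heterotopic
fibers and 5% stray midplane crossings below the CC are injected as
negative controls. A flat strip rather than an anatomical arch is
deliberate: areas, densities and votes are geometry-agnostic, and the strip
makes ground truth exact. What the phantom does *not* emulate: curved
geometry, partial-volume effects at the mask boundary, spatially varying
seeding density, and scanner noise — a green phantom test therefore
establishes the correctness of selection, labelling, voting and
book-keeping, not robustness to real segmentation error.

**Cohorts** follow the generating model
$\mathrm{CcPS}_l = b_{0,l} + b_{SEX,l}\,SEX + b_{AGE,l}\,AGE +
b_{TCxS,l}\,TCxS + \delta_l\,DIAG + \varepsilon_l$, truncated at zero, with
the total CC as the exact sum of the parcels. Group sizes (38 controls, 37
FAS, 28 NS-FASD) and the 6–25 year age range follow the study design this
package mirrors; everything else is an arbitrary but realistic default:
TCxS ~ N(1900, 150) cm² (a plausible two-hemisphere total cortical
surface), total-CC coefficients $b_0 = 250$ mm², $b_{SEX} = 20$ mm²,
$b_{AGE} = 6$ mm²/yr, $b_{TCxS} = 0.15$ mm²/cm² (mean total ≈ 610 mm² at
age 12), per-parcel residual SD 12 mm², cortical shares jittered 3% and
renormalised so they sum to TCxS exactly. The truncation at zero is
negligible at these defaults (means are 5+ SDs above zero), which matters
for the calibration tests: the one-tailed DIAG test's type-I error is
checked at 5% ± 1.5% over 2000 null cohorts, and coefficient recovery at
≤ 2 Monte-Carlo standard errors over 500 replicates.

## Known limitations

* Oblique midsagittal planes and curved midsagittal surfaces are not
  supported (explicit error), and the anterior–posterior axis is assumed to
  be the world +y (RAS) direction.
* The within-thickness (superior–inferior) structure of the CC is not
  subdivided; the section is treated as a 2D sheet.
* Endpoint-to-parcel mapping is nearest-labelled-site within a radius; no
  geodesic or surface-based projection is attempted.
* The normative thresholds are in-sample for controls (no leave-one-out),
  so control flag counts are slightly optimistic by construction.
* Streamline weights are consumed, never estimated; tractography and
  tissue segmentation are upstream concerns.
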