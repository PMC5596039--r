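---
title: "A contrast-weighted white matter damage metric: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A contrast-weighted white matter damage metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmdamage)
```

## The problem

White matter hyperintensities (WMH) — bright regions on T2-weighted and
FLAIR MRI, of presumed vascular origin — are usually quantified by their
segmented volume. Volume alone discards signal information twice over.
First, the same lesion volume can represent very different tissue states:
intense, established lesions versus subtle, barely-brighter-than-normal
change. Second, subtle WMH near the normal-appearing white matter (NAWM)
intensity sit on the wrong side of any segmentation threshold for one
observer and the right side for another, which makes volumes — and
especially longitudinal volume *changes* — sensitive to processing choices
that have nothing to do with the patient.

## The metric

Let $I$ denote the mean FLAIR (or T2W) intensity of a tissue class,
$I = \sum_{i=1}^{n} I_i / n$ over the $n$ voxels the class occupies, and
let $V$ denote class volume. The damage metric is

$$
\mathrm{WMdamage} \;=\;
\frac{I_{\mathrm{WMH}} - I_{\mathrm{NAWM}}}{I_{\mathrm{NAWM}}}
\;\times\;
\frac{V_{\mathrm{WMH}}}{V_{\mathrm{WMH}} + V_{\mathrm{NAWM}}},
$$

the proportion of WMH in the tissue where WMH can appear (brain tissue
excluding the cortex), weighted by the relative image contrast of WMH over
NAWM. It is defined as exactly $0$ when $V_{\mathrm{WMH}} = 0$.

Properties the implementation asserts as tests:

* **Bounds.** WMH on FLAIR are conventionally at least $3$ NAWM standard
  deviations above the NAWM mean
  ($I_{\mathrm{WMH}} \ge I_{\mathrm{NAWM}} + 3\,SD_{\mathrm{NAWM}}$ with
  $0 \le SD_{\mathrm{NAWM}} \le (I_{max}-I_{min})/2$), and NAWM intensity
  lies between $50\%$ and $2/3$ of the maximum intensity of a T2W-based
  sequence. Inside that region the contrast term lies in $[0, 1]$ and the
  proportion term in $(0, 1)$, so the metric lies in $[0, 1]$. The lower
  NAWM bound matters: without $I_{\mathrm{NAWM}} \ge I_{max}/2$ the
  contrast ratio is unbounded, so the package's validity-region sampler
  (`wm_damage_sweep()`) draws $I_{\mathrm{NAWM}}$ from
  $[\tfrac12, \tfrac23] \cdot I_{max}$, the stated NAWM intensity
  convention.
* **Scale invariance, shift sensitivity.** Multiplying all intensities by
  $c > 0$ leaves the metric unchanged (the ratio cancels scanner gain);
  adding a constant offset does not. The metric is therefore comparable
  across acquisitions only up to sequence type, which is also why the
  implementation records `sequence_used`.
* **Monotonicity.** Strictly increasing in $I_{\mathrm{WMH}}$ and in
  $V_{\mathrm{WMH}}$ with everything else fixed.
* **Negative contrast** ($I_{\mathrm{WMH}} < I_{\mathrm{NAWM}}$) can only
  arise from a wrong segmentation. The raw negative value is reported with
  `valid = FALSE` rather than clamped, so the failure stays visible.

When intense and less-intense WMH compartments both exist,
$I_{\mathrm{WMH}}$ is measured over their union — equivalently the
volume-weighted mean of the compartment intensities — which is what the
definition of $I$ over "the region occupied by WMH" implies.

## Inputs and their geometry

Scans are co-registered 3D volumes (FLAIR mandatory; T1W, T2W, T2*W
optional) sharing one grid; registration and bias-field correction are
upstream concerns, not reimplemented here. Masks are voxel-binary;
probabilistic maps are binarised at a configurable threshold, default
$0.5$, chosen as the natural posterior cut in the absence of a stated
convention. Mask validation enforces the anatomical partition (NAWM and
WMH disjoint and inside the ICV, subcompartments partitioning the total,
exclusion masks — e.g. stroke lesions — disjoint from both tissues).
Volumes in ml are voxel counts times the voxel volume from the FLAIR
header ($\mathrm{mm^3}/1000$); masks are never resampled.

Longitudinal change is computed both ways practitioners use: numerically
(follow-up volume minus baseline volume) and spatially (subtraction of
co-registered masks into *new* and *vanished* volumes). The net spatial
change equals the numeric change of the same masks; the decomposition
differs, and the spatial route is the more informative one when
co-registration is trustworthy.

## Segmentation routes

**Colour fusion with minimum-variance quantisation.** Two sequences are
min-max normalised within the brain mask and mapped to the red and green
channels (T2*W + FLAIR for WMH work; T1W + T2W for normal tissue). The
joint colour distribution is quantised into $k$ levels so as to minimise
the total within-level squared deviation. Implementation: greedy
variance-minimising cuts — repeatedly split the box with the largest
within-box sum of squares at the SSE-optimal threshold along the better of
the two axes (computed exactly by prefix sums over the distinct colours) —
followed by Lloyd refinement (`stats::kmeans`). A plain median cut was
rejected: with a dominant NAWM cluster the weighted median falls inside
NAWM, and Lloyd refinement then converges to a local optimum that splits
NAWM and merges the lesion compartments. The procedure is deterministic.

Level selection is operator-guided in the original workflow; here it is an
explicit, configurable rule: levels whose green (FLAIR-driven) centroid
exceeds the green centroid of the modal level by more than `margin`
(default $0.1$ in normalised units) are WMH; the highest of those is the
intense compartment; all non-WMH levels count as normal white matter,
since the input mask is already restricted to tissue in which WMH can
appear. This rule is a faithful encoding, not a claimed equivalent, of the
interactive step.

**Gaussian-mixture clustering.** Per-voxel feature vectors concatenate the
normalised channels; a $k$-component Gaussian mixture with diagonal
covariances is fitted by EM (default $k = 4$: CSF, cortex/grey matter,
NAWM, WMH, so the brain mask for this route should be the whole
brain-extracted region). Numerical choices: k-means initialisation with
ten random starts under a fixed seed, two independent EM starts keeping
the better likelihood, relative log-likelihood tolerance $10^{-6}$,
variance floor $10^{-8}$, up to ten restarts on component collapse. The
per-iteration log-likelihood trace is stored and tested to be
non-decreasing, and the fitted means are cross-checked against an
independent EM implementation (mclust) in the test suite. The NAWM class
is the one with the highest T1W mean (white matter is brightest on T1);
without T1W, the largest component, NAWM being modal in brain tissue. The
NAWM class then provides the reference statistics from which WMH are
thresholded on FLAIR.

**FLAIR histogram thresholding.** WMH are voxels at least
$k \cdot SD_{\mathrm{NAWM}}$ above the NAWM mean, default $k = 3$ per the
definitional convention, with a second threshold (default $K = 5$)
separating intense from less-intense WMH. The reference statistics can be
a measured NAWM region, nominal values, or a robust median/MAD estimate
over the brain mask (valid because NAWM is the modal tissue there). The
threshold uses $\ge$, so $k = 0$ degenerates to "everything at or above
the NAWM mean", a documented sensitivity boundary.

## The phantom

`generate_phantom()` builds the simplest geometry that supports "brain
tissue excluding the cortex": nested ellipsoids (ICV ⊃ cortical ribbon ⊃
white matter compartment ⊃ ventricular CSF) with ellipsoidal lesions
placed entirely inside the white matter compartment, odd-numbered lesions
intense, even-numbered less intense. FLAIR tissue means default to CSF 30,
cortex 70, NAWM 100 (nominal SD 10), lesions at the NAWM mean plus
$k \cdot SD$ ($k_{less} = 3.5$, $k_{intense} = 5$), ceiling 160 — NAWM at
$62.5\%$ of the ceiling, inside the $50$–$75\%$ convention. The T1W/T2W/
T2*W channels use per-tissue lookup tables that reproduce the qualitative
orderings of those sequences (bright NAWM on T1W, bright CSF on T2W);
they are configurable constants, documented, and not claimed
physiological. Noise is additive i.i.d. Gaussian (default SD 5, i.e.
SNR 20 relative to the NAWM mean) — adequate at the SNRs tested, though
real magnitude MRI noise is Rician and spatially correlated. No partial
volume, bias field or motion is modelled, so passing phantom tests
demonstrates correctness of the estimators and the pipeline plumbing, not
robustness to real-world artefacts.

Because the noiseless phantom paints exact tissue means, the metric
measured on the truth masks must equal the closed-form
$\mathrm{WMdamage}$ of the generating parameters to $10^{-12}$ — the
package's strongest end-to-end correctness check. With noise, the estimate
converges to the closed form as the lesion voxel count grows (checked at
three grid sizes with seed-averaged errors), and each of the three
segmentation routes recovers it within $15\%$ at SNR 20 with the weakest
($3\,SD$) lesion contrast.

## Rating scales

Total Fazekas is the sum of the periventricular and deep ratings (0–6);
total Prins change is the sum of $\pm1/0$ change ratings over 14 regions
(−14..14); the total SVD burden score sums four binary features (0–4),
with the WMH point awarded when periventricular Fazekas is 3 or deep
Fazekas is at least 2 — the standard rule, which the source scales cite
rather than restate, so it is exposed as an explicit function
(`svd_wmh_item()`).

## Evaluation statistics

The evaluation battery mirrors how such metrics are judged against visual
ratings: Spearman correlations with percentile-bootstrap confidence
intervals (2000 resamples by default; the replicate count and CI type are
package choices, as the toolboxes usually used do not state theirs),
Bland–Altman agreement with differences expressed as percentages of the
pair mean (so repeatability of measurements with different magnitudes
shares one ordinate; absolute mode available), paired t and signed-rank
tests (zero differences handled by the Pratt method — ranked with the
rest, contributing to neither sum — with tie-corrected normal
approximation), ANCOVA of the follow-up measurement on baseline plus a
change score (OLS, optional log outcome, listwise deletion reported,
near-collinearity warned via the design-matrix condition number), and
plain change scores. No multiple-testing correction is applied by default,
matching common practice for these descriptive batteries; Holm-adjusted
p-values can be computed by the caller from the tidy output.

## Problem sizes and determinism

Test and validation runs use 24³–64³ phantom grids (a 64³ default keeps a
full four-channel EM fit under a second), $10^4$ draws for the bounds
sweep, 100 random instances per oracle-equivalence check, and 100
replicates for ANCOVA interval coverage at $n = 400$. Every stochastic
component (phantom, bootstrap, EM initialisation, sweep) takes an explicit
seed and restores the caller's RNG state, so all results in this vignette
and the test suite are exactly reproducible.

## Known limitations

* The metric depends on sequence type and acquisition parameters (it uses
  intensity, not quantitative, images); values are comparable within a
  protocol, associations more widely.
* The colour-fusion level-selection rule replaces an interactive step; its
  intense/less-intense boundary degrades at low contrast-to-noise (the
  quantiser may legitimately prefer splitting NAWM before splitting the
  lesion compartments).
* The phantom's Gaussian noise and sharp tissue boundaries are idealised;
  partial-volume and bias-field robustness are untested here.
* Registration, brain extraction and cortex delineation are assumed done;
  on real data the user supplies the brain/tissue masks.
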