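---
title: "Texture quantification of pigmented-lesion ROIs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture quantification of pigmented-lesion ROIs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Benign nevi (BN), dysplastic nevi (DN) and melanomas (MM) can look alike in
a clinical examination while requiring very different management. Dermoscopy
photographs of such lesions carry quantifiable texture information: a
melanoma's expansion of pigmented cells blurs the fine, chaotic pattern of a
benign lesion and produces large uniformly dark areas. `lesiontex`
implements a small, fully specified pipeline that turns an 8-bit grayscale
region of interest (ROI) into five per-ROI statistics and compares them
across lesion groups:

* **Entropy** and **difference entropy (DifEntrp)** of the gray-level
  co-occurrence matrix — measures of pattern randomness;
* **long-run emphasis (LngREmph)** of the gray-level run-length matrix — a
  measure of extended uniform structure;
* the ratio indices **TI = Entropy / LngREmph** and
  **BI = DifEntrp / LngREmph** (texture and bone index), which contrast
  structural diversity against uniform longitudinal structure.

Polarized-light dermoscopy suppresses surface reflection and exposes
subsurface pigment structure; non-polarized light retains specular glare.
The pipeline treats lighting mode as a first-class grouping variable.

## Preprocessing: the μ ± 3σ window

Each ROI (450 × 450 px by convention) is windowed to
\[μ − 3σ, μ + 3σ\], where μ and σ are the mean and *population* standard
deviation of its own intensities, and mapped linearly onto `Ng` gray levels:

    level(v) = clamp(1 + floor((v − (μ − 3σ)) / (6σ) · Ng), 1, Ng)

Values outside the window clamp to levels 1 and `Ng`. Choices that the
equations themselves leave open, fixed here once:

* **`Ng` = 64** by default (configurable to any value ≥ 2). Reduced-level
  analysis is the convention of the texture-software family this analysis
  descends from, and it keeps co-occurrence matrices dense enough to
  estimate from one ROI.
* **Population (divide-by-N) σ.** The window is a whole-ROI density
  statistic, not a sample estimate; the choice changes the window and is
  therefore stated.
* **Floor-based binning**; a value exactly on a bin edge goes to the higher
  level. An explicit rule makes every downstream number reproducible.
* **σ = 0** (constant ROI) maps every pixel to the middle level
  `round((Ng+1)/2)`, so constant images stay constant and the closed-form
  feature values used in the tests hold.

Because the window is recomputed per ROI, the level image — and every
feature — is invariant under positive affine intensity changes
`a·v + b`, except for pixels landing exactly on a bin edge. This is the
property that makes features comparable across exposure changes, and it is
tested directly.

## Texture statistics

The co-occurrence matrix at displacement `(dr, dc)` counts all in-bounds
ordered pixel pairs in both orders (symmetric accumulation, so
`p(i,j) = p(j,i)` and the offset sign is irrelevant) and normalizes to
`sum(p) = 1`. The working displacement is **distance 5**, evaluated at the
four canonical offsets `(5,0), (0,5), (5,5), (5,−5)` (Chebyshev distance 5
on the diagonals). Entropy is `−Σ p log p` and difference entropy is the
entropy of the marginal of `|i−j|`; terms with `p = 0` contribute 0.

The run-length matrix decomposes each scan line (horizontal, vertical and
the two diagonal directions) into maximal runs of equal level;
`LngREmph = Σ k² r(i,k) / Σ r(i,k)` with **no run-length cap** — capping
would silently truncate the long uniform runs of dark lesion areas, the key
melanoma signal.

Per-ROI features aggregate the four directional values by their arithmetic
mean (configurable), and TI/BI are computed from the aggregated values *per
ROI* — never as ratios of group means. Open choices, fixed here:

* **Natural logarithm** by default (`log_base = 10` available). The base is
  a global scale factor on Entropy, DifEntrp, TI and BI; group orderings are
  invariant, which is why the directional conclusions do not depend on it.
* The direction reducer is configurable because single-direction variants of
  these statistics exist in the field; the mean is the default since no
  direction is privileged on skin.

A caveat worth stating precisely: on an n × n constant image the
*horizontal/vertical* long-run emphasis is n², but a diagonal scan sees
lines of lengths 1, 2, …, n, …, 2, 1, so its long-run emphasis is
`(2·Σ_{k<n} k² + n²)/(2n − 1)`. The aggregated value for a constant ROI is
therefore the mean of the four closed forms, not n²; the tests assert
exactly that.

## Statistical stage

For each feature and lighting mode, per-group normality is checked with
Shapiro–Wilk. If **all** groups pass at α (the conservative reading of
"depending on the normality of distribution"), the omnibus test is classic
one-way ANOVA (no Welch correction; two groups degenerate to the pooled t
test); otherwise Kruskal–Wallis (two groups: Mann–Whitney). When the
omnibus p-value is below α = 0.05, a post-hoc runs: **Tukey HSD** after
ANOVA, **Dunn's test with Bonferroni correction** after Kruskal–Wallis —
the standard companions of each omnibus test; no post-hoc is named in the
tradition this follows, so the one used is recorded in the report. An
ordering string such as `MM > DN > BN` is emitted only when every pairwise
comparison is significant with consistent directions; otherwise the
significant pairs are listed, or `n.s.`.

Dunn's test is implemented in the package (no installed package provides
it), with the tie-corrected variance
`(N(N+1)/12 − Σ(t³−t)/(12(N−1)))(1/n_a + 1/n_b)`; it is verified against a
hand-derived tied-free case and a null-calibration simulation. No
multiple-testing correction spans the five features: each feature is
reported marginally, as in the tradition this mirrors.

## The synthetic cohort: what it emulates, and what it does not

The source images of the motivating study are available only on request, so
the package ships a generator whose presets are **calibration artifacts**:
they are frozen so that a cohort of 166 ROIs per class per lighting mode,
pushed through the real pipeline, reproduces the published *ordering and
significance patterns* — not the absolute feature magnitudes, which depend
on unstated binning details of the original software and are treated as
directional evidence only.

Each ROI is built as: (1) white Gaussian noise smoothed at a class-specific
correlation length (periodic FFT convolution), standardized and placed in a
mid-gray band (mean 150, sd 25); (2) a number of uniformly dark ellipses;
(3) in non-polarized mode, saturated glare blobs plus global contrast
compression toward mid-gray; (4) i.i.d. Gaussian pixel noise, clamping,
rounding. Determinism is strict: each image's seed is derived
hierarchically from the master seed, class, lighting and index, so any
single image can be regenerated alone.

The polarized presets encode the biological story directly: correlation
length (1.5 / 3 / 5 px for BN / DN / MM) models the coarsening of pigment
structure, and dark-patch area grows with malignancy. All five features
then separate the three groups with the full ordering — LngREmph increasing
and Entropy, DifEntrp, TI, BI decreasing from BN to MM.

The non-polarized presets encode the opposite observation: surface
reflection hides the subsurface differences. All classes share one surface
correlation length (2.0 px; melanoma 1.84 px, see below), one expected
dark-patch *area*, and the same glare model; what differs is patch
**granularity** — nevi carry many small dark dots (13 ellipses, semi-axes
5–12 px), melanoma few large black blotches (2 ellipses, 12–30 px). Equal
dark area keeps the gray-level distribution, and hence both entropies,
statistically indistinguishable between groups, while the k²-weighting of
long-run emphasis responds to blotch size, separating melanoma from both
nevus groups. The residual difference-entropy imbalance of the granularity
contrast is nulled by the small melanoma correlation-length offset
(2.0 → 1.84 px) — a pure calibration step, recorded here because it is not
a biological claim. The DN preset differs from BN only cosmetically
(patch semi-axis upper bound 12.1 vs 12 px), emulating the finding that
nothing distinguishes the two nevus groups under non-polarized light.

What a green test on this cohort establishes: the pipeline's statistics
respond to spatial correlation, uniform dark area and glare the way the
published pattern requires, end to end, including the normality routing and
post-hocs. What it does not establish: anything about real dermoscopy
images — the generator has no pigment network, globules, streaks, hair,
vignetting, or camera noise model, and its absolute feature values are not
comparable to published means.

## Numerical choices and degenerate inputs

* Zero-probability cells contribute 0 to both entropies (limit convention).
* An offset leaving no valid pixel pair, an empty ROI, or a run-length
  matrix with no runs raise contract errors rather than returning NaN.
* A co-occurrence matrix is checked for normalization (tolerance 1e-8)
  before any entropy is computed.
* Grayscale conversion of RGB input uses ITU-R BT.709 luminance weights
  with round-half-up (BT.601 available). The original study converted
  images in an external editor without stating the formula, so bit-exact
  agreement with its bitmaps is not claimable and not attempted.
* JPEG input is accepted with a warning — lossy artifacts perturb texture
  features. TIFF is not supported in this build (no reader in the
  dependency set); uncompressed BMP is read and written by a minimal codec
  in the package, as no installed package provides one.
* Configs are JSON rather than YAML for the same dependency reason.

## Known limitations

* Feature magnitudes depend on `Ng`, the displacement and the logarithm
  base; only orderings are stable across those choices. Cross-study
  comparisons of absolute values are not meaningful.
* The μ ± 3σ window assumes a roughly unimodal intensity distribution;
  an ROI dominated by one huge black area shifts its own window, which is
  faithful to the method but means "level 1" is not an absolute darkness.
  A consequence worth knowing: long-run emphasis grows with total dark-patch
  area only while that area is small relative to the ROI — once dark pixels
  inflate σ enough that μ − 3σ falls below their value, they stop clipping
  to a constant level, pixel noise breaks their runs, and LngREmph drops
  again. The class presets sit well inside the clipping regime.
* Shapiro–Wilk is defined here for 3 ≤ n ≤ 5000; larger cohorts would need
  a different normality gate.
* The two-group route (in-situ vs invasive comparisons) uses pooled t /
  Mann–Whitney; no effect-size or power machinery is included, because the
  effect size behind the original power statement is not recoverable.
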