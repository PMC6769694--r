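---
title: "Quantifying histochemical mucin staining: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histochemical mucin staining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucinquant)
```

## The measurement problem

PAS and alcian blue histochemistry color mucin polysaccharides (magenta and
blue respectively) against a counterstained tissue background (hematoxylin
blue-violet for PAS, safranin red for AB) and bright glass. The quantity of
interest is the stain **area fraction A%** — what share of the tissue shows
the reaction. Two independent pixel-level definitions are implemented:

* **Threshold backend**: `A% = reaction / tissue × 100`, where the reaction
  mask is an HSV box threshold and tissue is everything that is not glass.
* **Classification backend**: `A% = n1 / (n1 + n2) × 100` over a
  three-class label mask (1 reaction, 2 non-reacting tissue,
  3 background).

Both treat a field as an unordered bag of pixels: no morphology, no
neighborhoods, no texture. That is deliberate — the published methods are
pure color operations, and keeping them so makes the two backends genuinely
independent routes to the same statistic.

## HSV thresholding

Hue is handled in degrees in [0, 360) with *closed, possibly wrapping*
intervals: `[330, 30]` crosses the red seam. Achromatic pixels (S = 0) are
assigned hue 0 by convention and can only be captured via saturation and
value bounds — a deterministic rule that keeps gray pixels out of any
narrow hue interval.

Tunable parameters of `filter_hsv_config()`:

| parameter | default | meaning |
|---|---|---|
| PAS hue range | [280, 345]° | magenta reaction product |
| AB hue range | [180, 260]° | blue reaction product |
| saturation range | [0.15, 1] | excludes near-gray pixels |
| value range | [0.15, 0.95] | excludes glare and near-black debris |
| `background_sat_max` | 0.10 | glass is unsaturated |
| `background_val_min` | 0.85 | glass is bright |

These are calibration choices for typical 8-bit brightfield material, not
published constants (the original program's thresholds were never printed);
every bound is overridable per batch and the resolved values are logged
with each run.

The denominator counts **all non-background pixels, reaction included**.
The alternative (tissue = non-reaction, non-background) was rejected
because strongly reacting control mucosa reaches A% around 60%, which is
only meaningful when reaction pixels sit in the denominator.

## Seeded three-class classification

The interactive color-picking step of commercial tools is replaced by
explicit per-class seed pixels. Each class is a Gaussian in color space
(mean + full 3×3 covariance); classification is quadratic discriminant
analysis with equal priors. Numerical choices:

* **Ridge `epsilon = 1.0`** (0–255 scale) added to every covariance
  diagonal: a class seeded with a single color stays invertible, and on the
  8-bit scale one gray level of slack is below perceptual relevance.
* **Ties go to the lowest class index** (reaction < tissue < background).
  Exact ties occur with identical class models; the rule makes results
  reproducible bit-for-bit.
* **Feature space**: RGB by default (seeds are RGB pixels). An
  `hsv-cartesian` alternative maps pixels to
  `255·(S cos H, S sin H, V)`, removing the hue seam for classes of reds
  straddling 0°; it is a modeling option, not a different contract.
* Equal priors, not empirical class frequencies: the class balance of seed
  sets is an artifact of how seeds were picked, not of the image.

Per-pixel color is the entire feature set. A texture- or
neighborhood-aware classifier might beat it on real slides, but would no
longer be comparable to the published three-class color contract.

## IRS scoring

`IRS = PP × SI` with PP ∈ {0..4}, SI ∈ {0..3}. The PP bins follow the
classical convention, made half-open for determinism:
`0 | (0, 0.10) | [0.10, 0.50] | (0.50, 0.80] | (0.80, 1]`, so a fraction of
exactly 0.10 is category 2. Bands: 0 negative, 1–2 low, 3–4 moderate, 6–12
strong; the products 5, 7, 10, 11 are unreachable and asserted so in the
tests. SI is an operator judgment and is never inferred from pixels. Both a
per-field and a global PP input path are acceptable; the package scores
whatever fraction it is given, so callers may average fields before or
after binning as their protocol dictates.

## Statistics harness

All tests are two-sided at α = 0.05, with no multiple-testing correction
(matching the analysis plan this package supports; add your own if you run
many contrasts).

* **Cronbach's alpha**: `k/(k−1)·(1 − Σ item variances / var(row sums))`,
  sample variances. Zero total variance is an error, not NaN.
* **Spearman**: midranks for ties; exact two-sided p by enumerating all
  `n!` permutations for n ≤ 8, else the t approximation on n − 2 df.
* **Wilcoxon signed-rank**: zeros dropped, midranks on |differences|;
  exact p for ≤ 15 non-zero pairs by convolution over all `2^n` sign
  assignments (valid under ties); otherwise normal approximation with
  tie-corrected variance `Σr²/4` and continuity correction.
* **Mann–Whitney**: midranks; exact p by enumerating all group assignments
  when the pooled n ≤ 12, else normal approximation with tie correction
  and continuity correction.
* **Mean split**: values equal to the mean go to the *low* group; an
  all-equal input leaves the high group empty with a warning.
* **Kaplan–Meier / log-rank**: product-limit per group honoring right
  censoring; two-group log-rank with the hypergeometric variance on
  pooled risk sets, 1 df.

The exact/approximate switchover sizes were chosen for determinism at test
scale and standard behavior at cohort scale (n = 33 uses the
approximations); both branches are exposed and both are tested against
brute-force enumeration oracles.

One stated invariant had to be narrowed: *"alpha never decreases when a
duplicated column is added"* is *not* a theorem for arbitrary matrices —
counterexamples exist even with all-non-negative inter-item covariances.
It does hold for exchangeable items (equal variances, equal non-negative
covariances), which is the parallel-methods regime alpha is used for here,
and the property test constructs exactly compound-symmetric data to assert
it there.

## What the synthetic generator does and does not emulate

`generate_field()` builds: one large elliptical tissue region on
near-white glass (with small punched-out lumina), reaction blobs as unions
of random ellipses placed inside tissue, hue-preserving luminance texture
on tissue (SD 10 gray levels), a multiplicative illumination ramp
(default 8% corner-to-corner), and independent per-channel Gaussian camera
noise (default SD 8 on the 0–255 scale — ordinary 8-bit camera noise).
The last reaction ellipse is trimmed pixel-by-pixel so the truth mask hits
the target count exactly; the emitted true A% *is* the class-count formula
applied to the truth mask. All randomness flows from one explicit seed via
`withr::with_seed`; global RNG state is never touched.

Default colors (hues chosen so each stain's reaction is well inside its
preset hue range and each counterstain is well outside it): PAS reaction
(190, 30, 130), hematoxylin (110, 95, 170); AB reaction (40, 90, 170),
safranin (205, 85, 90); glass (250, 248, 251).

What it deliberately does **not** model: chromatic illumination casts,
stain co-localization and partial-volume mixing at reaction borders, JPEG
artifacts, out-of-focus blur, folds and debris, and the full morphological
vocabulary of real crypts. A green recovery test therefore establishes
that the pipelines are *correct on their stated world* — color-separable
stains under achromatic nuisance — not that the default thresholds are
clinically calibrated for any particular scanner.

`generate_cohort()` draws latent per-patient slide A% values
(tumor ≈ 18/10%, control ≈ 62/56% for PAS/AB — magnitudes anchored to
published colorectal cohorts), adds independent per-backend measurement
error (SD 2 pp, which reproduces backend-agreement alphas in the high
0.9s), builds in a mucinous AB elevation (+7 pp), a flat-tumor PAS
elevation (+9 pp), control-tissue PAS–AB, AB–hemoglobin and PAS–glucose
correlations (0.55 / 0.45 / 0.40) via a latent-normal construction, and an
exponential survival model (0.005 events/month, uniform 30–60 month
administrative censoring, ≈ 20% observed deaths) with an optional hazard
ratio on above-mean expression (default 1: no survival effect). Setting
the shifts and correlations to 0, the tumor means equal to the control
means and the hazard ratio to 1 yields the null cohorts used for type-I
calibration.

## Degenerate inputs

Empty fields (no tissue pixels; no class-1-or-2 pixels) raise errors
naming the offending image — A% is never NaN. Single-field slides report
SD 0 with a warning; mixed backends or stains within one slide are a
consistency error. Cohort report tables degrade individually: a missing
covariate or a one-patient cohort skips the affected tables with warnings
and produces the rest. Corrupt rasters in a batch are logged per file and
surface as a nonzero exit status while remaining fields are processed.

## Infrastructure substitutions

The offline environment provides no PNG/TIFF/JPEG codec for R, so raster
I/O uses the portable anymap family (PPM/PGM, binary and ASCII) — a
lossless, self-describing container any imaging tool can write.
Structured configs are JSON rather than YAML for the same reason (no YAML
parser available offline). Both are serialization choices; the interfaces
and schemas are unchanged.

## Known limitations

* Per-pixel color classification cannot separate stains that overlap in
  color space; neither backend attempts stain unmixing (color
  deconvolution is explicitly out of scope).
* Threshold defaults are calibration choices; on real material they must
  be tuned once per staining protocol and camera, then frozen and logged.
* The log-rank test with very few events (small cohorts, heavy censoring)
  relies on a 1-df chi-square approximation; its calibration is verified
  by simulation at the default cohort size, not guaranteed universally.
* IRS saturates at 12 in strongly reacting tissue; the package reproduces
  this (control IRS is pinned at the ceiling in the cohort generator)
  rather than repairing it — that saturation is precisely why A% exists.
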