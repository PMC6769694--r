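# mucinquant

Quantitative evaluation of histochemical mucin staining in brightfield
microscopy of colorectal tissue.

Pathologists stain neutral mucins with the periodic acid–Schiff reaction
(PAS, magenta product) and acidic mucins with alcian blue at pH 2.5 (AB,
blue product), then ask how much of the tissue reacts. Semi-quantitative
eyeball scores saturate — in normal colonic mucosa nearly every crypt cell
produces mucus — so the readout of interest is the **stain area fraction**

```
A% = reaction area (pixels) / tissue area (pixels) × 100
```

computed per microscope field and averaged over ~10 fields per slide.
`mucinquant` implements two independent segmentation backends for A%, the
classical semi-quantitative score for comparison, the statistical toolkit
used to relate A% to clinicopathological data, and a synthetic
stained-tissue generator with exact ground truth so every stage is testable
without patient material.

## The two backends

**HSV threshold filter** (`field_area_fraction_hsv`). Pixels are converted
to HSV (hue in degrees, wraparound-aware hue intervals); a pixel is
*reaction* when H, S and V all fall inside a stain-specific acceptance
range, *background* when it is bright and unsaturated glass
(S < 0.10, V > 0.85), and *tissue* otherwise. A% divides reaction pixels by
all non-background pixels. Preset ranges: PAS H ∈ [280, 345]°,
AB H ∈ [180, 260]°, both with S ∈ [0.15, 1], V ∈ [0.15, 0.95] — calibration
defaults, fully overridable.

**Seeded three-class pixel classification** (`field_area_fraction_smart`).
An open reimplementation of commercial "smart segmentation": three color
classes — 1 reaction, 2 tissue without reaction, 3 background — are fitted
as full-covariance Gaussians from user-supplied seed pixels
(`fit_color_classes`), every pixel gets the maximum-log-density class
(quadratic discriminant, equal priors, ties to the lowest index), and

```
A% = n(class 1) / (n(class 1) + n(class 2)) × 100
```

so background never touches the statistic.

**Third method**: the immunoreactive score `IRS = PP × SI ∈ {0..12}`
(`pp_category`, `irs_score`), the product of the percentage-of-positive-cells
category (0–4) and staining intensity (0–3), banded negative / low (1–2) /
moderate (3–4) / strong (6–12).

The statistics harness (`cronbach_alpha`, `spearman_rho`,
`wilcoxon_paired`, `mann_whitney`, `split_by_mean`, `km_logrank`,
`cohort_report`) provides inter-method agreement, paired and unpaired
nonparametric tests with exact small-sample branches (full enumeration for
n ≤ 8 Spearman, ≤ 15 signed-rank pairs, pooled n ≤ 12 Mann–Whitney),
below/above-mean expression grouping and Kaplan–Meier/log-rank survival.

## Worked example

```r
library(mucinquant)

# a synthetic 512x512 PAS field with a known 20% reaction fraction
f <- generate_field(field_spec(512, 512, target_fraction = 0.20,
                               stain = "pas", seed = 42))
f$true_fraction_percent
#> [1] 20

field_area_fraction_hsv(f$image, filter_hsv_config("pas"))
#> <field_result [filter_hsv/pas] A% = 19.88 (reaction 45207 / tissue 227368, background 34776)>

model <- fit_color_classes(sample_seeds_from_labels(f$image, f$truth, 200, seed = 43))
field_area_fraction_smart(f$image, model)
#> <field_result [smart_seg/pas] A% = 20.00 (reaction 45133 / tissue 225666, background 36478)>
```

Both backends land within 0.2 pp of the known truth. On a full synthetic
cohort the whole statistical plan runs in one call:

```r
co  <- generate_cohort(cohort_spec(seed = 7))   # 33 paired tumor/control patients
rep <- cohort_report(co)
rep$tables$expression[, c("stain", "backend", "tumor_mean", "control_mean", "p_value")]
#>   stain backend tumor_mean control_mean  p_value
#> 1   pas     hsv      22.11         66.6 5.64e-07
#> 2    ab     hsv       9.38         59.6 5.64e-07
#> 3   pas   smart      22.85         67.2 5.64e-07
#> 4    ab   smart       9.17         59.6 5.64e-07

rep$tables$agreement
#>   stain   group alpha_backends alpha_three_methods
#> 1   pas   tumor          0.986               0.969
#> 2   pas control          0.992               0.744
#> 3    ab   tumor          0.975               0.931
#> 4    ab control          0.990               0.742
```

The built-in tumor-vs-control shift is detected (paired Wilcoxon), and the
two digital backends agree at Cronbach's α ≈ 0.98–0.99, while agreement of
all three methods drops in control tissue where the 12-point IRS scale
saturates — exactly the failure mode that motivates computing A%.

```r
irs_score(irs_inputs(pp_category(0.85), si = 3))
#> $score [1] 12   $band "strong"
```

## Command line

```sh
Rscript exec/mucinquant simulate field --out f.ppm --truth f.pgm --target 0.2 --seed 3
Rscript exec/mucinquant segment --backend filter-hsv --stain pas --out results.csv f.ppm
Rscript exec/mucinquant simulate cohort --out cohort.csv --seed 4
Rscript exec/mucinquant stats --cohort cohort.csv --out report/
Rscript exec/mucinquant agree --matrix ratings.csv
```

`segment` writes per-field CSV rows (counts + A%); batch runs via
`run_batch()` also emit per-slide summaries, the fully resolved config and
a run log with version, config hash and seed.

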