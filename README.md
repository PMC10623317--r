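# quindorm

Seed dormancy phenotyping for quinoa (*Chenopodium quinoa*) variety
panels: rule-based classification of primary dormancy strength from
hormone germination assays, and the downstream analyses that relate
dormancy to seed morphology.

Breeders screening for preharvest-sprouting tolerance need to grade
dormancy across hundreds of varieties. Dormant seeds stay sensitive to
abscisic acid (ABA) and insensitive to gibberellin (GA); non-dormant
seeds are the opposite. quindorm turns that physiology into an explicit
classifier over day-7 germination fractions:

* **SD** (strong dormancy): < 25% germination with or without ABA, and
  < 30% with GA;
* **MD** (moderate): ≥ 50% on GA but < 50% without hormone, still
  ABA-responsive;
* **WD** (weak): > 50% without hormone or with GA, still
  ABA-responsive;
* **ND** (none): > 75% regardless of ABA concentration.

"ABA-responsive" is itself operational: the 10 µM ABA mean lies below
the no-treatment mean with a pooled-variance t test on
arcsin √p-transformed replicate fractions rejecting at α = 0.05 (or a
≥ 20-point drop when replicates carry no variance). Varieties that stay
dormant then pass through an after-ripening / scarification /
long-after-ripening decision tree that separates embryo-imposed from
seed-coat-imposed dormancy and flags viability concerns.

Around the classifier, the package implements the rest of the
phenotyping pipeline:

* germination statistics: arcsine transform, one-way ANOVA with Tukey
  all-pairwise comparisons and compact letter display;
* seed morphometrics from 1200-dpi flatbed scans: watershed
  segmentation, per-seed area, Crofton perimeter, moment-ellipse axes,
  eccentricity √(1 − (b/a)²), convex-hull solidity, in mm units;
* NIR spectral QC (141 wavelengths, 950–1650 nm): calibration-range
  filter, Mahalanobis-distance filter against the χ²(141) quantile at
  α = 0.001, dry-matter adjustment;
* FAMD (factorial analysis of mixed data) from the weighted encoding
  up, with the ≥ 50% cumulative-inertia support rule;
* proportional-odds ordinal regression
  logit P(Y ≤ j) = θⱼ − x′β fit by Newton–Raphson maximum likelihood,
  reported in the standard Estimate / SE / t / p layout;
* a seeded synthetic-panel generator with known ground truth (dormancy
  classes, dose-response parameters, class-conditional traits, low-rank
  NIR spectra, rendered seed scans) so every stage is testable without
  lab data.

## Worked example

```r
library(quindorm)

res <- run_pipeline(run_config())  # default 189-variety synthetic panel

res$report$category_counts
#>  ND  WD  MD  SD
#> 141  27   9  12

# classifier recovery against the generator's ground truth
mean(as.character(res$calls$category) ==
     as.character(res$panel$truth$true_class))
#> [1] 1

res$report$famd_summary
#>     analysis n_rows n_dims dim1_pct dim2_pct cumulative_pct supported
#> 1 all_traits    189      2 22.03075 10.24262       32.27338     FALSE
#> 2       coat    189      2 16.60697 13.34039       29.94736     FALSE
#> 3      shape    189      2 43.74834 14.69158       58.43992      TRUE
#> 4    quality    189      2 30.02613 21.64602       51.67215      TRUE

head(res$report$olr_tables$coat, 3)
#>         Variables    Estimate Standard Error   t value      p value
#> 1       thickness 138.2973217     20.8890045 6.6205813 3.577890e-11
#> 2 coat_colorblack   1.6193140      0.5950654 2.7212372 6.503808e-03
#> 3 coat_colorbrown  -0.3634995      0.6459156 -0.5627662 5.735941e-01
```

The default run reproduces the panel composition exactly (141 ND, 27
WD, 9 MD, 12 SD of 189), recovers every true class at this seed, and —
by construction of the class-conditional trait distributions — shows a
strongly positive seed-coat-thickness slope in the ordinal model, a
shape-trait FAMD clearing the 50% support rule, and an all-traits FAMD
that does not.

Single stages work standalone:

```r
classify_refined(c(NT = 0.35, ABA10 = 0.05, GA10 = 0.8),
                 responsive = TRUE)$category
#> [1] MD

shape <- analyze_seed_image("scan.png", dpi = 1200,
                            overlay_path = "mask.png")
```

A thin CLI wraps the same functions
(`system.file("scripts/quindorm.R", package = "quindorm")`) with
subcommands `simulate`, `classify`, `morph` and `run`.

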