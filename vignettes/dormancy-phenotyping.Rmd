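---
title: "Seed dormancy phenotyping: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed dormancy phenotyping: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quindorm)
```

## The screening problem

Quinoa varieties differ widely in primary (physiological) seed dormancy:
some germinate on the panicle after rain (preharvest sprouting), others
stay dormant for months. Dormancy strength at physiological maturity can
be graded by hormone germination assays, because dormant seeds remain
sensitive to abscisic acid (ABA, a germination inhibitor) and
insensitive to gibberellin (GA, a promoter), while non-dormant seeds are
the reverse. quindorm packages that grading as an explicit, testable
rule set, together with the downstream association analyses (seed
morphometrics, NIR quality control, FAMD ordination, proportional-odds
regression) that relate dormancy strength to seed morphology.

## Dormancy classification rules

Germination is scored at day 7 as a fraction of sown seeds, averaged
over replicates. Two staged rule sets assign the ordered categories
ND < WD < MD < SD (none, weak, moderate, strong dormancy); we use "MD"
throughout for the middle dormant class that screening protocols also
call simply "D".

**Initial stage** (ABA dose-response at 0, 0.1, 1, 10 µM), rules in
order:

1. **SD** — all four means below 0.25;
2. **ND** — all four means above 0.75 and not operationally
   ABA-responsive (a stricter variant, `nd_rule = "strict"`, instead
   requires > 0.95 without hormone and > 0.75 at 10 µM ABA);
3. **MD** — no-treatment mean below 0.50 and means non-increasing in
   ABA concentration with a total drop of at least 5 percentage points
   (the tolerance absorbs binomial noise in "decreasing" sequences);
4. **WD** — no-treatment mean above 0.50 and ABA-responsive.

**Refined stage** (no hormone, 10 µM ABA, 10 µM GA; only for varieties
not initially ND): SD if NT and ABA means are below 0.25 and GA below
0.30; MD if GA reaches at least 0.50 while NT stays below 0.50 with
ABA-responsiveness; WD if NT **or** GA exceeds 0.50 with
ABA-responsiveness. We read the WD condition disjunctively — a variety
germinating well on GA but moderately without hormone is still only
weakly dormant provided ABA suppresses it — and this is safe because the
MD rule is evaluated first. Inequalities are deliberately literal:
"0–24%" is strict `< 0.25`, "50% or greater" is `>= 0.50`, "above 50%"
is strict `> 0.50`.

Inputs satisfying no rule are assigned the **nearest** rule's category
with an `ambiguous` flag rather than silently forced into a category.
Nearness is the summed threshold violation in percentage points; a
mismatched responsiveness requirement contributes `20 - drop` points
when responsiveness is required but absent (20 points being the
operational zero-variance responsiveness drop) and the observed drop
itself when it must be absent. Ties resolve in rule order (SD, ND, MD,
WD), i.e. toward the more restrictive rule that was missed most
narrowly.

**Responsiveness** is never a raw threshold: a variety is operationally
ABA-responsive when the 10 µM ABA mean lies below the no-treatment mean
and a pooled-variance t test on arcsine-transformed replicate fractions
rejects at α = 0.05 (with two groups this is exactly Tukey's HSD).
When replicates carry no variance at all — common with 10-seed
technical replicates at the extremes — the test degenerates, and a
fallback fires instead: a raw drop of at least 20 percentage points.

**Viability and mechanism.** Refined SD/MD varieties enter a decision
tree over one-month after-ripening (AR), scarification (SCR) and
three-month after-ripening (LAR) screens, in fixed order: (1) AR
germination ≥ 0.75 without hormone or with GA means dormancy was
released by dry storage — embryo-imposed, viable; (2) a significant AR
increase that stays below 0.50 marks a slow after-ripener — also
embryo-imposed, since a response to dry after-ripening is evidence of
physiological rather than coat-imposed dormancy; (3) scarified
germination ≥ 0.50 and significantly above the refined baseline marks
seed-coat-imposed dormancy; (4–5) the same two contrasts after three
months; (6) otherwise the variety is flagged as a viability concern.
"Failed to germinate", the trigger for scarification in the wet-lab
protocol, is operationalized as max(NT, GA) < 0.50 after AR; rescue
requires both the 0.50 level and statistical significance.

## The synthetic panel generator

The generator is the package's study-condition definition, not a test
fixture. Its defaults reproduce the screened panel structure: 189
varieties split 141/27/9/12 into ND/WD/MD/SD (largest-remainder
rounding keeps counts exact for any panel size), 10 seeds per technical
replicate, 3 technical replicates in the initial round and 3 biological
× 3 technical replicates afterwards.

Each variety carries a closed-form dose-response truth: baseline
germinability g0, a two-parameter Hill inhibition by ABA
(`g / (1 + (c/ic50)^h)`), a multiplicative GA boost on the
non-germinating fraction, a per-month after-ripening release fraction
(compounded over months) and a scarification release fraction. This is
the simplest parameterization that reproduces the qualitative assay
patterns — SD varieties flat and low under everything, MD rescued by
GA, WD high but ABA-suppressible, ND flat and high. Class-conditional
parameter ranges are chosen so that expected germination respects the
class definitions with margin (e.g. SD stays below 0.25 in expectation
under every in-assay treatment), while binomial replicate noise still
produces occasional boundary cases; within-variety variance is purely
binomial because replicate-level overdispersion is not identifiable
from published error bars, and it remains configurable through the
replicate structure. Of the SD varieties, one sixth are
seed-coat-imposed (scarification releases, after-ripening does not) and
the rest embryo-imposed, split 70/30 into fast and slow after-ripeners.

Traits are drawn from class-conditional truncated normals that encode
the known morphology–dormancy associations — strongly dormant varieties
get thicker seed coats and a narrow, low eccentricity range — with
internal consistency enforced (minor axis derived from major axis and
eccentricity; area and perimeter near-elliptical). Coat colors are
multinomial with class-specific weights dominated by beige. What the
generator does **not** emulate: genetic structure among varieties,
secondary dormancy induction, environmental (sowing-date, weather)
effects, and trait–trait residual correlations beyond the shape
identities. Passing recovery tests therefore demonstrate that the
classifier implements its rules faithfully under realistic binomial
noise — not that the rules are robust to field-grade measurement error.

Determinism: every generator consumes a single master seed;
per-variety substreams are derived by counter offsets, so extending a
panel does not reshuffle existing varieties.

## Morphometrics

Scanner images are segmented by Otsu thresholding of the Rec. 601
luminance (polarity auto-detected from the border median, seeds assumed
darker than the bed), hole filling, removal of specks below 0.1 mm²,
and watershed splitting on the distance transform with h-maxima
suppression at 10% of the maximum distance — a standard, testable
substitute for proprietary kernel-counting software. Descriptors follow
the equivalent-ellipse conventions: axes from second central moments
(full axis = 4·√eigenvalue), eccentricity `sqrt(1 - (b/a)^2)`,
perimeter by the 4-direction Crofton estimate (lower bias than pixel
edge counting), solidity as area over the convex hull of pixel corners
(guaranteeing solidity ≤ 1). Pixel size is fixed at 25.4/dpi mm, dpi
defaulting to 1200. Because "eccentricity" in grain-imaging reports can
mean either the axis ratio b/a or `sqrt(1 - (b/a)^2)`, and reported
value ranges (0.34–0.85, zero = circular) match the latter, the moment
eccentricity is the canonical column and the aspect ratio is emitted
alongside it in the per-seed table.

## NIR quality control

Two exclusion steps run in order, then the adjustment. Predicted
constituents outside the instrument's calibration range are excluded
(boundaries inclusive). Remaining spectra are excluded when their
squared Mahalanobis distance from the calibration centroid exceeds the
χ² quantile at 1 − α (α = 0.001) with degrees of freedom equal to the
141 wavelengths. Two fidelity-driven choices: the centroid uses
calibration spectra only while the covariance pools experimental and
calibration rows (as the instrument protocol specifies, even though
calibration-only covariance is more common), and the *squared* distance
is compared with the χ² quantile — the standard-correct pairing when
"distances" are compared with a χ² law; a `statistic` switch reports
unsquared distances with an identical keep decision. Because 141
dimensions can exceed the pooled row count, a near-singular covariance
(condition number above 1e12) receives a ridge of 1e-8·trace(Σ)/141 on
the diagonal; both knobs are arguments. Dry-matter adjustment is
`value·100/(100 − moisture)`, the standard as-is-to-dry-basis
conversion, flagged here as an assumption since instrument protocols
rarely print it.

## FAMD

Quantitative columns are standardized with the population (1/n)
standard deviation and categorical levels enter as indicator columns
divided by `sqrt(p_l)` and centered, so one SVD with uniform row masses
yields the joint PCA/MCA: eigenvalues are squared singular values over
n, total inertia is exactly `K + sum(levels - 1)`, and the all-
quantitative case collapses to correlation-matrix PCA. Population
standardization matches the convention of the reference FAMD
formulation (sample-sd standardization is available via
`population_sd = FALSE`). Rows with any missing cell are dropped with a
logged count rather than imputed, mirroring complete-case practice in
trait panels. Signs are fixed by making the largest-magnitude loading
element positive per dimension, so output is reproducible. Plots retain
2 dimensions by default; the ≥ 50% cumulative-inertia support rule is
evaluated on the retained count and reported per analysis. Cluster
interpretation is visual; no formal cluster test is attempted.

## Proportional-odds regression

The model is `logit P(Y <= j) = theta_j - x'beta` with common slopes —
the parameterization whose cut-points print naturally as "1|2", "2|3",
"3|4". The likelihood is maximized by Newton–Raphson on the
unconstrained reparameterization (θ₁, log successive gaps, β) with
step-halving, so the log-likelihood is non-decreasing across
iterations; gradients are analytic, the Hessian is a central finite
difference of the gradient, convergence demands a gradient max-norm of
1e-8 within 100 iterations, and cut-points start at marginal
cumulative-proportion logits with zero slopes. Standard errors come
from the inverse observed information in the original parameterization;
p-values use the two-sided normal approximation 2(1 − Φ(|t|)), which is
what applied ordinal-regression tables report even though t-values
alone are the conservative default. Predictors are deliberately **not**
standardized: a seed-coat-thickness slope is only interpretable per
millimetre on the raw scale. Complete separation is detected on the
scale-free statistic |β_j|·sd(x_j) > 30 and raised as a diagnostic
error instead of silent divergence; an unobserved middle category is an
error.

## Problem sizes and test design

The test suite checks each stage against an independent oracle: ANOVA
and Tukey p-values against from-scratch sums of squares and `ptukey`
(100 random small data sets, 1e-6), FAMD against correlation-PCA and a
from-scratch correspondence analysis of the indicator matrix (1e-8,
inertia conservation to 1e-10 on 100 random tables), the ordinal fit
against binary logistic regression at J = 2 (1e-6), a dense grid search
on 30-observation problems, and an independent proportional-odds
implementation. Calibration simulations use 1,000 replicates at n = 200
(type-I error) and n = 500 (Wald coverage); the Mahalanobis null
exclusion rate uses 10,000 spectra; end-to-end recovery uses the full
default 189-variety panel. These sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances while keeping a full run
fast.

## Known limitations

* The classifier consumes day-7 means; germination-course dynamics
  (time-to-50%) are out of scope.
* The viability tree cannot distinguish a seed lot with storage-induced
  viability loss from genuinely recalcitrant material; both end as
  "concern".
* The NIR module implements only the exclusion filters and adjustment;
  the calibration model producing predicted constituents is instrument
  proprietary and out of scope.
* Category counts and color cross-tabulations should always be read
  with their denominators: color is typically scored for a subset of a
  panel, so per-category color counts need not sum to the full panel.

## A worked run

```{r run, eval = FALSE}
res <- run_pipeline(run_config())
res$report$category_counts
#>  ND  WD  MD  SD
#> 141  27   9  12
res$report$famd_summary
subset(res$report$trait_by_category, trait == "thickness")
```
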