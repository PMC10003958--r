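---
title: "Methods: specimen equivalence and method comparison for POC Cr/BUN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specimen equivalence and method comparison for POC Cr/BUN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specimeq)
```

## The problem

A blood gas analyzer at the point of care reports creatinine (Cr) and blood
urea nitrogen (BUN) from heparinized whole blood (H-WB), its
manufacturer-validated *primary* specimen. Two practical questions arise in
a laboratory running such a device alongside central-lab chemistry
analyzers:

1. **Method comparison** — do its results agree with the chemistry
   analyzers well enough to be used interchangeably?
2. **Specimen equivalence** — may *candidate* specimens (serum, or
   sodium-citrated whole blood, C-WB) be substituted for H-WB on the same
   device?

`specimeq` implements the statistical machinery for both questions in the
CLSI EP09/EP35 style: nonparametric method-comparison regression and
Bland–Altman agreement for (1), and decision-level bias plus
duplicate-based imprecision with SD-ratio acceptance for (2). Because
patient-level data of this kind are rarely public, the package also ships a
synthetic cohort generator with the same design (paired specimens, duplicate
measurements), so every stage is exercised end-to-end in tests.

## Passing–Bablok regression

For paired values $(x_i, y_i)$ (comparator, candidate), the slope estimate
is the *shifted median* of all pairwise slopes
$S_{ij} = (y_j - y_i)/(x_j - x_i)$, $i < j$:

* pairs with $x_i = x_j$ (including identical points) are discarded;
* slopes exactly $-1$ are discarded;
* with $N$ valid sorted slopes and $K = \#\{S_{ij} < -1\}$, the slope is
  the $((N+1)/2 + K)$-th order statistic ($N$ odd) or the arithmetic mean
  of the $(N/2 + K)$-th and $(N/2+1+K)$-th ($N$ even);
* the intercept is $\operatorname{median}(y_i - b x_i)$.

The $K$ offset makes the estimator invariant to exchanging the axes
($b \mapsto 1/b$, $a \mapsto -a/b$). Two caveats we verified and encode in
the test suite rather than gloss over:

* exact exchange symmetry is a theorem for an **odd** valid-slope count;
  with an even count the arithmetic-mean convention only pins the slope and
  the reciprocal of the swapped-axes slope into the same central slope
  bracket (agreement to the square of the bracket spacing — negligible on
  real data, visible on adversarial 5-point instances);
* the $K$-shift argument assumes the shifted index stays inside
  $[1, N]$ in both orientations, i.e. positively associated methods. Our
  implementation clamps the index instead of erroring, but the symmetry
  property is only asserted where it actually holds.

Confidence intervals come two ways. The analytic *rank* interval indexes the
ordered pairwise slopes at ranks given by the normal approximation of
Kendall's statistic, $C = z_{1-\alpha/2}\sqrt{n(n-1)(2n+5)/18}$. The
*bootstrap percentile* interval (the default, matching common practice for
this analysis) resamples subjects — never individual replicates — with
replacement, refits, and takes percentiles; the resampled
(slope, intercept) draws are retained so any function of the coefficients
can be propagated without assuming independence between them. The point
estimate is always the classical estimator; only the interval is
bootstrapped. The two interval methods agree closely on well-behaved data
(tested at $n = 100$, 5000 iterations, bound 0.05 per endpoint), and the
percentile interval's coverage for the slope is checked by simulation
(500 repetitions of $n = 100$ with 1000 iterations each; observed coverage
is required to fall in 93–97%).

## Agreement and decision-level bias

Bland–Altman differences are `candidate − comparator`; limits of agreement
are the mean difference $\pm 2$ SD of differences (the multiplier is
configurable; 2 is the field's usual plotting convention and our default),
and the mean-difference CI is t-based. The *percent* mean difference is the
mean of per-subject percentages $100(y_i - x_i)/x_i$, not the ratio of
means — on skewed clinical distributions the two differ, and the
per-subject definition is the standard percent-difference plot statistic.

The equivalence question is asked at **medical decision levels** — the
concentrations where clinical action changes (0.6/1.6/6.0 mg/dL Cr;
6/26/50 mg/dL BUN). The systematic difference at level $\ell$ is the
fitted equation's deviation from identity,
$\Delta(\ell) = a + (b-1)\ell$, expressed also as $100\,\Delta(\ell)/\ell$
and judged against the total allowable error (TEa: 7.4% Cr, 17.8% BUN,
desirable specifications from the EFLM biological-variation database). The
boundary passes: TEa is an *allowable* limit. CIs for $\Delta(\ell)$
propagate the joint bootstrap (slope, intercept) draws through the same
formula — differencing the endpoint CIs of slope and intercept separately
would ignore their strong negative dependence and overstate the width.

## Duplicate imprecision and the three-tier SD-ratio rule

With duplicates $X_{i,1}, X_{i,2}$ for $K$ subjects, the within-specimen SD
is estimated as

$$\mathrm{SD}^2 = \frac{1}{K} \sum_{i=1}^{K} \frac{(X_{i,2}-X_{i,1})^2}{2},$$

and %CV as $100\,\mathrm{SD}/\bar X$. Subjects are split into three
concentration subintervals at cutoffs bracketing the decision levels
(0.7/1.7 mg/dL Cr; 20/30 mg/dL BUN); the middle interval is closed on both
ends, so an exact boundary value falls in the middle group. Grouping uses
the **primary-specimen duplicate mean** and the subject keeps its group
across specimens — an SD ratio over different subject sets would be
meaningless. Within each subinterval (and pooled), the candidate/primary SD
ratio gets a subject-level *paired* bootstrap CI (resample subjects, recompute
both SDs and the ratio), and acceptability is decided in order:

* **(i)** ratio ≤ 1.00;
* **(ii)** ratio > 1.00 but its CI includes 1.00;
* **(iii)** ratio and lower CI bound > 1.00, but the candidate's %CV is
  within the allowable CV (2.3% Cr, 7.0% BUN);
* otherwise **unacceptable**.

Degenerate inputs are contracts, not crashes: an empty subinterval is
reported as missing with a warning; a zero primary SD (possible only with
noise-free duplicates) makes the ratio undefined, again reported as
missing at the pipeline level.

## The synthetic cohort generator

The generator emulates the study design the analysis assumes: `n_subjects`
(default 105) each contribute three simultaneously collected specimen types
measured in duplicate on the device under test, optionally plus comparator
analyzers measured in duplicate on serum from the same true concentrations.

* **Concentration mixture.** Per-subinterval subject counts are fixed
  (defaults 34/56/15 for Cr, 62/22/21 for BUN — the skewed clinical case
  mix), and true concentrations are drawn log-uniformly within each
  subinterval (overall ranges 0.3–8 mg/dL Cr, 4–80 mg/dL BUN, chosen to
  bracket the subinterval means such a case mix implies). Log-uniform draws reproduce a
  right-skewed clinical distribution without inventing a finer histogram
  the data do not constrain.
* **Boundary guard.** Group membership downstream is decided by the
  *observed* duplicate mean, which is noisy; sampling intervals abutting a
  cutoff are therefore shrunk multiplicatively by 6 duplicate-mean noise
  SDs, so each subject's observed mean lands in its configured group with
  near-certainty and the configured counts are reproduced by construction.
* **Specimen effects.** Each specimen's latent value is
  $\text{slope}\cdot c + \text{intercept}$; presets `"cr-study"` and
  `"bun-study"` carry the preset candidate-specimen biases
  (e.g. C-WB Cr slope 0.89, intercept −0.01 mg/dL).
* **Replicate noise.** Multiplicative, constant CV (default 2% per
  specimen, consistent with typical whole-blood mid-range duplicate
  CVs of ~1.4–3.2%), independent across replicates, specimens and systems;
  draws are redrawn if a value would be non-positive. An additive-SD mode
  exists for sensitivity checks, since the allowable limits are CV-based
  but some instruments show constant absolute scatter at the low end.

What the generator deliberately does **not** model: analyzer calibration
drift, hemolysis/citrate interference beyond a fixed linear effect,
between-day imprecision components, or heavier-than-lognormal concentration
tails. Passing tests therefore demonstrate the *statistical machinery* is
correct under the stated design, not that any particular instrument is
equivalent on real patients.

## Numerical and design choices

* Computation is full precision throughout; rounding happens exactly once,
  in `write_report()` (default 2 digits).
* All bootstraps resample the **subject**; the default seed 20230301 is
  recorded in provenance, and per-comparison seeds are derived
  deterministically from the run seed, so reruns are byte-identical.
* A bootstrap resample on which a statistic is undefined (e.g. all
  comparator values equal after resampling) is redrawn, with a hard cap of
  10× the iteration count before erroring.
* Problem sizes in the test suite were chosen to make sampling error
  negligible relative to the asserted tolerances: 1000 random instances for
  oracle equality; 200 seeds at $n = 105$ for median-slope recovery
  (tolerance ±0.01); 500×1000 for bootstrap coverage; 500 subjects for
  point recovery of slope (±0.02) and %CV (±0.4 points, read off the
  narrow middle subinterval, since a pooled SD/mean across a wide skewed
  range overstates a constant replicate CV).
* The one-way ANOVA across analyzers or specimens is the classical
  fixed-effects omnibus test, one per analyte per axis of comparison; the
  all-constant degenerate case is defined as $F = 0$, $p = 1$.

## Known limitations

* Passing–Bablok here targets positively associated methods (the usual
  method-comparison setting); no Part-III-style variant for negatively
  associated or scale-shifted methods is provided.
* Percent systematic differences computed from *rounded, printed*
  regression coefficients will not exactly match values computed from
  full-precision coefficients (e.g. −12.67% vs −12.96% at 0.6 mg/dL Cr from
  two-digit C-WB coefficients); the package always reports full-precision
  values and rounds only at output.
* Regression and agreement use the per-subject duplicate mean; with
  complete duplicates this matches pooling all replicates, and subjects
  missing a replicate keep their single value there while being excluded
  from duplicate-SD statistics.

## A minimal run

```{r, eval = FALSE}
library(specimeq)
coh <- generate_cohort(preset_cohort("cr-study"))
res <- run_pipeline(coh, analysis_config(bootstrap_iterations = 1000))
res$bias[, c("specimen", "decision_level", "systematic_difference_pct", "verdict")]
write_report(res, "tables", format = "csv")
```
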