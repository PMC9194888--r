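---
title: "Methods: normative standardization of a telephone-based frontal screening battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative standardization of a telephone-based frontal screening battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfab)
```

## The measurement problem

The telephone-based Frontal Assessment Battery is a short executive
screening test: four tasks scored 0–3, a total of 0–12, in two versions
(motor and verbal responses to the interference and inhibition tasks) that
share subtest 1 (conceptualization + mental flexibility). Like most brief
cognitive screens in healthy adults, its totals are strongly left-skewed
with a heavy ceiling — roughly 36–39% of healthy respondents score 12/12 —
and depend on education (all scores) and age (motor scores only). A raw
cut-off is therefore meaningless: a 10/12 is unremarkable for a young
graduate and would be an excellent score for a 90-year-old with primary
education. The package implements the normative machinery that turns raw
scores into demographically fair, clinically interpretable bands, and the
psychometric and design analyses that accompany such a standardization.

## Demographic adjustment

Raw scores are corrected additively towards the cohort-average profile:

$$AS = RS + \sum_k \beta_k\,\bigl(f_k(x_k) - \overline{f_k(x_k)}\bigr),$$

with $f_k$ a transform of age or education and the centering constant the
*normative-cohort mean of the transformed variable* (the published centering
constant for $\text{age}^3$ is the mean cube of age, not the cube of mean
age — the two differ by thousands of years³). A participant at the average
profile is untouched; the adjustment grows for older/less-educated
profiles and turns negative above the centers. Adjusted scores are *not*
clamped to 0–12: the adjusted scale is an open regression scale, and the
printed grids themselves warn that extreme cells need not reflect
empirically occurring profiles.

`fit_adjustment()` re-derives equations from a cohort by forward stepwise
selection. The procedure was deliberately pinned down as: per variable
(age, education, sex), pre-screen the candidate transforms (age: identity,
square, cube; education: identity, log10, ln, reciprocal; sex: indicator)
by residual sum of squares given the terms already in the model; across
variables, the best candidate enters if its coefficient is significant at
`entry_alpha = 0.05`; stop when none is. Forward entry at 0.05 reproduces
the expected selection pattern on cohorts generated under the shipped
model (education everywhere, age only on motor outcomes). Two numerical
details matter:

* **Log-base ties.** `log10` and `ln` span exactly the same model, so their
  residual sums of squares differ only by floating-point noise. Ties are
  broken deterministically to the first candidate in declared order, and
  comparisons of fitted equations against a known truth should treat the
  two as one equivalence class (coefficients convert by a factor
  $\ln 10$).
* **Refit after selection.** Reported slopes, p-values and centers come
  from a final joint fit of the selected terms, not from the entry steps.

Sex is a candidate predictor throughout; the shipped model has no sex term
(it was not significant in the normative cohort), but user-derived norms
may select it.

## Tolerance limits and Equivalent Scores

Because the score distribution is discrete and ceiling-heavy, the
impairment threshold is non-parametric. The outer tolerance limit is the
order statistic that bounds the worst 5% of the population with 95%
confidence: the largest rank $r$ with
$P[\mathrm{Bin}(n, 0.05) \ge r] \ge 0.95$, evaluated by exact binomial
enumeration at every $n$ (no normal approximation; `tolerance_limit_ranks()`).
The criterion is infeasible for $n \le 58$ ($1 - 0.95^{58} < 0.95$), so the
smallest cohort with a defined outer limit has $n = 59$; smaller cohorts
yield a model explicitly flagged `"no outer TL"` with ES 0 undefined,
never a silent default. Ranking uses a stable sort tie-broken by
participant id, so a rebuilt model is byte-identical.

Equivalent Scores partition the adjusted scale: ES 0 (impaired) at or
below the outer limit, ES 4 from the sample median upward, ES 1–3 between.
The placement of the two interior cut points is not fixed by a single
convention in the normative literature, so it is explicit and configurable
here: the default splits the standard-normal interval $[-1.645, 0]$ into
four equal z-segments, giving target centiles 0.1086 and 0.2054 for the
lower edges of ES 2 and ES 3. The shipped model's printed bands cannot be
re-derived without the original cohort, so the scheme is documented as the
package's default rather than asserted as identical to the authors'.
Boundaries are reported at 2-decimal resolution, and classification rounds
the adjusted score to 2 decimals *first* — the printed bands are closed
intervals at that resolution (e.g. 8.08–9.45), and rounding first avoids
gaps between adjacent bands. Whether the original scoring sheet rounds or
truncates before lookup is unstated; rounding was chosen as the
convention that makes the printed band edges exhaustive.

Demographic coverage (ages 18–96, education 4–23 for the shipped model) is
enforced as a *flag*, not an error: clinical users scoring a 17-year-old
get a result marked `extrapolated`, so use outside the normative range
degrades loudly rather than silently.

## Psychometric validation

* **Correlations** choose Pearson when both variables pass the moment rule
  (|skewness| < 1 and |excess kurtosis| < 3) and Spearman otherwise, with
  Bonferroni adjustment `alpha / family_size`. The family size is a
  required, explicit quantity (reported in every output row) because the
  comparison count behind a published adjusted level is easy to
  mis-reconstruct after the fact.
* **ICC** defaults to the two-way random-effects, absolute-agreement,
  single-rater coefficient — the stricter choice for inter-rater data,
  where systematic rater offsets should count against reliability; the
  consistency variant is available for test–retest designs. Confidence
  intervals use the McGraw–Wong F-bounds (Satterthwaite df for the
  agreement form).
* **PCA** decomposes the task-score correlation matrix, retains components
  by the eigenvalue > 1 rule, and fixes the first-component sign so the
  loading sum is positive. On an exact equicorrelation matrix the leading
  eigenvalue is $1 + (p-1)\rho$, which the tests verify to $10^{-9}$.
* **TOST** interprets the equivalence bounds as standardized $d_z$ (bounds
  times the sample SD of the differences), the parametrization under which
  the published design size of 52 pairs arises from the normal
  approximation $n = \lceil (z_{1-\alpha} + z_{1-(1-\text{power})/2})^2 /
  d_z^2 \rceil$. With sample-SD-scaled bounds the two one-sided t tests
  reduce to $|t| < d_z\sqrt{n} - t_{1-\alpha,\,n-1}$, so the exact
  equivalence rate at a true zero effect is
  $2\,F_{t,n-1}(d_z\sqrt{n} - t_{1-\alpha,n-1}) - 1$ — about 0.941 at
  $n = 52$, slightly below the design's nominal 95% because the normal
  approximation ignores the $t$ critical value. `tost_sample_size(exact =
  TRUE)` iterates that exact rate instead.

## Design calculators

`regression_sample_size()` finds the smallest total $n = u + v + 1$ whose
noncentral-F power (noncentrality $\lambda = f^2(u + v + 1)$) reaches the
target; at $f^2 = 0.05$, $u = 3$, power 0.95 it returns 348 under this
standard convention. `roc_sample_size()` implements the Obuchowski
binormal-variance formula; the published pair (19 cases, 190 controls at
AUC 0.7, allocation 10, power 0.90) arises under a one-sided level, which
is therefore the default, with the two-sided variant behind a flag. The
AUC itself is estimated by the tie-corrected Mann–Whitney statistic with
DeLong standard errors (Hanley–McNeil available for comparability with
spreadsheet calculators); scores are oriented `lower_score_is_case` by
default because impairment lowers screening scores.

## What the synthetic cohorts do and do not emulate

`simulate_normative()` reproduces: the stratification table (age band ×
education band × sex), education/age effects via the shipped equations
used as generating truth, residual spread `latent_sd = 1.3` points
(chosen so the discretized totals show a marginal SD near the observed
1.2–1.5), a motor–verbal latent correlation `version_cor = 0.6` (not
published; exposed as a free parameter), and ceiling rates 0.358/0.393
calibrated per sample by bisection of the latent anchor — a deterministic
pre-pass on the seeded draw, accurate to one count in $n$. Discretization
is round-then-truncate; no item-response process is modelled. Two
consequences bound what passing tests can show about real data:

* Censoring at the ceiling attenuates regression slopes, so
  parameter-recovery checks of the norming estimators run on the
  continuous latent scores (`discretize = FALSE`); on discretized cohorts
  only the sign pattern and transform selection are asserted.
* Totals are decomposed into tasks greedily (3, then the remainder),
  which makes individual task columns nearly degenerate; the generator's
  contract covers subtests and totals, and task-level analyses in the
  tests build factor-structured task data directly.

`simulate_clinical()` draws totals from a truncated-rounded bivariate
normal at the reported group means/SDs — adequate for ROC and equivalence
structure, with no claim about within-group demographics–score coupling.
`simulate_raters()` composes subject and error effects at an exact
variance-ratio target; integer rounding adds $\approx 1/12$ to the error
variance (about a 1% ICC attenuation at the default spread).

## Problem sizes and determinism

The test suite exercises: exhaustive tolerance-rank enumeration to
$n = 2000$; norming recovery at $n = 5000$; a $10^4$-replicate TOST
Monte-Carlo at the designed $n = 52$; ICC interval coverage over 120
seeded replicates at $n = 60$; and ROC oracle equality up to $19 \times
190$. These sizes keep the full suite under a minute on one core while
leaving Monte-Carlo error well inside the asserted bands. All generators
require explicit seeds, every derivation is deterministic given cohort
and settings, and a rebuilt model serializes to byte-identical JSON —
the audit property a normative instrument needs.

## Known limitations

No parametric (Gaussian z-score) norming alternative and no
reliable-change or longitudinal norms are provided. The interior ES cut
points follow the documented default scheme, not a reconstruction of the
original ones. The clinical generators reproduce marginal moments only.
Task items and administration are out of scope; companion test scores are
treated as opaque numbers.
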