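---
title: "Calibrating Likert instruments with the rating scale model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating Likert instruments with the rating scale model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrasch)
```

## The model

`polyrasch` fits the Rasch rating scale model (RSM) to persons × items
matrices of ordered category codes. For person measure $\theta_j$, item
difficulty $\delta_i$ and shared Andrich thresholds $\tau_2,\dots,\tau_m$,

$$\ln\frac{P_{ijk}}{P_{ij(k-1)}} = (\theta_j - \delta_i) - \tau_k,$$

equivalently, category $k$ (scored $s = k-1$) has probability proportional
to $\exp\{s(\theta_j-\delta_i) - \sum_{l \le k}\tau_l\}$. The RSM's defining
assumption — one threshold set shared by all items — is what makes it
appropriate for instruments whose items use identical category labels, and
is what the rating-scale diagnostics interrogate. Higher measures endorse
higher categories by construction. Published presentations of this family
sometimes print the model with the person term subtracted from the item
term; written that way literally, endorsement probability would *decrease*
with the trait, contradicting the universal interpretation ("higher logit =
higher risk"). We implement the interpretation: the person-minus-item
orientation above.

The model is a description of frequency-of-endorsement behaviour, not of
classical scores; the classical 0–3 EAT-26 scoring (with its mirrored
reverse map for item 26 — the published instrument convention, adopted here
as an exact mirror of the forward map) is provided separately for the
referral-cutoff workflow, and `collapse_for_rasch()` can recode the six
categories through the point maps when a four-category sensitivity analysis
is wanted. The calibration default is the raw six categories.

## Estimation

Joint maximum likelihood (JMLE): alternating Newton–Raphson updates of
persons, items, then thresholds, each step capped at 1 logit and scaled by
a damping factor that halves whenever a full cycle would decrease the joint
log-likelihood (so the likelihood is non-decreasing across accepted
iterations). Identification is the standard convention under which person
summaries like a mean of −0.72 logits are reported: items mean-centered
over non-extreme items, thresholds sum to zero, persons free. Both
constraints are exact reparameterizations and cost no likelihood.

Defaults (all in `estimation_config()`):

* `convergence_tol = 0.005` logits on the maximum parameter change, and
  `max_iterations = 200` — desk-scale settings that converge in 10–30
  cycles on the problem sizes below;
* `extreme_adjustment = 0.3` score points: persons/items with zero or
  perfect raw scores have no finite MLE, are excluded from iteration, and
  afterwards receive measures by solving the anchored score equation at a
  raw score pulled 0.3 points inside the boundary — the common convention
  for giving extremes finite, ordered measures;
* `bias_correction = FALSE`: the well-known JMLE spread bias can be
  corrected by the first-order $(L-1)/L$ factor, but the reported
  conventions this package mirrors use raw JMLE, so the flag is off by
  default.

Standard errors come from the inverse observed information per parameter.
Exact numerical agreement with any specific commercial implementation is
not promised: extrapolation rules and bias handling differ across programs
and versions; what is guaranteed is internal consistency and the recovery
behaviour demonstrated in the test suite.

Degenerate inputs are refused loudly: fewer than two non-extreme persons or
items, or a category never observed among non-extreme cells (the score
equations for a never-seen category have no solution; the error instructs
the user to collapse categories first).

## Diagnostics and their conventions

**Fit.** Standardized residuals $z = (x - E)/\sqrt{W}$ at the fitted
parameters; item/person Outfit is the unweighted mean of $z^2$, Infit the
information-weighted $\sum W z^2 / \sum W$. Removal uses the conventional
0.5/1.5 mean-square bounds. Because published removal decisions mix rules —
some rounds remove on both statistics violating, some on Outfit alone, and
judgment can exempt a substantively essential item — the rule is explicit
configuration: `removal_rule(mode = "both" | "either", exempt = ...)`, with
`"both"` the default and every round logged (flagged, removed,
exempt-retained, fit table). ZSTD statistics are computed
(Wilson–Hilferty) but never drive decisions; mean squares do.

**Rating scale.** Four criteria: (a) regular observation distribution,
operationalized as at least 10 observations per category (the
conventional guideline; the threshold is the `min_count` argument);
(b) average measures strictly advancing with category; (c) category Outfit
< 2.0; (d) strictly advancing Andrich thresholds. Disordered thresholds
are a property of the *scale*, not an estimation failure, and the
simulator will happily generate from disordered thresholds — the reference
fixture does exactly that, and the diagnostics recover the disorder.

**Dimensionality.** PCA of the item × item correlation matrix of
standardized residuals, pairwise-complete; eigenvalues are in item units
so the first contrast is compared against the conventional 2.0-item
ceiling. Pairwise correlation matrices can be marginally non-positive
definite; trailing eigenvalues are clamped at zero. Zero-residual-variance
items are dropped with a note. Local independence uses the max absolute
residual correlation against 0.7.

**Separation.** $RMSE^2$ is the mean squared standard error over
non-extreme facets; true SD is $\sqrt{\max(0, SD_{obs}^2 - RMSE^2)}$
(clamped rather than imaginary when error swamps spread); $G$, $R$ and
strata $(4G+1)/3$ follow. Both the raw strata value and its floor are
reported, since published accounts sometimes round down (a separation of
2.51 yields $H = 3.68$, described as "about 3 strata"). Only model-based
SEs are used; misfit-inflated "real" SEs are out of scope.

**DIF.** Person measures and thresholds are anchored at the combined
calibration; each item's difficulty is re-solved within each group. The
flag requires *both* substantive size (|contrast| > 0.43 logits) and
significance (two-sided Welch t, p < 0.001, no further multiplicity
correction — the strict alpha is itself the multiple-comparison guard).
The focal group is the second sorted covariate level; positive size means
harder for the focal group. A Mantel–Haenszel common log-odds over
raw-score strata (pooled over category cutpoints, Liu–Agresti style) is
emitted alongside; it lives on the cumulative-odds scale, so it
cross-checks direction and magnitude order, not the logit value itself.

**Wright map.** Text rendering with 0.1-logit bins (mirroring the usual
published granularity; configurable), one `#` per $\lceil n/50\rceil$
persons with `.` for remainders, and M/S/T markers at each facet's mean
and ±1/±2 SD. Text output is the canonical artifact because it is testable
byte-for-byte; nothing in the pipeline is timestamped, so identical input,
configuration and seed reproduce every artifact exactly.

## What the simulator emulates — and what it does not

`sim_spec()` draws person measures from a Normal distribution, responses
from the RSM, and layers on the three pathologies the diagnostics exist to
catch: uniform-shift DIF (chosen to match the difficulty-contrast
estimator — generator and estimator agree on what DIF *is*),
uniform-random replacement misfit (chosen because it provably inflates
Outfit), and a Normal second-dimension term added to flagged items'
linear predictors. `eat26_reference_spec()` fixes the study-like
conditions: 469 persons, 26 items, 6 categories, persons N(−0.72, 0.77),
difficulties on an even grid over [−0.72, 1.03], the published
(disordered, sum-zero) thresholds, covariates `female` (0.725) and
`obese` (0.58). Two caveats documented once: the reported person
statistics describe a post-removal 19-item calibration, and the fixture
applies them to all 26 items for want of anything better; and an even
difficulty grid plus exact normality are idealizations — real response
data have lumpy difficulty spacing, skewed category usage driven by the
population, person misfit, and missingness patterns none of which the
clean generator reproduces. Passing recovery tests therefore validate the
estimator and diagnostics under the model, not the behaviour of any real
dataset.

## Problem sizes and numerical checks

The test suite validates at sizes chosen to keep Monte-Carlo error small
relative to the asserted tolerances while running in seconds: 500 × 20 for
parameter recovery (difficulty correlation > 0.98, threshold RMSE < 0.1),
2000 × 20 for null fit-statistic calibration (mean Infit within 0.95–1.05),
1000 × 20 for misfit and dimensionality injections, 2000 persons for DIF
recovery (0.8-logit shift recovered ± 0.15) with 20 seeded replicates for
the power check, and a 5 × 3 dichotomous matrix against a brute-force
0.01-logit coordinate grid-search oracle (agreement within 0.02 logits).
Closed forms anchor the rest: enumeration of category weights, Bernoulli
moments, the $R = G^2/(1+G^2)$ identity, and the normal-CDF targeting
oracle ($\Phi(0) = 0.5$ of a N(−0.72, 0.77) population lies below an
easiest item at −0.72).

## Known limitations

* JMLE estimates are consistent only as both facets grow; at short test
  lengths difficulties are biased outward unless `bias_correction` is
  enabled.
* The partial credit model (item-specific thresholds), marginal ML with a
  latent distribution, non-uniform DIF, DIF purification and person-fit
  driven removal are out of scope.
* The Mantel–Haenszel figure is a cross-check, not a second decision rule.
* Classical totals are never imputed under missingness; Rasch estimation
  handles missing cells naturally, the 0–3 total does not.
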