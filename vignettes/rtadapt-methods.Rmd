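---
title: "Methods: testing microgeographic local adaptation in a reciprocal transplant experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing microgeographic local adaptation in a reciprocal transplant experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reciprocal transplant experiments (RTEs) move seeds between habitats and
regions and follow each individual's germination, survival and growth in
the field. Local adaptation is classically diagnosed by two comparisons:
*home vs. away* (does a population do better in its own environment than
elsewhere?) and *local vs. foreign* (do residents outperform immigrants
within one environment?). Both comparisons are fragile when germination
differences leave the final design badly unbalanced.

`rtadapt` implements an analysis built for exactly that situation, for a
cohort of tropical tree seedlings from two ecotypes (a seasonally-flooded
specialist, `glo`, and a generalist, `sp1`) and two provenance regions
(`E`, `W`), planted into 12 gardens crossing two plantation regions with
two microhabitats (`SF` seasonally flooded, `HT` hilltop). The package
couples fixed-effect (generalized) linear models with least-squares
(adjusted) means, a single combined home-vs-away contrast, and
permutation-based conditional inference trees.

## Data model

An individual carries its design factors — ecotype $e$, habitat $h$,
provenance $o$, plantation $r$, transplant status $s$ — its shadehouse
time $t$ (days between sowing and transplant, 27–315, set at the mother
level by collection date), a germination timing
(`at_transplant`, `year1` … `year5`, `never`) and a yearly fate sequence
(`pre_germination` / `alive` / `dead`). Censuses are yearly with one gap
year, so measurements exist at ages $\{0, 1, 2, 4, 5\}$; growth-rate
calculations divide by elapsed time across the gap. Traits are height
(cm), collar diameter (mm), total number of leaves, and herbivory: each
leaf is classed into damage quintiles (0–20% … 80–100%) and a seedling's
score is the mean of the class midpoints (10, 30, 50, 70, 90), which is
why observed herbivory lies in $[10, 90]$ and the observed minimum is
10%.

### Survival coding

The survival response is the number of whole years an individual was
recorded alive after germination. We count post-transplant censuses with
fate `alive`: a transplanted seedling found dead at the first census has
age 0; one alive at the final census is right-censored at age 5 (the
records do not say it died, so a coherent likelihood must treat it as
censored — the source material is silent on this point, so the package
states the convention explicitly). For individuals that germinate in the
field, the census at which they are first recorded is deterministically
"alive" (that is what being recorded means), so their counts carry one
guaranteed success; the generator reproduces this convention exactly, and
recovery tests for the geometric fitter use transplanted-seedling-style
cohorts where the count is purely geometric.

## Models

All models are fixed-effect; the experiment has too few mothers per cell
for useful random effects, and none are used.

**Shadehouse germination.** With only genetic factors and shadehouse time
acting before transplant,
$$\mathrm{logit}(p^G_{eok}) = \mu^G + \alpha^G_e + \delta^G_o +
\varepsilon^G_{eo} + (\beta + \gamma^G_e + \eta^G_o)\,t_{eok},$$
seven free coefficients with two-level factors. Fitting is iteratively
reweighted least squares written in the package (tolerance $10^{-10}$ on
the relative deviance change, 100 iterations), covariance from the
inverse Fisher information. Some design cells reach 100% germination, so
complete separation is possible: it is detected from diverging linear
predictors ($|\hat\eta| > 15$) and handled by an $L_2$ penalty of
$10^{-4}$ on non-intercept coefficients, always flagged and warned.

**Overall germination** uses the same logit machinery without the
shadehouse-time term, with factors $e, o, h, r$.

**Germination timing and survival** use a censored geometric model: an
individual continues one more year with probability $q$, so an
uncensored count $k$ contributes $q^k(1-q)$ and a censored one $q^k$.
The linear predictor is $\mathrm{logit}(q) = X\beta$. Because
$q/(1-q)$ *is* the geometric mean count, a log link on the mean waiting
time and a logit link on the yearly continuation probability are the
same fit — the package implements one Newton optimizer (analytic
gradient and Hessian, step-halving) and lets the caller pick the
reporting convention. On uncensored intercept-only data the MLE has the
closed form $\hat q = \sum k / (n + \sum k)$, which the tests check to
$10^{-8}$.

**Growth traits** are modelled on the natural-log scale (the yearly
figures in this literature plot log traits; multiplicative errors are
the natural assumption for sizes):
$$\mu^Y_{ehorsa} = \mu^Y + \alpha^Y_{eh} + \delta^Y_{ors} +
(\beta^Y + \gamma^Y_{eh} + \theta^Y_{ors})\,a,$$
22 coefficients. The $(e{\times}h) \times (o{\times}r{\times}s)$
interaction is deliberately excluded: not all 32 combinations were
observed, and requesting it raises an estimability error rather than a
silent column drop. Fitting is QR least squares with
$\hat\sigma^2 = \mathrm{RSS}/(n-p)$.

## Adjusted means and the combined contrast

A least-squares (adjusted) mean for a focal cell is the *unweighted*
average of model predictions over every nuisance-factor cell — $1/2$
over provenance for shadehouse germination, $1/8$ over
$(o, r, s)$ for survival and growth — at fixed covariate values (mean
shadehouse time $\bar t$, or age $a$). The package computes it by
prediction averaging, which is invariant to the factor coding; under
sum-to-zero coding it reproduces the closed-form weight expressions
exactly, and the tests assert equality with a brute-force enumeration of
cell predictions to $10^{-10}$ under both codings.

The headline statistic is, per age,
$$C_a = (\mu^{adj}_{11}(a) + \mu^{adj}_{22}(a)) -
(\mu^{adj}_{12}(a) + \mu^{adj}_{21}(a)),$$
where 11 and 22 are the sympatric ("home") origin-environment cells.
$C_a > 0$ means the average home individual outperforms the average away
individual. One Wald test of $C_a = 0$ (t reference with residual
degrees of freedom for Gaussian fits, normal otherwise) subsumes both
classical criteria; it deliberately confounds "true" local adaptation
with global superiority of one population, trading that for much better
behaviour under imbalance. Stars follow the usual
0.05 / 0.01 / 0.001 convention. Ages are tested one by one, never
pooled.

Pairwise comparisons of overall-germination adjusted means are
multiplicity-adjusted; the original analysis cites a multiple-comparison
framework without naming the correction, so the package exposes
`none` / `bonferroni` / `holm` and defaults to Bonferroni (conservative,
assumption-free).

## Conditional inference trees and forest

Trees split a node only when a permutation test rejects independence of
the response and some covariate. The statistic is Pearson's $X^2$ on the
contingency table for a nominal response (the 7-level fate code
`U`, `D1`–`D5`, `A`) and the between-level sum of squares for numeric
responses (year-6 traits and relative growth rates). When the number of
distinct covariate rearrangements is ≤ 10,000 the null set is enumerated
exactly (so the four-observation textbook case gives exactly $2/6$);
otherwise 9,999 Monte Carlo permutations by default, with the observed
statistic always counted in the null set so p is never 0. Per node,
p-values are Bonferroni-adjusted across the covariates tested; the split
uses $\alpha = 0.05$ and a minimum of 2 observations per branch. Ties in
the covariate selection break by configured covariate order, the split
partition maximizes the association statistic subject to the branch
minimum, and Monte Carlo streams are derived from the master seed and
node id after canonicalizing row order — trees are therefore invariant
to row order and reproducible. The death codes `D1`–`D5` are treated as
nominal, not ordinal, matching the visualization they mirror; no
surrogate splits.

The forest grows each tree on a bootstrap sample with `mtry` candidate
covariates per node; importance is the mean drop in out-of-bag accuracy
(nominal) or the mean rise in out-of-bag MSE (numeric) when a
covariate's out-of-bag values are permuted. The source material states
neither the permutation count, the multiplicity scheme, nor
`mtry`/`n_trees`; all are exposed as configuration with documented
defaults (9,999; Bonferroni; 2; 100), not reconstructions of anyone's
settings.

## The synthetic generator

`sim_config()` states one world and the defaults are not revisited: 14
mothers (5 eastern, 9 western; the published 35–39 seeds each, 510
total), 12 gardens (3 replicates per region × habitat), three seeds per
mother per garden with the remainder assigned at random, mother-level
shadehouse times uniform on 27–315 days. Germination follows the
shadehouse logit model with defaults calibrated so that roughly 36% of
seeds germinate before transplant and east strongly outgerminates west;
seeds transplanted ungerminated face a constant yearly field hazard
(0.14 east, 0.09 west) — the source material offers no
field-germination model, so constant hazard is a documented stand-in
that reproduces the observed pattern of western seeds germinating about
a year later and an overall germination near 61%. Survival is geometric
with yearly continuation probability around 0.88, a seasonally-flooded
home advantage for the flood specialist and a plantation-region effect;
growth is log-normal per trait calibrated to the published year-6
summaries (mean height ≈ 28 cm, diameter ≈ 4 mm, ≈ 17 leaves); herbivory
draws per-leaf damage classes from (ecotype × habitat) distributions
with the specialist suffering more damage outside its home habitat. Each
stage draws from its own seed-derived stream, so adding a stage never
perturbs earlier draws and identical configurations give byte-identical
datasets.

What the generator does *not* emulate: spatial autocorrelation within
gardens, maternal provisioning and epigenetic effects, overdispersion
beyond the stated families, and measurement error in trait readings. A
green test therefore establishes that the estimators recover the stated
generative structure at the stated design size — not that real data meet
these assumptions.

## Numerical and design choices

* Herbivory classes map to midpoints (10/30/50/70/90): the published
  minimum seedling herbivory of 10% identifies the midpoint convention.
* Rank deficiency in any design matrix is an error naming the aliased
  columns, never a silent drop.
* In rare generator replicates (&lt;1%) no eastern
  ungerminated-at-transplant seed is ever measured and the full growth
  model loses a status cell; the calibration tests then merge transplant
  statuses, the same fallback the original analysis applied when the
  data could not support the status distinction.
* Wald tests use a pseudo-inverse so degenerate (all-zero) contrasts
  return statistic 0 and p = 1 instead of failing.
* Tree exports: indented text, DOT, and a JSON form that round-trips
  routing and predictions exactly.
* All pipeline randomness flows from a single master seed; re-running a
  configuration reproduces every output file byte for byte.

## Known limitations

Fixed effects only (no mother-level random effects); the geometric
survival model assumes a constant yearly hazard per design cell; the
field-germination hazard is a modelling convenience, not an inference;
the forest importance is the plain permutation variant (no conditional
importance); and the package emits plot-ready tables rather than styled
figures.
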