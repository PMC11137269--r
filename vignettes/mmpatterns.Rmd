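---
title: "Multimorbidity patterns and trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity patterns and trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpatterns)
```

`mmpatterns` implements a complete workflow for discovering multimorbidity
patterns in a closed cohort of adults followed over repeated
cross-sections, tracking how patients move between patterns, and
estimating adjusted mortality and acute-disease associations. This
vignette is the package's own account of the science: the procedure, its
assumptions, the parameters that matter, and the choices made where the
design was genuinely open.

## The analysis model

### Cohort and filters

The unit of analysis is a **closed cohort**: membership is fixed at
baseline (every adult 18–65 with *multimorbidity*, i.e. at least two
chronic conditions from a fixed catalog of grouped chronic-condition
categories) and patients can only leave, by death or by loss to follow-up
(inactive registration). Three cross-sections ("waves") are analysed:
baseline and two four-year follow-ups. Chronic conditions are cumulative —
a condition once recorded stays in the clinical history — so each
patient's per-wave condition set is non-decreasing.

Each wave's analysis dataset is a binary patient × condition matrix over
the patients still included at that wave, restricted to conditions with
prevalence ≥ 1.0% in that wave (`build_wave()`; the comparison is
inclusive because the definition is "prevalence ≥ 1.0%", so the boundary
case is kept). Prevalence is carriers divided by included patients.

Two deduplication rules make drug and acute-disease burdens comparable
across patients: repeated dispensations within the same **fourth-level ATC
subgroup** (first five characters of the ATC code, mainly the chemical
subgroup) in a follow-up period count once, and repeated diagnoses of the
same **acute condition** within a period count once. Both counts are
per-period: the same label in both periods contributes once to each.

### Pattern discovery

Patients are partitioned with **k-means under the Jaccard distance**. The
field's convention measures patient similarity with the Jaccard index of
their binary disease profiles; to keep Lloyd-style alternation
well-defined with real-valued centroids we use the generalised (Tanimoto)
form

$$d(x, c) = 1 - \frac{\sum_j \min(x_j, c_j)}{\sum_j \max(x_j, c_j)},$$

which reduces exactly to the set Jaccard distance when both arguments are
binary (a property the tests assert). The algorithm alternates assignment
to the nearest centroid and centroid update to within-cluster column
means, so each centroid is a prevalence profile over conditions.

The number of patterns k is chosen with the **Caliński–Harabasz index**,
the ratio of between- to within-cluster dispersion normalised by degrees
of freedom, computed with Euclidean dispersion about the binary matrix's
centroids (its standard definition; no Jaccard-adapted variant of CH is
established, and the choice is recorded in the selection report). Model
selection is constrained by a **validity rule**: a partition is admissible
only if every pattern has at least one *essential* condition.

### Essential conditions and pattern profiles

For condition j in pattern p, the **observed prevalence** OP is its
prevalence among the pattern's members and the **expected prevalence** EP
its prevalence in the wave's whole analysed population; the **prevalence
ratio** is PR = OP/EP. A condition is *essential* to a pattern when

* PR ≥ 2.0 and OP ≥ 10%, or
* OP ≥ 20% and PR ≥ 1.5,

with inclusive comparisons. Essential conditions define a pattern's
clinical particularity — they are the over-represented conditions, not
necessarily the most prevalent ones. A useful exact identity links the two
prevalence notions: for every condition, the size-weighted sum of
per-pattern OPs reconstructs n·EP. The test suite asserts this to 1e-12.

Pattern naming in practice is a clinical-consensus exercise; the package
emits a deterministic mechanical stand-in (the top two essential
conditions by PR, ties broken alphabetically; "unspecific" when the
essential set is empty) and treats it as display metadata only — all
computations use raw labels. Note a subtle consequence of the rule: a
single-pattern wave has PR = 1 everywhere, so *no* condition can be
essential there and a k = 1 "partition" can never pass the validity rule.

### Selecting k

Analysts in this field prefer **the lowest number of patterns** that still
separates the population well. `select_k()` operationalises this: among
the candidates whose partitions are valid, it takes the smallest k whose
CH score is within a tolerance (default 10%) of the best valid score. The
tolerance is a configuration knob, and the full per-k curve (CH score,
validity, minimum essential-set size) is always reported so a human can
override the choice — the software equivalent of the consensus rounds such
studies use.

### Trajectories

Patterns are re-derived independently in each wave, so pattern identity
across waves is nominal. `link_waves()` computes, for each consecutive
wave pair, the number of patients flowing from each source pattern to each
target pattern or to the absorbing **Death**/**Lost** nodes, plus a
long-run table linking baseline patterns directly to final-wave patterns
(with deaths/losses routed to the absorbing node of the first such event).
Conservation holds by construction — every non-absorbing node's outflow
equals its size — and the tests verify it exactly, along with the two-hop
consistency of the long-run table on patients observed at all waves.
`export_alluvial()` writes the flow table and draws an alluvial diagram
whose box heights and stripe widths are proportional to counts; it also
returns the node geometry so proportionality is checkable without reading
pixels.

### Association models

Mortality: a binary logistic regression of death-by-horizon on pattern
membership, adjusted for attained age (linear, in years) and sex, fitted
by IRLS via `stats::glm`. The reference pattern is the one with the lowest
crude mortality at the modelled horizon. Patients lost to follow-up by the
horizon are excluded from the denominators by default (they are missing
data, not survivors); a flag restores the treat-as-alive convention.
Confidence intervals are Wald on the log-odds scale, exp(β ± 1.96·SE).
Perfect separation is detected (a zero cell in the outcome × predictor
table) and reported as an error naming the separating variable rather than
returning divergent estimates.

Acute diseases: a multinomial logistic regression (via `nnet::multinom`)
with pattern membership as the outcome, the acute-disease indicator for
the preceding period as exposure, and age and sex as covariates; the
baseline category is the smallest pattern. With two patterns this reduces
to the binary logistic model, which the tests assert numerically. No
multiplicity correction is applied across acute-disease scans; outputs
flag the nominal 0.05 threshold.

Descriptive comparisons use Pearson's chi-squared (uncorrected — the
textbook statistic, so results match hand computation), one-way ANOVA and
pairwise t-tests with Bonferroni correction (adjusted α = 0.05/m for m
pairs). Zero-variance groups are flagged and skipped rather than producing
NaN statistics.

## The synthetic-cohort generator

No individual-level data from such cohorts can be redistributed, so the
package ships a generator (`simulate_cohort()`) whose output has the
statistical structure the analysis assumes:

* patients are drawn from `n_clusters` latent clinical profiles; baseline
  conditions are independent Bernoulli draws with per-profile prevalences
  (`prevalence_matrix`). The default plants disjoint blocks of 6
  conditions at prevalence 0.30 over a 0.012 background in a 130-category
  catalog, giving a realistic mean of roughly three chronic conditions per
  multimorbid patient;
* multimorbidity is enforced by rejection sampling (redraw until ≥ 2
  conditions), which is exact for the Bernoulli model and avoids
  conditioning formulas;
* per four-year period, death follows a logistic model in attained age,
  sex and cluster (`mortality_coefs`, log-odds units); loss to follow-up
  hits period survivors with probability `lost_rate`. Death is evaluated
  before loss, so the two are mutually exclusive within a period and both
  are absorbing;
* ages advance four years per wave; baseline ages are uniform on 18–65
  (real cohorts are not uniform in age, but the analysis only uses age as
  a linear covariate);
* surviving, still-included patients gain new conditions with per-period
  probabilities (`incidence_matrix` — a free modelling knob: incidence
  mechanisms are not identified by the cross-sectional design being
  emulated);
* acute diagnoses and dispensations are Poisson counts of events per
  period with labels/codes sampled *with replacement*, so the duplicate
  records that the deduplication rules exist for actually occur. Patients
  who die or are lost during a period contribute no events for it.

Identical configurations (including the seed) produce byte-identical
cohorts; the external CSV interchange (`write_cohort()`/`read_cohort()`)
round-trips exactly in a canonical row order.

What the generator deliberately does **not** emulate: real marginal
prevalences or their age/sex gradients, coded diagnosis vocabularies
(conditions are opaque labels), within-patient disease correlations beyond
the cluster structure, seasonality or care-seeking behaviour in acute
events. Tests passing on synthetic cohorts therefore demonstrate the
*correctness of the computations* and the recoverability of planted
structure — not that any particular clinical pattern will emerge from real
data.

## Numerical choices and defaults

* `kmeans_jaccard()`: `n_init = 10` seeded restarts (seeds `seed`,
  `seed+1`, … so the best-of-restarts objective is non-increasing as
  restarts are added), `max_iter = 100`, centroid-shift tolerance
  `tol = 1e-6`; convergence is declared at an assignment fixed point or
  when the largest centroid shift falls below `tol`. A seed is required —
  the package never consumes the global RNG stream silently.
* Assignment ties break to the lowest cluster index; with a fixed seed the
  whole fit is deterministic.
* Emptied clusters are re-seeded to the point farthest from its current
  centroid (never stealing a singleton's only member).
* Jaccard distance between two all-zero profiles is defined as 0
  (identical patients). This matters only before filtering, since
  multimorbid patients have at least two conditions.
* CH on a zero-within-dispersion partition returns `Inf` (a perfectly
  separated degenerate optimum); k < 2 is an error, not a score.
* Percentages in profile tables are printed to 2 decimals with
  half-away-from-zero rounding, the convention of printed clinical tables;
  cumulative attrition percentages use the baseline n as denominator,
  wave-level shares the wave n, per-pattern mortality the pattern size at
  the wave of assignment.
* Pipeline seed fan-out is counter-based
  (`(seed * 48271 + 1009 * stage) mod (2^31 - 1)`), so adding a stage
  never shifts another stage's random stream.

## Validation experiments

The acceptance suite (and `scripts/acceptance.R`) validates the pipeline
in two complementary ways, since the original individual-level data cannot
be redistributed: exact arithmetic reproduction of published
closed-cohort accounting and descriptive-table ratios from their printed
numerators and denominators, and property-based checks on planted
synthetic cohorts. Problem sizes were chosen once as part of the
experimental design:

* cluster recovery: 20 cohorts of n = 3,000 with three disjoint
  10-condition blocks at prevalence 0.9 over a 0.05 background —
  separation at which a correct implementation recovers the planted
  labels essentially perfectly (adjusted Rand ≥ 0.9) and selects k = 3;
* odds-ratio recovery: one cohort of n = 50,000 with a planted pattern
  log-odds of death of log(1.16). The death model for this experiment uses
  a moderate event rate and a flat age effect (intercept −1.3, 0.02 per
  year, −0.2 for women) so that the sampling standard deviation of the
  estimated log-OR (≈ 0.019) is small relative to the ±0.05 assessment
  band; a steeper age gradient would make the band narrower than the
  estimator's own noise and the experiment uninformative;
* interval calibration: 200 replicates of n = 1,500 under a null pattern
  effect, requiring Wald 95% intervals to cover OR = 1 at least 93% of
  the time;
* small-instance optimality: exhaustive enumeration of all labellings of
  9-point instances confirms the Lloyd solution attains the global
  optimum of the within-distance objective, and CH values match an
  independently coded formula to 1e-9.

## Known limitations

* k-means with Jaccard distance is a local optimiser; restarts mitigate
  but do not eliminate dependence on initialisation. The selection report
  exposes the full CH curve for human judgement.
* CH uses Euclidean dispersion while clustering uses Jaccard distance;
  the two usually agree on block-structured binary data but are not
  guaranteed to.
* Age enters the association models linearly; age-band dummies can be
  emulated by passing a recoded covariate, but the packaged interface is
  the linear term.
* The multinomial acute-disease scan is unadjusted for multiplicity, by
  design parity with the descriptive convention it mirrors; treat isolated
  significant ORs as hypothesis-generating.
* Mortality models exclude patients lost to follow-up rather than
  modelling competing risks; no survival-time information is used.
* Pattern identity across waves is nominal. Trajectory statements like "X%
  of pattern A evolved to pattern B" depend on per-wave re-clustering, not
  on a longitudinal model of transitions.
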