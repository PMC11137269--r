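# mmpatterns

Multimorbidity pattern discovery and trajectory analysis for
electronic-health-record cohorts.

Most adults living with chronic disease have more than one chronic
condition, and those conditions do not co-occur at random: populations
split into **multimorbidity patterns** — groups of patients with similar
clinical profiles — that evolve over time along distinct trajectories with
different mortality. `mmpatterns` implements the full analysis workflow
used in large closed-cohort EHR studies of this phenomenon, for
epidemiologists and biostatisticians who want a tested, reproducible and
scriptable version of it:

1. **Cohort construction** — long-format patient, diagnosis and
   dispensation tables; the multimorbidity filter (≥ 2 chronic
   conditions at baseline); per-wave binary disease matrices keeping
   conditions with prevalence ≥ 1.0%; closed-cohort attrition accounting
   with absorbing death / lost-to-follow-up states; deduplicated counting
   of drugs (distinct fourth-level ATC subgroups per follow-up period) and
   acute diseases (distinct conditions per period).
2. **Pattern discovery** — k-means clustering of the binary disease matrix
   under the Jaccard distance
   `d(x, c) = 1 − Σⱼ min(xⱼ, cⱼ) / Σⱼ max(xⱼ, cⱼ)`,
   with the number of patterns selected by the Caliński–Harabasz index
   `CH = [tr(B)/(k−1)] / [tr(W)/(n−k)]` subject to a validity rule: every
   pattern must contain at least one *essential* condition, i.e. one with
   prevalence ratio `PR = OP/EP ≥ 2.0` and observed prevalence
   `OP ≥ 10%`, or `OP ≥ 20%` and `PR ≥ 1.5`.
3. **Trajectories** — linkage of wave-specific patterns into per-patient
   flows with absorbing Death/Lost nodes, conservation-checked transition
   tables, and alluvial-diagram export.
4. **Associations** — age- and sex-adjusted logistic regression of
   mortality on pattern membership (reference = lowest-mortality pattern)
   and multinomial logistic regression of pattern membership on acute-
   disease exposure (reference = smallest pattern), reported as odds
   ratios with Wald 95% confidence intervals `exp(β ± 1.96·SE)`.
5. **Synthetic cohorts** — a planted-cluster Bernoulli-mixture generator
   that emulates the structure such studies assume (three waves, deaths,
   losses, incident conditions, repeated acute diagnoses and ATC-coded
   dispensations), so the whole pipeline is testable without access to
   restricted patient data.

## Worked example

```r
library(mmpatterns)

cfg    <- cohort_config(n_patients = 5000, seed = 2024)
cohort <- simulate_cohort(cfg)
cohort <- multimorbidity_filter(cohort)            # >= 2 chronic conditions
wave   <- build_wave(cohort, wave = 1, prevalence_threshold = 0.01)
fit    <- fit_patterns(wave, cohort = cohort, k_candidates = 2:5, seed = 2024)
print(fit)
#> Multimorbidity patterns, wave 2011: k = 3 over 5000 patients, 130 conditions
#>   pattern 1 (C018 & C016): n = 1697 (33.94%), 6 essential condition(s)
#>   pattern 2 (C012 & C008): n = 1627 (32.54%), 6 essential condition(s)
#>   pattern 3 (C004 & C006): n = 1676 (33.52%), 6 essential condition(s)
#> Calinski-Harabasz score: 354.188; total within-cluster Jaccard distance: 4474.7311
```

The generator planted three profiles; `fit_patterns()` selected `k = 3`
from the Caliński–Harabasz curve and recovered them. Each pattern is named
mechanically after its two most over-represented essential conditions
(`C018 & C016`: the conditions whose prevalence inside the pattern most
exceeds their population prevalence).

```r
mort <- fit_mortality_model(cohort, fit, horizon_wave = 3)
print(mort)
#> Age- and sex-adjusted association model
#>   outcome:   death by wave 3 (8y horizon) given pattern at wave 2011
#>   reference: pattern 1 (lowest crude mortality rate); n = 4821, events = 252
#>         term      OR (95% CI)        p
#>  (Intercept) 0.00 (0.00-0.00) 6.28e-77
#>          age 1.08 (1.07-1.10) 2.10e-36
#>       female 0.78 (0.60-1.02) 6.61e-02
#>     pattern2 1.18 (0.85-1.64) 3.15e-01
#>     pattern3 1.33 (0.96-1.83) 8.44e-02
#>     pattern1             ref.       NA
```

252 of the 4,821 patients still under follow-up died within eight years
(patients lost to follow-up are excluded); each year of age multiplies the
odds of death by 1.08, and patterns 2 and 3 show elevated but (at this
sample size) non-significant odds relative to the lowest-mortality
pattern. The closed-cohort bookkeeping is available directly:

```r
cohort_accounting(293923, deaths = c(4895, 5680), lost = c(10003, 2072))
#>   wave included cum_deaths cum_lost pct_dead pct_lost
#> 1    1   293923          0        0     0.00     0.00
#> 2    2   279025       4895    10003     1.67     3.40
#> 3    3   271273      10575    12075     3.60     4.11
```

An end-to-end run (generate → filter → cluster each wave → profile →
trajectories → associations, with all artifacts and a manifest) is:

```r
run_pipeline(list(seed = 1, out_dir = "out",
                  generator = list(n_patients = 5000)))
```

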