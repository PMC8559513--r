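# pathburden

Pathway mutation burden survival screening for chemotherapy-treated
cancer cohorts.

## The problem

In small-cell lung cancer (SCLC) treated with platinum–etoposide
chemotherapy, the somatic mutation *count* of a patient's tumor within a
biological pathway — for example the fatty-acid metabolism gene set — can
separate patients with better and worse prognosis.  The analysis pattern
is:

1. **Burden.** For every sample, count nonsilent somatic variants whose
   gene falls in each gene set of an MSigDB-style collection (C2/C5/H),
   giving a samples × gene-sets burden matrix, plus the per-sample tumor
   mutational burden (TMB).
2. **Grouping.** Split each burden column at the cohort median:
   *mut-high* = burden strictly above the median, *mut-low* otherwise, so
   `|mut-high| ≤ ⌊n/2⌋` always.
3. **Screen.** For each gene set, fit a univariate Cox
   proportional-hazards model of the group indicator against survival
   (PFS or OS): `h(t | z) = h₀(t) · exp(β z)`, `z = 1[mut-high]`, with
   the partial likelihood maximized by Newton–Raphson (Efron tie
   correction by default) and Wald inference
   `HR = exp(β̂)`, `CI = exp(β̂ ± z₀.₉₇₅ · se)`.
4. **Replicate.** Keep the gene sets significant (p < α) in *every*
   cohort with the same direction of effect (protective HR < 1
   everywhere, or risk HR > 1 everywhere) — replication across cohorts
   standing in for multiplicity control.
5. **Mechanism.** For the chosen pathway: TMB and per-gene
   mutation-frequency comparisons (Wilcoxon rank-sum, Fisher's exact),
   moderated-t differential expression, preranked GSEA
   (weighted-KS running sum, gene-label permutation null), ssGSEA-style
   per-sample pathway scores with their own survival analysis, lnIC50
   drug-response group tests, and a Connectivity-Map style two-tag KS
   drug score in [−1, 1] with a permutation p-value.

All of the survival machinery (Kaplan–Meier with log-log confidence
intervals, log-rank test, Cox Efron/Breslow partial likelihood) is
implemented in the package itself; `survival`, `limma` and `fgsea` are
used only as independent cross-checks in the test suite.  Because the
original patient-level cohort data are access-controlled, the package
ships a synthetic cohort generator with known ground truth (Poisson
per-gene mutation counts, Weibull survival with a group hazard ratio,
Gaussian expression with pathway mean shifts, lognormal IC50s) so every
stage is testable end to end and parameter recovery is measurable.

## Worked example

```r
library(pathburden)

cohort <- generate_cohort(synth_config(seed = 42))     # 100 samples, true HR 0.5
sets   <- generate_null_geneset_universe(100, sprintf("G%04d", 1:500),
                                         planted = cohort$truth$causal_set,
                                         seed = 43)
burden <- compute_burden(cohort$mutations, sets, cohort$roster)
rows   <- screen_cohort(burden, cohort$clinical, endpoint = "OS",
                        cohort_id = "synthA")
head(rows[order(rows$p), ], 3)
#>         set_name threshold n_high n_low        hr     lower     upper           p
#>       CAUSAL_SET         1     43    57 0.4090644 0.2394903 0.6987073 0.001065907
#>     NULL_SET_012         2     31    69 0.5201679 0.2995743 0.9031972 0.020253933
#>     NULL_SET_072         2     40    60 1.6565767 1.0133379 2.7081255 0.044135689
```

The planted causal pathway tops the screen: patients with more than one
mutation in it (the cohort median burden is 1) have an estimated hazard
ratio of 0.41 — mut-high is protective, as constructed (true HR 0.5).
The two chance findings among the 100 null sets illustrate why the
pipeline demands cross-cohort replication before believing a hit.

```r
grp <- dichotomize(burden[, "CAUSAL_SET"])
dat <- cohort$clinical; dat$group <- grp
cox_fit(dat, "group")
#> Cox proportional-hazards fit (efron ties), n = 100, events = 64
#>                  coef     se     HR  lower  upper      z        p
#> groupmut_high -0.8939 0.2731 0.4091 0.2395 0.6987 -3.273 0.001066

km_fit(dat$time, dat$event, grp)
#> Kaplan-Meier fit (2 group(s), 95% log-log CI)
#>     group  n events median    lower    upper
#>   mut_low 57     41  22.85 17.80434 28.02237
#>  mut_high 43     23  43.73 29.63628 75.33922
```

Median survival of 43.7 vs 22.9 months for the mut-high vs mut-low arm,
consistent with the fitted hazard ratio.  `concordance_filter()` combines
two or more such screens; `run_pipeline()` drives the full
discovery → verification → mechanism → drug workflow from one config
(see the methods vignette, `vignettes/pathway-burden-methods.Rmd`).

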