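---
title: "Methods: pathway mutation burden survival screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway mutation burden survival screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathburden)
```

This vignette is the package's own account of the statistics it
implements: the models, the defaults and why they were chosen, the
numerical details, and what the synthetic-data tests do and do not show
about real cohorts.

## The screening model

The unit of analysis is a cohort of tumor samples with somatic mutation
calls (MAF-style records), a survival endpoint (PFS or OS, months), and
a gene-set collection.  For sample $s$ and gene set $G$ the burden is

$$ b_{sG} \;=\; \#\{\text{nonsilent variant records of } s
   \text{ with gene} \in G\}, $$

counted per *variant* by default.  The alternative, counting distinct
mutated *genes*, is a first-class option (`mode = "genes"`): published
gene-level mutation tables collapse multiple hits per gene, and the two
conventions genuinely differ, so both are kept and recorded in the
burden matrix's metadata.  "Nonsilent" defaults to the protein-altering
MAF classes (missense, nonsense, nonstop, frameshift and in-frame
indels, splice site, translation start); the vocabulary is
configurable and unknown classes are flagged rather than dropped.

Grouping is a **median-strict split**: mut-high iff $b_{sG}$ strictly
exceeds the cohort median of column $G$.  The median itself always
falls in mut-low, so $|\text{mut-high}| \le \lfloor n/2\rfloor$, and a
column with constant burden degenerates to a single group (downstream
survival operations refuse such splits).  Each cohort is split at *its
own* median — the grouping rule transfers between cohorts, never the
numeric threshold, because background mutation rates differ by cohort
and platform.

Each split is tested with a univariate Cox proportional-hazards model,
$h(t \mid z) = h_0(t)\,e^{\beta z}$ with $z = 1[\text{mut-high}]$.  The
screen records, per gene set and cohort: the threshold, group sizes,
$\widehat{HR} = e^{\hat\beta}$, the Wald 95% CI, the two-sided Wald p,
and the direction $\mathrm{sign}(\hat\beta)$.  The **concordance
filter** then keeps the sets with $p < \alpha$ in *every* cohort and a
common direction, classifying them as protective ($HR < 1$ everywhere)
or risk ($HR > 1$ everywhere); sets significant everywhere with
opposite directions are reported separately as discordant.

No multiple-testing correction is applied across gene sets by default:
the design treats independent replication in a second cohort as the
false-positive control, which is the screen's defining logic.  This is
a real statistical caveat — at $\alpha = 0.05$ and ~15k sets, hundreds
of sets will pass in any single cohort by chance — so
`multiplicity_adjust(method = "bh")` is available when a per-cohort FDR
is wanted, and the global-null behaviour of the two-cohort filter
(about $\alpha^2/2$ expected survivors) is exercised in the tests.

## Cox partial likelihood

`cox_fit()` maximizes the log partial likelihood by Newton–Raphson with
step-halving.  With tied event times the Efron correction is the
default (Breslow is switchable); for an event block of size $d$ at one
time, with risk-set sums $S_0, S_1, S_2$ and event-only sums
$s_0^d, s_1^d, s_2^d$, the block contributes

$$ \sum_{i \in D} \eta_i - \sum_{l=0}^{d-1}
   \log\!\big(S_0 - \tfrac{l}{d}\,s_0^d\big), $$

and the score and observed information have closed forms in the scalar
sums $\sum_l 1/D_l$, $\sum_l \phi_l/D_l$, $\sum_l 1/D_l^2$, … with
$D_l = S_0 - \phi_l s_0^d$, $\phi_l = l/d$.  The implementation
evaluates all blocks at once through cumulative sums over the
time-sorted design and `rowsum()` over an expanded tie index, which is
what makes screening ~200 sets × 2 cohorts × dozens of replicates
affordable in pure R.

Numerical conventions:

* convergence when $\max_j |U_j| < 10^{-9}$ or the log-likelihood
  changes by less than $10^{-10}$; at most 50 iterations, with
  step-halving whenever a Newton step decreases the likelihood;
* a monotone likelihood (perfect separation) is detected by
  $|\hat\beta| > 15$, capped there, flagged on the object and warned
  about — the fit is reported rather than silently diverging, and the
  screen skips such sets as "unstable";
* Wald intervals use the exact normal quantile
  `qnorm(0.975)` $\approx 1.959964$, not the rounded 1.96, so
  "CI excludes 1" and "$p < 0.05$" agree exactly (a tested invariant);
* censored observations tied with an event time remain in the risk set
  for that event (the standard convention; matches `survival`).

Kaplan–Meier curves use the product-limit estimator with Greenwood
variance and **log-log** pointwise intervals
($S^{\exp(\pm z\,\hat\sigma)}$), the transform that keeps bounds inside
$(0,1)$; at $S = 0$ the interval is undefined and reported `NA`.  The
median is the smallest $t$ with $S(t) \le 0.5$ ("not reached" if never),
its CI the first crossings of the confidence bounds.  The log-rank test
uses the hypergeometric (tie-corrected) variance.  Both are
hand-implemented and cross-checked against `survival` in the tests to
within $10^{-10}$.

## Association tests

The clinical-balance conventions were chosen to reproduce baseline
tables as actually published in this literature: Pearson chi-square
with the *truncated* Yates correction
$\sum (\max(0, |O-E| - 0.5))^2/E$ for 2×2 tables (so a table with every
$|O-E| < 0.5$ gives statistic 0 and $p = 1$), uncorrected Pearson for
r×c tables, Wilcoxon rank-sum for continuous covariates.  Fisher's
exact test uses the probability-mass two-sided definition (sum of all
tables with fixed margins no more likely than the observed one, with a
$10^{-7}$ relative tolerance on the comparison), the convention under
which $[[1,0],[0,1]]$ gives $p = 1$; the reported odds ratio is the
sample OR by default with the conditional-MLE OR as an option.  The
Wilcoxon test is exact (full permutation null) when
$n_x n_y \le 400$ and there are no ties, otherwise normal with
tie-corrected variance and continuity correction; the effect summary is
the rank-biserial correlation.  These are thin wrappers over base R's
implementations of exactly these conventions; the test suite verifies
them against independent full-enumeration oracles rather than trusting
the wrapper.

Per-gene comparisons (`compare_top_genes()`) rank genes by overall
mutated-sample frequency, keep the top 20 (boundary ties all kept,
alphabetical), append pathway members above 5% overall frequency, and
test each gene's mutated × group 2×2 table with Fisher's exact test,
starring at 0.05 / 0.01 / 0.001 / 0.0001.

## Expression stages

**Moderated t.**  Per-gene two-group comparison with empirical-Bayes
variance shrinkage: $\tilde s_g^2 = (d_0 s_0^2 + d\,s_g^2)/(d_0 + d)$,
with the prior $(d_0, s_0^2)$ estimated by moment matching on
$\log s_g^2$ (digamma/trigamma identities; the trigamma inverse is
solved by Newton iteration).  The moderated $t$ is referred to
$d_0 + d$ degrees of freedom; $d_0 = 0$ recovers the ordinary t exactly
and $d_0 = \infty$ (which the estimator returns when the observed
log-variances are *less* dispersed than chi-square sampling noise
alone, as happens for homoscedastic simulated data) gives the fully
pooled z-test.  Zero-variance genes are flagged with $t = 0$, $p = 1$
and excluded from prior estimation.  The DE call defaults to
$p < 0.05$ and fold change > 2 — on the log2 scale the matrix is
assumed to be on, $|\mathrm{logFC}| > 1$.  The implementation is
verified against `limma::eBayes` ($d_0$, $s_0^2$, $t$ and $p$ to
$10^{-6}$) on heteroscedastic data.

**Preranked GSEA.**  Weighted-KS running sum over the ranking (by logFC
here; ties broken by gene label for determinism): hit increments
$\propto |r|^w$ normalized over the set, miss decrements uniform over
the complement, ES = the signed peak deviation, so ES ∈ [−1, 1] always
and a set occupying the top ranks attains exactly 1.  Defaults: weight
1, set-size bounds 5–500 ranked members.  The null permutes *gene
labels* (equivalently redraws the set's positions), the only null
available to a preranked analysis; with $B$ permutations,
$p = (1 + \#\{|ES^\pi| \ge |ES|\})/(1 + B) \in [1/(B+1), 1]$, and
NES divides ES by the mean $|ES^\pi|$ of same-sign permutations
(`NA` if no permutation shares the sign).  $B = 1000$ by default,
seeded, bit-reproducible.

**ssGSEA.**  Per-sample scores use the rank-ECDF formulation: genes
ranked by expression within the sample, score = integrated difference
between the $\text{rank}^{\alpha}$-weighted in-set ECDF and the uniform
out-of-set ECDF, $\alpha = 0.25$; optional normalization by the global
max − min of the score matrix.  This variant was chosen over the
kernel-density GSVA estimator deliberately: it is rank-based (hence
invariant under any monotone per-sample transform — a tested
invariant), deterministic, and hand-checkable on a 5-gene example.
Scores feed a per-set two-sample t between burden groups (pooled
variance by default, Welch optional) and a median-split survival
analysis reusing the same machinery as the mutation screen.

## Connectivity scoring

A query signature (up- and down-regulated tag lists) is scored against
each reference instance — a column of ranks $1..n$ (1 = most
up-regulated) — with the two-sided tag KS statistic
$a = \max_i(i/t - V_i/n)$, $b = \max_i(V_i/n - (i-1)/t)$,
$ks = a$ if $a \ge b$ else $-b$ (the $a = b$ tie resolves to the
positive side; note the statistic is *not* exactly mirror-symmetric —
tags occupying the top $t$ ranks give $a = 1 - t/n$ while tags at the
bottom give $-b = -(1 - (t-1)/n)$, one rank-width larger in
magnitude).  The
raw connectivity is $s = ks_{up} - ks_{down}$ when the two disagree in
sign, else 0; scaling divides positive $s$ by the maximum positive $s$
and negative $s$ by $|\min s|$, pinning the extremal instances to ±1.
The permutation p draws size-matched random disjoint tag sets; because
every reference column is a permutation of $1..n$, one batch of null
draws serves all instances.  Per-compound aggregation takes the most
extreme instance score by default (mean optional), and the MoA summary
counts compounds passing $(|score| > 0.8, p < 0.05)$ per mechanism
class, positive and negative connections separately.  Feature space is
gene symbols; mapping to array probes is upstream of this package.

## The synthetic cohort generator

`generate_cohort()` draws, from a single master seed with per-table
substreams (so resizing one table never perturbs another):

* per-gene background rates $\lambda_g \sim$ lognormal(median 0.025,
  sdlog 1) over a 500-gene universe, per-sample counts
  $\sim$ Poisson$(\lambda_g)$ — with the 40-gene causal set this puts
  the causal burden median at 1–2, matching the medians the clinical
  cohorts this design emulates actually exhibit, and mut-high fractions
  of roughly 35–45%;
* survival from a Weibull baseline (shape 1.2, median 20 months —
  an OS scale typical of extensive-stage SCLC on chemotherapy) with the
  hazard multiplied by $e^\beta$ for mut-high samples, $\beta = \log
  0.5$ by default; censoring is administrative-uniform on $[0, c_{max}]$
  with $c_{max}$ solved numerically (integrating the marginal survival
  function) to hit a 30% target fraction;
* expression $\sim N(0,1)$ on the log scale with a $+1$ SD shift on
  causal-set genes in mut-high samples; lnIC50
  $\sim N(\mu_d, 1)$ with a $+1$ shift for mut-low lines on a subset of
  drugs (mut-low less drug-sensitive).

What it deliberately does **not** model: mutational signatures, gene
length and replication-timing covariates, expression–mutation eQTL
coupling, overdispersion beyond Poisson, informative censoring, or
cohort batch structure.  Passing tests on this generator therefore
demonstrate that the *estimators* recover the *generating model's*
parameters — hazard ratios within ±0.08 of truth on the log scale, Wald
coverage near 0.95, planted screen hits recovered far above the
$\sim\alpha^2/2$ null rate — not that the biological conclusions about
any real cohort are correct.  Real-data behaviour additionally depends
on everything the generator idealizes away.

A note on screen power: requiring $p < 0.05$ in each of two cohorts
multiplies the per-cohort powers.  With ~70 observed events per
100-patient cohort (30% censoring) and the realistic 35–45% mut-high
fraction, the per-cohort Wald power for a hazard ratio of 0.45 is about
0.85–0.90, so two-cohort recovery sits near 0.75 rather than near 1 —
the replication requirement buys its false-positive control with real
sensitivity, which is worth knowing before running the design on a
cohort of this size.

## Problem sizes and runtime choices

The shipped studies use: 200 synthetic cohorts (n = 100) for parameter
recovery; 50 two-cohort replicates of a 201-set screen for recovery and
20 permuted screens for the global null; 1000 permutations for GSEA and
connectivity p-values.  These sizes give Monte-Carlo standard errors
well below the decision margins they feed (e.g. ±0.015 on a 0.95
coverage estimate) while keeping a full run in the minutes range on one
CPU; they are set in `scripts/acceptance.R` and the test files, not
baked into the package.

## Known limitations

* Symbol harmonization is uppercase + trim only; no alias mapping, so
  gene-set and mutation tables from different annotation eras must be
  harmonized upstream.
* TMB is a raw nonsilent count by default (per-megabase available via
  `exome_size_mb`); cross-platform TMB comparisons need the latter.
* The Cox machinery is right-censoring only: no time-varying
  covariates, frailty, competing risks, or proportional-hazards
  diagnostics.
* The screen's default of no multiplicity correction is faithful to the
  replication design but places all error control on the second cohort;
  use the BH option when screening a single cohort.
* Overlapping gene sets are screened independently and not
  deduplicated, so concordant hits can be near-duplicates of one
  another.
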