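Package: pathburden
Title: Pathway Mutation Burden Survival Screening for Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening gene-set (pathway) somatic mutation burden
    against survival in chemotherapy-treated cancer cohorts.  Per-sample
    gene-set mutation counts and tumor mutational burden are computed from
    MAF-style mutation tables, samples are split at the cohort median into
    mut-high and mut-low groups, and every gene set in an MSigDB-style GMT
    collection is screened with univariate Cox proportional-hazards models
    (Efron or Breslow ties, implemented from the partial likelihood) with a
    cross-cohort concordance filter.  Downstream mechanism stages include
    per-gene Fisher comparisons of mutation frequency, moderated-t
    differential expression, preranked GSEA, single-sample gene-set (ssGSEA)
    scoring, connectivity-map style two-tag KS drug scoring, and drug
    response (lnIC50) group tests.  A synthetic cohort generator with known
    ground truth (Poisson mutation counts, Weibull survival with a group
    hazard ratio, Gaussian expression with pathway shifts, lognormal IC50s)
    supports end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), survival, limma, fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
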