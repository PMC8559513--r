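# Two-group association tests used across the pipeline: Fisher's exact
# test for per-gene mutation frequencies, Pearson chi-square (with the
# truncated Yates correction for 2x2 tables) for clinical balance tables,
# and the Wilcoxon rank-sum test for continuous comparisons.

test_result <- function(statistic, p, method, effect = NULL,
                        effect_name = NULL) {
  structure(list(statistic = statistic, p.value = p, method = method,
                 effect = effect, effect_name = effect_name),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(x$method, ": p = ", format.pval(x$p.value, digits = 4), sep = "")
  if (!is.null(x$effect)) {
    cat(", ", x$effect_name, " = ", format(x$effect, digits = 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

as_2x2 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == 2L))
  } else {
    stopifnot(length(x) == 4L)
    x <- matrix(x, 2L, 2L, byrow = TRUE)
  }
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("empty table")
  x
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass convention: the sum of
#' hypergeometric probabilities (fixed margins) of every table at most as
#' likely as the observed one, so `[[1,0],[0,1]]` gives p = 1.  The
#' reported effect is the sample odds ratio by default; the conditional
#' MLE odds ratio is available.
#'
#' @param x 2x2 matrix, or length-4 vector `c(a, b, c, d)` filled by row.
#' @param or_type `"sample"` (ad/bc, default) or `"cmle"`.
#' @return An `"assoc_test"` with `p.value` and odds-ratio `effect`.
#' @export
fisher_exact <- function(x, or_type = c("sample", "cmle")) {
  or_type <- match.arg(or_type)
  x <- as_2x2(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    warning("zero margin: p = 1 by convention")
    return(test_result(NA_real_, 1, "Fisher's exact test",
                       NA_real_, "odds ratio"))
  }
  ft <- stats::fisher.test(x)
  or <- if (or_type == "sample") {
    (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  } else {
    unname(ft$estimate)
  }
  test_result(NA_real_, ft$p.value, "Fisher's exact test", or, "odds ratio")
}

#' Pearson chi-square test for an r x c table
#'
#' `correction = "yates"` (2x2 only) uses the truncated continuity
#' correction `sum((max(0, |O - E| - 0.5))^2 / E)`, which sends the
#' statistic to zero when every `|O - E| < 0.5`; `"auto"` applies Yates
#' for 2x2 tables and no correction otherwise -- the convention that
#' reproduces standard clinical baseline tables.
#'
#' @param x contingency matrix (or length-4 vector for 2x2, filled by row).
#' @param correction `"auto"`, `"yates"` or `"none"`.
#' @return An `"assoc_test"` with the chi-square `statistic` and `p.value`.
#' @export
chi2_test <- function(x, correction = c("auto", "yates", "none")) {
  correction <- match.arg(correction)
  if (!is.matrix(x)) x <- as_2x2(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("zero row or column margin")
  }
  is2x2 <- all(dim(x) == 2L)
  if (correction == "yates" && !is2x2) {
    stop("Yates correction applies to 2x2 tables only")
  }
  correct <- switch(correction, auto = is2x2, yates = TRUE, none = FALSE)
  ct <- suppressWarnings(stats::chisq.test(x, correct = correct))
  test_result(unname(ct$statistic), unname(ct$p.value),
              paste0("Pearson chi-square",
                     if (correct) " (Yates)" else ""))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties; exact permutation null when `n_x * n_y <= 400` and
#' there are no ties, otherwise the normal approximation with
#' tie-corrected variance and continuity correction.  Two-sided.  The
#' effect summary is the rank-biserial correlation `2 U / (n_x n_y) - 1`.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"` (default rule above), `"exact"` or `"normal"`.
#' @return An `"assoc_test"` with the Mann-Whitney `U` statistic (pairs
#'   where `x > y`, ties counted half), `p.value` and rank-biserial effect.
#' @export
wilcoxon_ranksum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical; p = 1")
    return(test_result(length(x) * length(y) / 2, 1,
                       "Wilcoxon rank-sum test", 0, "rank-biserial"))
  }
  exact <- switch(mode,
                  auto = length(x) * length(y) <= 400 && !ties,
                  exact = TRUE, normal = FALSE)
  if (exact && ties) stop("exact mode is unavailable with ties")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  u <- unname(wt$statistic)
  rb <- 2 * u / (length(x) * length(y)) - 1
  test_result(u, wt$p.value,
              paste0("Wilcoxon rank-sum test (",
                     if (exact) "exact" else "normal", ")"),
              rb, "rank-biserial")
}

#' Per-gene mutation-frequency comparison between burden groups
#'
#' Ranks genes by overall mutated-sample frequency, keeps the top `top_k`
#' (frequency ties at the boundary all kept, alphabetical order), appends
#' any `extra_genes` whose overall frequency exceeds `extra_min_freq`, and
#' tests each gene's mutated/not x mut-high/mut-low 2x2 table with
#' Fisher's exact test.  Significance tiers: `*` p<0.05, `**` p<0.01,
#' `***` p<0.001, `****` p<0.0001.
#'
#' @param mutations a [mutation_table()].
#' @param groups a [dichotomize()] factor named by sample; its names are
#'   the cohort roster.
#' @param top_k number of top-mutated genes.
#' @param extra_genes genes (e.g. a pathway's members) appended when their
#'   overall frequency exceeds `extra_min_freq`.
#' @param extra_min_freq overall-frequency threshold for `extra_genes`.
#' @param class_filter variant classes that count as a mutated gene.
#' @return `data.frame`: per gene, mutated-sample counts and frequencies
#'   per group, overall frequency, Fisher p and `stars`.
#' @export
compare_top_genes <- function(mutations, groups, top_k = 20L,
                              extra_genes = NULL, extra_min_freq = 0.05,
                              class_filter = nonsilent_classes()) {
  stopifnot(inherits(mutations, "mutation_table"), top_k >= 1L)
  roster <- names(groups)
  if (is.null(roster)) stop("groups must be named by sample id")
  rec <- mutations
  if (!is.null(class_filter)) {
    rec <- rec[rec$variant_class %in% class_filter, , drop = FALSE]
  }
  rec <- rec[rec$sample_id %in% roster, , drop = FALSE]
  if (!nrow(rec)) stop("no mutation records for the roster")
  rec <- rec[!duplicated(rec[c("sample_id", "gene")]), , drop = FALSE]
  freq <- table(rec$gene) / length(roster)
  ranked <- names(sort(freq, decreasing = TRUE))
  # keep all genes tied with the top_k-th frequency, alphabetical order
  if (length(ranked) > top_k) {
    cut <- sort(freq, decreasing = TRUE)[top_k]
    keep <- names(freq)[freq >= cut]
  } else {
    keep <- ranked
  }
  extra <- normalize_symbols(extra_genes)
  extra <- extra[extra %in% names(freq)[freq > extra_min_freq]]
  genes <- sort(unique(c(keep, extra)))
  high <- roster[groups == "mut_high"]
  low <- roster[groups == "mut_low"]
  out <- do.call(rbind, lapply(genes, function(g) {
    mut_samples <- unique(rec$sample_id[rec$gene == g])
    a <- sum(high %in% mut_samples); b <- length(high) - a
    c_ <- sum(low %in% mut_samples); d <- length(low) - c_
    p <- suppressWarnings(fisher_exact(matrix(c(a, b, c_, d), 2L,
                                              byrow = TRUE))$p.value)
    data.frame(gene = g, n_high_mut = a, n_low_mut = c_,
               freq_high = a / length(high), freq_low = c_ / length(low),
               freq_overall = unname(freq[g]), p = p,
               stars = stars_for(p), stringsAsFactors = FALSE)
  }))
  out[order(-out$freq_overall, out$gene), ]
}

stars_for <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Clinical balance table between burden groups
#'
#' Baseline-characteristics style comparison: continuous covariates by the
#' Wilcoxon rank-sum test, categorical covariates by Pearson chi-square
#' (Yates-corrected for 2x2, uncorrected otherwise).
#'
#' @param clinical a [clinical_table()].
#' @param groups a [dichotomize()] factor named by sample id.
#' @param covariates covariate column names; defaults to every column
#'   beyond `sample_id`, `time`, `event`.
#' @return `data.frame` with one row per covariate: test used and p-value.
#' @export
clinical_balance <- function(clinical, groups, covariates = NULL) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (is.null(covariates)) {
    covariates <- setdiff(names(clinical), c("sample_id", "time", "event"))
  }
  g <- groups[match(clinical$sample_id, names(groups))]
  out <- lapply(covariates, function(v) {
    x <- clinical[[v]]
    ok <- !is.na(x) & !is.na(g)
    if (is.numeric(x)) {
      tr <- wilcoxon_ranksum(x[ok & g == "mut_high"], x[ok & g == "mut_low"])
    } else {
      tab <- table(x[ok], droplevels(g[ok]))
      tr <- chi2_test(as.matrix(tab), correction = "auto")
    }
    data.frame(covariate = v, method = tr$method, p = tr$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
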