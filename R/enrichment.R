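# Expression-side mechanism stages: empirical-Bayes moderated-t
# differential expression, preranked GSEA with a gene-label permutation
# null, single-sample (ssGSEA-style) pathway scoring, pathway-score
# survival analysis and differential pathway expression.

# Newton inversion of the trigamma function (for the prior-df estimate)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderated-t differential expression between burden groups
#'
#' Per-gene two-group comparison on a log-scale expression matrix with
#' empirical-Bayes variance shrinkage: residual variances are shrunk to
#' the posterior `(d0 s0^2 + d s^2) / (d0 + d)` with the prior
#' `(d0, s0^2)` estimated by moment matching on `log s^2` (digamma /
#' trigamma method), and the moderated t referred to `d0 + d` degrees of
#' freedom.  As `d0 -> 0` the ordinary two-sample t is recovered.
#'
#' @param expr numeric matrix genes x samples, log2 scale.
#' @param groups factor named by sample with levels `mut_low`, `mut_high`
#'   (as from [dichotomize()]).
#' @param prior_df optional fixed prior degrees of freedom `d0`
#'   (overrides estimation; `0` gives the ordinary t, `Inf` fully pooled).
#' @param p_cut,lfc_cut thresholds for the `de_call` column
#'   (fold change > 2 on the log2 scale means `|logFC| > 1`).
#' @return `data.frame` per gene: `logFC` (mut_high - mut_low), moderated
#'   `t`, `df`, `p`, BH-adjusted `q`, `de_call`, `zero_variance` flag;
#'   attributes `d0` and `s02`.
#' @export
dge_moderated_t <- function(expr, groups, prior_df = NULL,
                            p_cut = 0.05, lfc_cut = 1) {
  groups <- groups[match(colnames(expr), names(groups))]
  if (anyNA(groups)) stop("every expression sample needs a group label")
  hi <- groups == "mut_high"; lo <- groups == "mut_low"
  n1 <- sum(hi); n2 <- sum(lo)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  m1 <- rowMeans(expr[, hi, drop = FALSE])
  m2 <- rowMeans(expr[, lo, drop = FALSE])
  logfc <- m1 - m2
  d <- n1 + n2 - 2L
  ss <- (rowSums((expr[, hi, drop = FALSE] - m1)^2) +
           rowSums((expr[, lo, drop = FALSE] - m2)^2)) / d
  zerov <- ss <= 0
  # prior estimated from genes with positive variance
  z <- log(ss[!zerov])
  e <- z - digamma(d / 2) + log(d / 2)
  if (is.null(prior_df)) {
    evar <- stats::var(e) - trigamma(d / 2)
    d0 <- if (is.na(evar) || evar <= 0) Inf else 2 * trigamma_inverse(evar)
  } else {
    d0 <- prior_df
  }
  s02 <- if (is.infinite(d0)) {
    exp(mean(e))
  } else if (d0 == 0) {
    NA_real_
  } else {
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  stilde2 <- if (d0 == 0) ss else if (is.infinite(d0)) {
    rep(s02, length(ss))
  } else {
    (d0 * s02 + d * ss) / (d0 + d)
  }
  df_mod <- if (is.infinite(d0)) Inf else d0 + d
  tval <- logfc / sqrt(stilde2 * (1 / n1 + 1 / n2))
  p <- if (is.infinite(df_mod)) {
    2 * stats::pnorm(-abs(tval))
  } else {
    2 * stats::pt(-abs(tval), df = df_mod)
  }
  tval[zerov] <- 0; p[zerov] <- 1
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(expr), logFC = logfc, t = tval,
                    df = df_mod, p = p, q = q,
                    de_call = p < p_cut & abs(logfc) > lfc_cut,
                    zero_variance = zerov, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, d0 = d0, s02 = s02)
}

# weighted KS running-sum enrichment score for hit positions in a ranked
# list; returns the signed peak deviation and its position
gsea_es <- function(hit, absw) {
  nr <- sum(absw[hit])
  n <- length(hit)
  n_miss <- n - sum(hit)
  incr <- ifelse(hit, absw / nr, -1 / n_miss)
  run <- cumsum(incr)
  i <- which.max(abs(run))
  list(es = run[i], peak = i, run = run)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score over a ranked
#' gene list (hit steps proportional to `|score|^weight`, miss steps
#' uniform over the complement), with a gene-label permutation null: each
#' permutation redraws the set's positions in the fixed ranking.
#' `p = (1 + #{|ES_perm| >= |ES|}) / (1 + n_perm)`; NES divides ES by the
#' mean `|ES_perm|` of permutations with matching sign.
#'
#' @param ranking named numeric vector, gene -> ranking score (e.g. logFC);
#'   no duplicate names.  Ties are ordered by gene label for determinism.
#' @param sets a [gene_set_collection()] or named list.
#' @param n_perm permutations per set.
#' @param weight exponent on `|score|` for hit increments (0 = classic KS).
#' @param min_size,max_size ranked-member count bounds; sets outside are
#'   skipped.
#' @param seed RNG seed for the permutation null.
#' @return `data.frame` per retained set: `set_name`, `size`, `es`, `nes`,
#'   `p`, `leading_edge` (comma-separated genes up to / from the peak).
#' @export
gsea_preranked <- function(ranking, sets, n_perm = 1000L, weight = 1,
                           min_size = 5L, max_size = 500L, seed = NULL) {
  if (is.null(names(ranking)) || anyDuplicated(names(ranking))) {
    stop("ranking must be named with unique genes")
  }
  if (!is.null(seed)) set.seed(seed)
  ord <- order(-ranking, names(ranking), method = "radix")
  genes <- names(ranking)[ord]
  score <- ranking[ord]
  n <- length(genes)
  absw <- abs(score)^weight
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], genes)
    t <- length(members)
    if (t < min_size || t > max_size) return(NULL)
    if (t == n) stop("gene set '", nm, "' covers the whole ranking")
    hit <- genes %in% members
    obs <- gsea_es(hit, absw)
    perm_es <- vapply(seq_len(n_perm), function(b) {
      ph <- logical(n)
      ph[sample.int(n, t)] <- TRUE
      gsea_es(ph, absw)$es
    }, 1)
    p <- (1 + sum(abs(perm_es) >= abs(obs$es))) / (1 + n_perm)
    same <- perm_es[sign(perm_es) == sign(obs$es)]
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    le <- if (obs$es >= 0) {
      genes[seq_len(obs$peak)][hit[seq_len(obs$peak)]]
    } else {
      genes[obs$peak:n][hit[obs$peak:n]]
    }
    data.frame(set_name = nm, size = t, es = obs$es, nes = nes, p = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no gene set within the size bounds")
  rownames(out) <- NULL
  out
}

#' Single-sample gene-set scores (ssGSEA-style)
#'
#' Rank-based per-sample pathway scores: within each sample, genes are
#' ranked by expression; the score is the integrated difference between
#' the weighted in-set rank ECDF (weights `rank^alpha`) and the uniform
#' out-of-set ECDF, walked from the most- to the least-expressed gene.
#' Being rank-based, scores are invariant to any monotone transform of a
#' sample's expression values, and to set members absent from the matrix.
#'
#' @param expr numeric matrix genes x samples.
#' @param sets [gene_set_collection()] or named list.
#' @param alpha rank-weighting exponent.
#' @param normalize divide all scores by the overall `max - min`.
#' @param min_overlap minimum expressed members; smaller sets are skipped
#'   with a warning.
#' @return Matrix gene sets x samples, attribute `method = "ssgsea"`.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25, normalize = TRUE,
                         min_overlap = 2L) {
  genes <- rownames(expr)
  keep <- vapply(sets, function(s) sum(s %in% genes) >= min_overlap, TRUE)
  if (any(!keep)) {
    warning("skipping ", sum(!keep),
            " set(s) with < ", min_overlap, " expressed members")
  }
  sets <- sets[keep]
  if (!length(sets)) stop("no gene set overlaps the expression matrix")
  n <- length(genes)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  member <- lapply(sets, function(s) genes %in% s)
  for (j in seq_len(ncol(expr))) {
    rk <- rank(expr[, j], ties.method = "average")   # n = most expressed
    ord <- order(-rk)                                # walk top-down
    w <- rk[ord]^alpha
    for (i in seq_along(sets)) {
      inset <- member[[i]][ord]
      ecdf_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
      ecdf_out <- cumsum(!inset) / (n - sum(inset))
      out[i, j] <- sum(ecdf_in - ecdf_out)
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  structure(out, method = "ssgsea", alpha = alpha)
}

#' Survival analysis of a per-sample pathway score
#'
#' Median-strict split of the chosen pathway score (higher-than-median =
#' `mut_high`-analogous "score-high" arm) followed by Kaplan-Meier curves
#' and a univariate Cox fit of the score group.
#'
#' @param scores matrix from [ssgsea_score()] (gene sets x samples).
#' @param clinical a [clinical_table()] matched by sample id.
#' @param set_name row of `scores` to analyse.
#' @return list with `groups`, the two-arm `km` ([km_fit()]) and `cox`
#'   ([cox_fit()]; HR is score-high vs score-low).
#' @export
pathway_score_survival <- function(scores, clinical, set_name) {
  if (!set_name %in% rownames(scores)) {
    stop("set '", set_name, "' not in the score matrix")
  }
  shared <- intersect(colnames(scores), clinical$sample_id)
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  s <- scores[set_name, shared]
  grp <- dichotomize(s)
  if (any(table(grp) == 0L)) stop("degenerate split of the pathway score")
  dat <- cl
  dat$group <- grp
  list(groups = grp,
       km = km_fit(cl$time, cl$event, grp),
       cox = cox_fit(dat, "group"))
}

#' Differential pathway expression between burden groups
#'
#' Per-set two-sample t-test of ssGSEA-style scores between mut-high and
#' mut-low samples (pooled variance by default, Welch optional), with BH
#' adjustment across sets.
#'
#' @param scores matrix gene sets x samples.
#' @param groups factor named by sample (levels `mut_low`, `mut_high`).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return `data.frame` per set: group means, `diff` (high - low), `t`,
#'   `df`, `p`, `q`.
#' @export
diff_pathway_expression <- function(scores, groups, var_equal = TRUE) {
  g <- groups[match(colnames(scores), names(groups))]
  if (anyNA(g)) stop("every scored sample needs a group label")
  if (min(table(g)) < 2L) stop("need at least 2 samples per group")
  rows <- lapply(rownames(scores), function(nm) {
    hi <- scores[nm, g == "mut_high"]; lo <- scores[nm, g == "mut_low"]
    if (stats::sd(c(hi, lo)) == 0) {
      return(data.frame(set_name = nm, mean_high = mean(hi),
                        mean_low = mean(lo), diff = 0, t = 0,
                        df = length(c(hi, lo)) - 2, p = 1,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(hi, lo, var.equal = var_equal)
    data.frame(set_name = nm, mean_high = mean(hi), mean_low = mean(lo),
               diff = mean(hi) - mean(lo), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
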