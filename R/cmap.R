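# Connectivity-map style two-tag KS drug scoring against a reference
# matrix of per-instance gene ranks, with a size-matched random-tag
# permutation p-value and mechanism-of-action aggregation.

#' Two-sided KS statistic for a tag set in a ranked list
#'
#' For `t` tag positions `V(1) < ... < V(t)` among `n` ranked features:
#' `a = max_i (i/t - V(i)/n)`, `b = max_i (V(i)/n - (i-1)/t)`; the score
#' is `a` if `a >= b`, else `-b` (ties resolve to the positive side).
#' Positive means the tags concentrate at the top of the list.
#'
#' @param positions integer ranks of the tags (1 = most up-regulated),
#'   distinct, in `1..n`.
#' @param n number of ranked features.
#' @return KS score in `[-1, 1]`.
#' @export
ks_tag_score <- function(positions, n) {
  t <- length(positions)
  if (t == 0L || t >= n) stop("need 1 <= t < n tag positions")
  v <- sort(positions)
  if (anyDuplicated(v) || v[1L] < 1 || v[t] > n) {
    stop("positions must be distinct ranks in 1..n")
  }
  i <- seq_len(t)
  a <- max(i / t - v / n)
  b <- max(v / n - (i - 1) / t)
  if (a >= b) a else -b
}

#' Connectivity score of an up/down tag signature against reference ranks
#'
#' Per reference instance: `ks_up` and `ks_down` from the two tag lists;
#' the raw connectivity `s = ks_up - ks_down` when the two have opposite
#' signs, else 0.  Scaled scores divide positive `s` by the maximum
#' positive `s` over instances and negative `s` by `|min s|`, so the
#' extremal instances sit at +1 / -1.  The permutation p per instance
#' draws `n_perm` random disjoint tag sets of the same sizes and uses
#' `p = (1 + #{|s_perm| >= |s|}) / (1 + n_perm)`.
#'
#' @param up_tags,down_tags disjoint gene-symbol vectors; tags absent from
#'   the reference features are dropped with a warning.
#' @param refs integer matrix features x instances; each column is a
#'   permutation of `1..n_features` (1 = most up-regulated).
#' @param meta optional data.frame of instance metadata with columns
#'   `instance`, `compound` (and optionally `moa`), matched to `colnames(refs)`.
#' @param n_perm random tag-set draws for the null.
#' @param seed RNG seed.
#' @param compound_agg per-compound aggregation of scaled scores:
#'   `"extreme"` (largest absolute, default) or `"mean"`.
#' @return Object of class `"connectivity_result"`: per-instance table
#'   (`ks_up`, `ks_down`, `s`, `score`, `p`), per-compound table.
#' @export
connectivity_score <- function(up_tags, down_tags, refs, meta = NULL,
                               n_perm = 1000L, seed = NULL,
                               compound_agg = c("extreme", "mean")) {
  compound_agg <- match.arg(compound_agg)
  up_tags <- unique(normalize_symbols(up_tags))
  down_tags <- unique(normalize_symbols(down_tags))
  if (length(intersect(up_tags, down_tags))) {
    stop("up and down tags must be disjoint")
  }
  feats <- rownames(refs)
  if (is.null(feats)) stop("reference matrix needs feature rownames")
  n <- nrow(refs)
  up <- intersect(up_tags, feats)
  dn <- intersect(down_tags, feats)
  dropped <- length(up_tags) + length(down_tags) - length(up) - length(dn)
  if (dropped) warning(dropped, " tag(s) absent from the reference features")
  if (!length(up) || !length(dn)) {
    stop("no mapped tags of one or both signs")
  }
  if (!is.null(seed)) set.seed(seed)

  inst_s <- vapply(seq_len(ncol(refs)), function(j) {
    ku <- ks_tag_score(refs[up, j], n)
    kd <- ks_tag_score(refs[dn, j], n)
    c(ku, kd, if (sign(ku) == sign(kd)) 0 else ku - kd)
  }, numeric(3))
  ks_up <- inst_s[1L, ]; ks_down <- inst_s[2L, ]; s <- inst_s[3L, ]

  # size-matched random-tag null; the rank columns are exchangeable
  # permutations of 1..n, so one draw of nulls serves every instance
  perm_s <- vapply(seq_len(n_perm), function(b) {
    pos <- sample.int(n, length(up) + length(dn))
    ku <- ks_tag_score(pos[seq_along(up)], n)
    kd <- ks_tag_score(pos[length(up) + seq_along(dn)], n)
    if (sign(ku) == sign(kd)) 0 else ku - kd
  }, 1)
  p <- vapply(s, function(si) (1 + sum(abs(perm_s) >= abs(si))) / (1 + n_perm),
              1)

  score <- s
  if (any(s > 0)) score[s > 0] <- s[s > 0] / max(s)
  if (any(s < 0)) score[s < 0] <- s[s < 0] / abs(min(s))

  inst <- data.frame(instance = colnames(refs),
                     ks_up = ks_up, ks_down = ks_down,
                     s = s, score = score, p = p, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    m <- meta[match(inst$instance, meta$instance), , drop = FALSE]
    inst$compound <- m$compound
  } else {
    inst$compound <- inst$instance
  }
  agg <- do.call(rbind, lapply(split(inst, inst$compound), function(d) {
    sc <- if (compound_agg == "extreme") {
      d$score[which.max(abs(d$score))]
    } else {
      mean(d$score)
    }
    data.frame(compound = d$compound[1L], score = sc, p = min(d$p),
               n_instances = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(instances = inst, compounds = agg,
                 n_up = length(up), n_down = length(dn),
                 n_perm = n_perm, compound_agg = compound_agg),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat("Connectivity scores: ", nrow(x$instances), " instances, ",
      nrow(x$compounds), " compounds (", x$n_up, " up / ", x$n_down,
      " down tags, ", x$n_perm, " permutations)\n", sep = "")
  top <- x$compounds[order(-abs(x$compounds$score)), ]
  print(utils::head(top, 10), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Aggregate connectivity hits by mechanism of action
#'
#' Counts, per MoA, the compounds passing `score > score_cut, p < p_cut`
#' (positive connections) and `score < -score_cut, p < p_cut` (negative)
#' separately.  Compounds without an annotation fall in `"unannotated"`.
#'
#' @param results a [connectivity_score()] result.
#' @param moa_table data.frame with columns `compound` and `moa`.
#' @param score_cut,p_cut selection thresholds.
#' @return `data.frame` per MoA: `n_positive`, `n_negative`, and the
#'   passing compound names.
#' @export
moa_aggregate <- function(results, moa_table, score_cut = 0.8,
                          p_cut = 0.05) {
  stopifnot(inherits(results, "connectivity_result"))
  d <- results$compounds
  d$moa <- moa_table$moa[match(d$compound, moa_table$compound)]
  d$moa[is.na(d$moa)] <- "unannotated"
  pos <- d[d$score > score_cut & d$p < p_cut, ]
  neg <- d[d$score < -score_cut & d$p < p_cut, ]
  moas <- sort(unique(c(pos$moa, neg$moa)))
  out <- do.call(rbind, lapply(moas, function(m) {
    data.frame(moa = m,
               n_positive = sum(pos$moa == m),
               n_negative = sum(neg$moa == m),
               positive = paste(pos$compound[pos$moa == m], collapse = ","),
               negative = paste(neg$compound[neg$moa == m], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(moa = character(), n_positive = integer(),
                      n_negative = integer(), positive = character(),
                      negative = character(), stringsAsFactors = FALSE)
  }
  out[order(-(out$n_positive + out$n_negative), out$moa), ]
}
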