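# Per-sample gene-set mutation burden, tumor mutational burden, and the
# median-split mut-high / mut-low grouping that drives the whole screen.

#' Compute a samples x gene-sets mutation burden matrix
#'
#' For each sample in `roster` and each gene set, counts either the filtered
#' variant records whose gene belongs to the set (`mode = "variants"`) or
#' the distinct mutated genes of the sample within the set
#' (`mode = "genes"`).  Samples absent from the mutation table get zero
#' counts, so the roster must enumerate the full cohort.
#'
#' @param mutations a [mutation_table()].
#' @param sets a [gene_set_collection()].
#' @param roster character vector of all cohort sample ids.
#' @param mode counting mode, `"variants"` (default) or `"genes"`.
#' @param class_filter variant classes counted; `NULL` counts everything.
#' @return Integer matrix samples x gene sets, class `"burden_matrix"`,
#'   with attributes `mode` and `class_filter`.
#' @export
compute_burden <- function(mutations, sets, roster,
                           mode = c("variants", "genes"),
                           class_filter = nonsilent_classes()) {
  mode <- match.arg(mode)
  stopifnot(inherits(mutations, "mutation_table"))
  if (!inherits(sets, "gene_set_collection")) {
    sets <- gene_set_collection(sets)
  }
  roster <- trimws(as.character(roster))
  if (!length(roster)) stop("empty sample roster")
  if (anyDuplicated(roster)) stop("duplicate sample ids in roster")

  rec <- mutations
  if (!is.null(class_filter)) {
    rec <- rec[rec$variant_class %in% class_filter, , drop = FALSE]
  }
  rec <- rec[rec$sample_id %in% roster, , drop = FALSE]
  if (mode == "genes") {
    rec <- rec[!duplicated(rec[c("sample_id", "gene")]), , drop = FALSE]
  }
  sid <- factor(rec$sample_id, levels = roster)
  out <- matrix(0L, nrow = length(roster), ncol = length(sets),
                dimnames = list(roster, names(sets)))
  universe <- unique(rec$gene)
  for (j in seq_along(sets)) {
    inset <- rec$gene %in% sets[[j]]
    if (!any(sets[[j]] %in% universe)) {
      warning("gene set '", names(sets)[j],
              "' has no overlap with the mutation universe")
    }
    out[, j] <- as.integer(tabulate(sid[inset], nbins = length(roster)))
  }
  structure(out, class = c("burden_matrix", class(out)),
            mode = mode, class_filter = class_filter)
}

#' Per-sample tumor mutational burden
#'
#' Counts nonsilent variant records per sample; downstream group
#' comparisons use the raw count (display on a log scale is a plotting
#' choice, not a transformation of the statistic).
#'
#' @param mutations a [mutation_table()].
#' @param roster cohort sample ids (samples without records get TMB 0).
#' @param class_filter variant classes counted as nonsilent.
#' @param exome_size_mb optional captured exome size; when given, a
#'   per-megabase value is attached as attribute `per_mb`.
#' @return Named integer vector of counts.
#' @export
compute_tmb <- function(mutations, roster,
                        class_filter = nonsilent_classes(),
                        exome_size_mb = NULL) {
  stopifnot(inherits(mutations, "mutation_table"))
  roster <- trimws(as.character(roster))
  if (!length(roster)) stop("empty sample roster")
  rec <- mutations
  if (!is.null(class_filter)) {
    rec <- rec[rec$variant_class %in% class_filter, , drop = FALSE]
  }
  counts <- table(factor(rec$sample_id, levels = roster))
  out <- as.integer(counts)
  names(out) <- roster
  if (!is.null(exome_size_mb)) {
    stopifnot(exome_size_mb > 0)
    attr(out, "per_mb") <- out / exome_size_mb
  }
  out
}

#' Median-split a burden column into mut-high / mut-low
#'
#' The threshold is the cohort median of the values; a sample is `mut_high`
#' iff its value is strictly greater than the median (the median itself
#' falls in `mut_low`), so `mut_high` can never exceed half the cohort.
#'
#' @param values numeric burden (or score) vector, named by sample.
#' @param policy split policy; only `"median_strict"` is implemented.
#' @return Factor with levels `c("mut_low", "mut_high")` (reference level
#'   first), attributes `threshold` and `n` (group sizes).  When every
#'   sample falls in one group a degenerate-grouping warning is emitted.
#' @export
dichotomize <- function(values, policy = "median_strict") {
  policy <- match.arg(policy, "median_strict")
  if (length(values) < 2L) stop("need at least 2 samples to dichotomize")
  if (any(!is.finite(values))) stop("non-finite burden values")
  thr <- stats::median(values)
  grp <- factor(ifelse(values > thr, "mut_high", "mut_low"),
                levels = c("mut_low", "mut_high"))
  names(grp) <- names(values)
  tab <- table(grp)
  if (any(tab == 0L)) {
    warning("degenerate grouping: all samples fall in one group")
  }
  structure(grp, threshold = thr, n = c(tab))
}
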