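# The discovery engine: median-split every gene set's burden column, Cox
# each split against survival, and keep the sets that replicate across
# cohorts with a consistent direction of effect.

#' Screen every gene set of a burden matrix against survival
#'
#' For each gene-set column: median-strict dichotomization into
#' mut-high/mut-low, then a univariate Cox fit of the group indicator.
#' Splits with fewer than `min_group` samples in either arm, or cohorts
#' with no events, are skipped with a reason rather than fitted.
#'
#' @param burden a [compute_burden()] matrix (samples x gene sets).
#' @param clinical a [clinical_table()]; samples matched by `sample_id`.
#' @param endpoint label recorded with each row (`"OS"` or `"PFS"`); the
#'   times in `clinical` must already be the chosen endpoint.
#' @param cohort_id label recorded with each row.
#' @param alpha nominal significance level recorded with the screen.
#' @param min_group minimum samples per arm for a usable split.
#' @param ties tie handling passed to [cox_fit()].
#' @return A `data.frame` of class `"screen_rows"`: one row per screened
#'   set (`set_name`, `cohort_id`, `endpoint`, `threshold`, `n_high`,
#'   `n_low`, `n_events`, `hr`, `lower`, `upper`, `p`, `direction`), with
#'   skipped sets and reasons in attribute `skipped`.
#' @export
screen_cohort <- function(burden, clinical, endpoint = c("OS", "PFS"),
                          cohort_id = "cohort", alpha = 0.05,
                          min_group = 3L, ties = "efron") {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(clinical, "clinical_table"))
  shared <- intersect(rownames(burden), clinical$sample_id)
  if (length(shared) < 10L) {
    stop("burden and clinical tables share fewer than 10 samples")
  }
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  if (sum(cl$event) < 1) stop("no events among shared samples")
  b <- burden[shared, , drop = FALSE]

  prep <- cox_prep(cl$time, cl$event)   # shared across all gene sets
  q <- stats::qnorm(0.975)
  rows <- vector("list", ncol(b))
  skipped <- list()
  for (j in seq_len(ncol(b))) {
    set_name <- colnames(b)[j]
    grp <- withCallingHandlers(
      dichotomize(b[, j]),
      warning = function(w) invokeRestart("muffleWarning"))
    tab <- table(grp)
    if (any(tab < min_group)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(set_name = set_name, reason = "degenerate grouping",
                   stringsAsFactors = FALSE)
      next
    }
    X <- matrix(as.numeric(grp == "mut_high"), ncol = 1L)
    fit <- tryCatch(
      suppressWarnings(coxph_core(X, cl$time, cl$event, ties = ties,
                                  prep = prep)),
      error = function(e) NULL)
    se <- if (is.null(fit)) NA_real_ else sqrt(fit$var[1L, 1L])
    if (is.null(fit) || !is.finite(se)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(set_name = set_name, reason = "unstable fit",
                   stringsAsFactors = FALSE)
      next
    }
    beta <- fit$beta[1L]
    rows[[j]] <- data.frame(
      set_name = set_name, cohort_id = cohort_id, endpoint = endpoint,
      threshold = attr(grp, "threshold"),
      n_high = as.integer(tab["mut_high"]), n_low = as.integer(tab["mut_low"]),
      n_events = fit$n_events,
      hr = exp(beta), lower = exp(beta - q * se), upper = exp(beta + q * se),
      p = 2 * stats::pnorm(-abs(beta / se)),
      direction = sign(beta),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no usable gene sets in the screen")
  rownames(out) <- NULL
  structure(out, class = c("screen_rows", "data.frame"), alpha = alpha,
            skipped = if (length(skipped)) do.call(rbind, skipped) else
              data.frame(set_name = character(), reason = character()))
}

#' Cross-cohort concordance filter
#'
#' Keeps the gene sets that are significant (`p < alpha`) in every cohort
#' with the same direction of effect; classifies them as protective
#' (HR < 1 everywhere) or risk (HR > 1 everywhere).  Sets significant
#' everywhere but with opposite directions are reported separately as
#' discordant.
#'
#' @param ... two or more [screen_cohort()] row tables (or a single list
#'   of them) over a shared gene-set universe.
#' @param alpha significance threshold applied per cohort.
#' @return Object of class `"screen_report"`: `concordant` (set, class,
#'   per-cohort HR and p), `discordant`, `alpha`, `cohorts`, and the input
#'   row tables.
#' @export
concordance_filter <- function(..., alpha = 0.05) {
  reports <- list(...)
  if (length(reports) == 1L && is.list(reports[[1L]]) &&
      !is.data.frame(reports[[1L]])) {
    reports <- reports[[1L]]
  }
  if (length(reports) < 2L) stop("need at least two cohort screens")
  ids <- vapply(reports, function(r) r$cohort_id[1L], "")
  shared <- Reduce(intersect, lapply(reports, function(r) r$set_name))
  if (!length(shared)) stop("no shared gene sets across cohorts")
  per <- lapply(reports, function(r) r[match(shared, r$set_name), ])
  sig <- Reduce(`&`, lapply(per, function(r) r$p < alpha))
  dirs <- vapply(per, function(r) r$direction, numeric(length(shared)))
  if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow = 1L)
  same_dir <- apply(dirs, 1L, function(d) all(d == d[1L]))
  hr_mat <- vapply(per, function(r) r$hr, numeric(length(shared)))
  p_mat <- vapply(per, function(r) r$p, numeric(length(shared)))
  if (is.null(dim(hr_mat))) {
    hr_mat <- matrix(hr_mat, nrow = 1L)
    p_mat <- matrix(p_mat, nrow = 1L)
  }
  colnames(hr_mat) <- paste0("hr_", ids)
  colnames(p_mat) <- paste0("p_", ids)
  base <- data.frame(set_name = shared, stringsAsFactors = FALSE)
  base <- cbind(base, hr_mat, p_mat)
  conc <- base[sig & same_dir, , drop = FALSE]
  conc$class <- ifelse(dirs[sig & same_dir, 1L] < 0, "protective", "risk")
  disc <- base[sig & !same_dir, , drop = FALSE]
  rownames(conc) <- rownames(disc) <- NULL
  structure(list(concordant = conc, discordant = disc, alpha = alpha,
                 cohorts = ids, rows = reports),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Cross-cohort screen over ", length(x$cohorts), " cohorts (",
      paste(x$cohorts, collapse = ", "), "), alpha = ", x$alpha, "\n",
      sep = "")
  cat("Concordant sets: ", nrow(x$concordant),
      " (", sum(x$concordant$class == "protective"), " protective, ",
      sum(x$concordant$class == "risk"), " risk); discordant: ",
      nrow(x$discordant), "\n", sep = "")
  if (nrow(x$concordant)) print(utils::head(x$concordant, 20), digits = 3)
  invisible(x)
}

#' Append multiplicity-adjusted q-values to screen rows
#'
#' The screen's default follows the replication logic (raw p per cohort,
#' no correction across sets); Benjamini-Hochberg q-values are available
#' as an option.
#'
#' @param rows a [screen_cohort()] row table (or any data.frame with `p`).
#' @param method `"none"` (default) or `"bh"`.
#' @return `rows`, with a `q` column appended when `method = "bh"`.
#' @export
multiplicity_adjust <- function(rows, method = c("none", "bh")) {
  method <- match.arg(method)
  if (!nrow(rows)) stop("empty row table")
  if (method == "bh") rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows
}
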