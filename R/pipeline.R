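# End-to-end orchestration of the three-step workflow: discovery
# (burden -> per-cohort screen -> cross-cohort concordance), verification
# on a held-out cohort, mechanism stages (TMB, per-gene comparisons, DGE,
# GSEA, per-sample scoring, pathway survival), and drug stages (lnIC50
# group tests, connectivity scoring).

#' Run the full pathway-burden pipeline
#'
#' `config` is a list (or a YAML file path whose entries name input
#' files).  Recognized entries:
#' \describe{
#'   \item{cohorts}{named list; each cohort has `mutations`
#'     (a [mutation_table()] or file path), `clinical`
#'     (a [clinical_table()] or path) and `endpoint` (`"OS"`/`"PFS"`).}
#'   \item{gene_sets}{a [gene_set_collection()] or GMT path.}
#'   \item{stages}{subset of `c("screen", "verify", "mechanism",
#'     "drugs", "cmap")`; an empty vector validates the config only.}
#'   \item{discovery_cohorts, verification_cohort}{cohort names; the
#'     verification cohort is re-split at its own median (the grouping
#'     rule, not the threshold, transfers).}
#'   \item{chosen_set}{gene set carried into verification/mechanism;
#'     defaults to the concordant set with the smallest combined p.}
#'   \item{expression, expression_cohort}{genes x samples matrix (or
#'     path) and the cohort its samples belong to.}
#'   \item{drug_response}{a drug-response table or path; cell lines are
#'     grouped by their own chosen-set burden median.}
#'   \item{cmap}{list with `up`, `down` tag vectors (defaulting to the DGE
#'     up/down calls), `refs` rank matrix, optional `meta` and `moa`.}
#'   \item{alpha, mode, seed}{screen threshold, burden counting mode,
#'     RNG seed for permutation stages.}
#' }
#'
#' @param config list or YAML path.
#' @param out_dir output directory; TSV results, `run_log.txt` and
#'   `manifest.json` (input checksums) are written there.
#' @return Invisible list with every stage's in-memory result.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "INFO", ...,
        "\n", file = log_path, append = TRUE)
  }
  alpha <- config$alpha %||% 0.05
  mode <- config$mode %||% "variants"
  seed <- config$seed %||% 1L
  stages <- config$stages %||% character()
  logf("pathburden", as.character(utils::packageVersion("pathburden")),
       "| alpha =", alpha, "| mode =", mode, "| seed =", seed,
       "| ties = efron | split = median_strict")

  manifest <- list()
  note_input <- function(name, x) {
    path <- if (is.character(x) && length(x) == 1L && file.exists(x)) x
    else {
      tf <- tempfile()
      saveRDS(x, tf)
      tf
    }
    manifest[[name]] <<- unname(tools::md5sum(path))
  }

  cohorts <- lapply(names(config$cohorts), function(nm) {
    co <- config$cohorts[[nm]]
    mut <- if (is.character(co$mutations)) {
      read_mutation_table(co$mutations)
    } else co$mutations
    cl <- if (is.character(co$clinical)) read_clinical(co$clinical)
    else co$clinical
    note_input(paste0("cohort_", nm, "_mutations"), co$mutations)
    note_input(paste0("cohort_", nm, "_clinical"), co$clinical)
    list(id = nm, mutations = mut, clinical = cl,
         endpoint = co$endpoint %||% "OS")
  })
  names(cohorts) <- names(config$cohorts)
  sets <- if (is.character(config$gene_sets)) read_gmt(config$gene_sets)
  else config$gene_sets
  if (!is.null(sets)) note_input("gene_sets", config$gene_sets)

  results <- list(config = config)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  burden_of <- function(co) {
    compute_burden(co$mutations, sets, co$clinical$sample_id, mode = mode)
  }
  run_stage <- function(name, fn) {
    logf("stage", name, "start")
    out <- tryCatch(fn(), error = function(e) {
      logf("stage", name, "FAILED:", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf("stage", name, "done")
    out
  }

  chosen <- config$chosen_set
  if ("screen" %in% stages) {
    results$screen <- run_stage("screen", function() {
      disc <- config$discovery_cohorts %||% names(cohorts)
      rows <- lapply(disc, function(nm) {
        co <- cohorts[[nm]]
        r <- screen_cohort(burden_of(co), co$clinical,
                           endpoint = co$endpoint, cohort_id = nm,
                           alpha = alpha)
        tsv(r, paste0("screen_", nm))
        r
      })
      if (length(rows) >= 2L) {
        rep <- concordance_filter(rows, alpha = alpha)
        tsv(rep$concordant, "concordant_sets")
        tsv(rep$discordant, "discordant_sets")
        rep
      } else rows[[1L]]
    })
    if (is.null(chosen) && inherits(results$screen, "screen_report") &&
        nrow(results$screen$concordant)) {
      conc <- results$screen$concordant
      pcols <- grep("^p_", names(conc))
      chosen <- conc$set_name[which.min(apply(conc[pcols], 1L, prod))]
      logf("chosen set:", chosen)
    }
  }

  group_by_set <- function(co) {
    b <- burden_of(co)
    if (!chosen %in% colnames(b)) stop("chosen set missing from burden")
    dichotomize(b[, chosen])
  }

  if ("verify" %in% stages) {
    results$verify <- run_stage("verify", function() {
      if (is.null(chosen)) stop("no chosen gene set for verification")
      nm <- config$verification_cohort %||% utils::tail(names(cohorts), 1L)
      co <- cohorts[[nm]]
      grp <- group_by_set(co)
      dat <- co$clinical
      dat$group <- grp[match(dat$sample_id, names(grp))]
      cox <- cox_fit(dat, "group")
      km <- km_fit(dat$time, dat$event, dat$group)
      lr <- logrank_test(dat$time, dat$event, dat$group)
      tsv(summary(cox), paste0("verify_cox_", nm))
      tsv(summary(km), paste0("verify_km_", nm))
      list(cohort = nm, groups = grp, cox = cox, km = km, logrank = lr)
    })
  }

  if ("mechanism" %in% stages) {
    results$mechanism <- run_stage("mechanism", function() {
      if (is.null(chosen)) stop("no chosen gene set for mechanism stage")
      nm <- config$expression_cohort %||% names(cohorts)[1L]
      co <- cohorts[[nm]]
      grp <- group_by_set(co)
      tmb <- compute_tmb(co$mutations, co$clinical$sample_id)
      tmb_test <- wilcoxon_ranksum(tmb[grp == "mut_high"],
                                   tmb[grp == "mut_low"])
      top <- compare_top_genes(co$mutations, grp,
                               extra_genes = sets[[chosen]])
      tsv(top, paste0("top_genes_", nm))
      out <- list(cohort = nm, groups = grp, tmb = tmb,
                  tmb_test = tmb_test, top_genes = top)
      expr <- config$expression
      if (!is.null(expr)) {
        if (is.character(expr)) expr <- read_expression(expr)
        note_input("expression", config$expression)
        shared <- intersect(colnames(expr), names(grp))
        expr <- expr[, shared, drop = FALSE]
        dge <- dge_moderated_t(expr, grp)
        tsv(dge, "dge")
        rk <- stats::setNames(dge$logFC, dge$gene)
        gsea <- gsea_preranked(rk, sets, seed = seed)
        tsv(gsea, "gsea")
        scores <- ssgsea_score(expr, sets)
        tsv(data.frame(set_name = rownames(scores), scores,
                       check.names = FALSE), "ssgsea_scores")
        dpe <- diff_pathway_expression(scores, grp)
        tsv(dpe, "diff_pathway_expression")
        psurv <- if (chosen %in% rownames(scores)) {
          pathway_score_survival(scores, co$clinical, chosen)
        }
        out <- c(out, list(dge = dge, gsea = gsea, scores = scores,
                           diff_pathway = dpe, pathway_survival = psurv))
      }
      out
    })
  }

  if ("drugs" %in% stages) {
    results$drugs <- run_stage("drugs", function() {
      if (is.null(chosen)) stop("no chosen gene set for drug stage")
      dr <- config$drug_response
      if (is.character(dr)) dr <- read_drug_response(dr)
      note_input("drug_response", config$drug_response)
      mut <- config$cell_line_mutations %||%
        cohorts[[config$expression_cohort %||% names(cohorts)[1L]]]$mutations
      lines <- unique(dr$cell_line)
      b <- compute_burden(mut, sets[chosen], lines, mode = mode)
      grp <- dichotomize(b[, chosen])
      tests <- do.call(rbind, lapply(split(dr, dr$drug), function(d) {
        g <- grp[match(d$cell_line, names(grp))]
        tr <- wilcoxon_ranksum(d$ln_ic50[g == "mut_high"],
                               d$ln_ic50[g == "mut_low"])
        data.frame(drug = d$drug[1L],
                   median_high = stats::median(d$ln_ic50[g == "mut_high"]),
                   median_low = stats::median(d$ln_ic50[g == "mut_low"]),
                   p = tr$p.value, stringsAsFactors = FALSE)
      }))
      rownames(tests) <- NULL
      tsv(tests, "drug_ic50_tests")
      list(groups = grp, tests = tests)
    })
  }

  if ("cmap" %in% stages) {
    results$cmap <- run_stage("cmap", function() {
      cm <- config$cmap
      up <- cm$up; down <- cm$down
      if ((is.null(up) || is.null(down)) &&
          !is.null(results$mechanism$dge)) {
        dge <- results$mechanism$dge
        up <- dge$gene[dge$de_call & dge$logFC > 0]
        down <- dge$gene[dge$de_call & dge$logFC < 0]
      }
      refs <- if (is.character(cm$refs)) {
        as.matrix(read_expression(cm$refs))
      } else cm$refs
      note_input("cmap_refs", cm$refs)
      res <- connectivity_score(up, down, refs, meta = cm$meta,
                                n_perm = cm$n_perm %||% 1000L, seed = seed)
      tsv(res$instances, "cmap_instances")
      tsv(res$compounds, "cmap_compounds")
      if (!is.null(cm$moa)) {
        moa <- moa_aggregate(res, cm$moa)
        tsv(moa, "cmap_moa")
        return(list(connectivity = res, moa = moa))
      }
      list(connectivity = res)
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  logf("run complete; stages:",
       if (length(stages)) paste(stages, collapse = ",") else "(none)")
  results$chosen_set <- chosen
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
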