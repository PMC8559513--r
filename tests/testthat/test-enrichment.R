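make_expr <- function(seed = 1, n_genes = 200L, n = 20L, shift = 0,
                      de_genes = integer()) {
  set.seed(seed)
  g <- sprintf("E%04d", seq_len(n_genes))
  s <- sprintf("S%03d", seq_len(n))
  grp <- factor(rep(c("mut_low", "mut_high"), each = n / 2),
                levels = c("mut_low", "mut_high"))
  names(grp) <- s
  m <- matrix(rnorm(n_genes * n), n_genes, n, dimnames = list(g, s))
  if (length(de_genes)) {
    m[de_genes, grp == "mut_high"] <- m[de_genes, grp == "mut_high"] + shift
  }
  list(expr = m, groups = grp)
}

test_that("moderated t reduces to the ordinary t when the prior df is 0", {
  d <- make_expr(1)
  mod <- dge_moderated_t(d$expr, d$groups, prior_df = 0)
  ref_t <- apply(d$expr, 1L, function(v) {
    stats::t.test(v[d$groups == "mut_high"], v[d$groups == "mut_low"],
                  var.equal = TRUE)$statistic
  })
  expect_equal(mod$t, unname(ref_t), tolerance = 1e-6)
})

test_that("moderated t agrees with limma's empirical Bayes machinery", {
  d <- make_expr(2, n_genes = 300L)
  # heterogeneous true variances so the prior is informative
  sds <- exp(rnorm(300, 0, 0.5))
  expr <- d$expr * sds
  mod <- dge_moderated_t(expr, d$groups)
  design <- stats::model.matrix(~ d$groups)
  fit <- limma::eBayes(limma::lmFit(expr, design))
  expect_equal(attr(mod, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mod, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(mod$t, fit$t[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(mod$p, fit$p.value[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("dge output satisfies its structural invariants", {
  d <- make_expr(3, shift = 2, de_genes = 1:20)
  mod <- dge_moderated_t(d$expr, d$groups)
  expect_true(all(mod$q >= mod$p))                  # BH never decreases p
  expect_true(all(sign(mod$logFC) == sign(mod$t) | mod$t == 0))
  # identical group means give logFC and t of exactly 0
  eq <- d$expr
  eq[1, d$groups == "mut_high"] <- 1:10
  eq[1, d$groups == "mut_low"] <- 1:10
  meq <- dge_moderated_t(eq, d$groups)
  expect_equal(meq$logFC[1], 0)
  expect_equal(meq$t[1], 0)
  # zero-variance flag path
  zv <- d$expr; zv[5, ] <- 7
  mz <- dge_moderated_t(zv, d$groups)
  expect_true(mz$zero_variance[5])
  expect_equal(mz$t[5], 0); expect_equal(mz$p[5], 1)
})

test_that("dge recovers planted differential genes at controlled FDR", {
  d <- make_expr(4, n_genes = 2000L, shift = 2, de_genes = 1:100)
  mod <- dge_moderated_t(d$expr, d$groups)
  called <- which(mod$q < 0.05 & abs(mod$logFC) > 1)
  recall <- mean(1:100 %in% called)
  fdr <- if (length(called)) mean(!(called %in% 1:100)) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdr, 0.1)
})

test_that("GSEA ES matches the classic KS running sum and its symmetries", {
  set.seed(5)
  rk <- setNames(seq(2, -2, length.out = 10), paste0("g", 1:10))
  set3 <- c("g1", "g5", "g9")
  out <- gsea_preranked(rk, list(S = set3), n_perm = 50, weight = 0,
                        min_size = 1, seed = 1)
  expect_equal(out$es, loop_gsea_es(names(sort(-rk)), set3))
  # top-concentrated set attains ES = 1
  top <- gsea_preranked(rk, list(S = paste0("g", 1:3)), n_perm = 50,
                        weight = 1, min_size = 1, seed = 1)
  expect_equal(top$es, 1)
  # reversing the ranking negates the weight-0 ES
  rev_rk <- setNames(-rk, names(rk))
  out_rev <- gsea_preranked(rev_rk, list(S = set3), n_perm = 50, weight = 0,
                            min_size = 1, seed = 1)
  expect_equal(out_rev$es, -out$es)
})

test_that("GSEA ES stays in [-1,1] and p in [1/(B+1), 1]", {
  set.seed(6)
  rk <- setNames(rnorm(300), sprintf("E%04d", 1:300))
  sets <- lapply(1:15, function(i) sample(names(rk), sample(5:50, 1)))
  names(sets) <- paste0("S", 1:15)
  out <- gsea_preranked(rk, sets, n_perm = 200, seed = 2)
  expect_true(all(out$es >= -1 & out$es <= 1))
  expect_true(all(out$p >= 1 / 201 & out$p <= 1))
  # fixed seed reproduces permutation p bit-identically
  out2 <- gsea_preranked(rk, sets, n_perm = 200, seed = 2)
  expect_identical(out$p, out2$p)
  expect_identical(out$nes, out2$nes)
})

test_that("GSEA ES agrees with fgsea on untied rankings", {
  set.seed(7)
  rk <- setNames(rnorm(500), sprintf("E%04d", 1:500))
  sets <- lapply(1:10, function(i) sample(names(rk), 30))
  names(sets) <- paste0("S", 1:10)
  ours <- gsea_preranked(rk, sets, n_perm = 10, seed = 1)
  ref <- suppressWarnings(
    fgsea::fgsea(sets, rk, minSize = 5, maxSize = 500, nPermSimple = 101))
  expect_equal(ours$es[match(ref$pathway, ours$set_name)], ref$ES,
               tolerance = 1e-12)
})

test_that("ssGSEA scoring matches a hand-computed toy case", {
  # one sample, 5 genes, 2-gene set; alpha 0.25; walk from top rank down
  expr <- matrix(c(5, 4, 3, 2, 1), ncol = 1,
                 dimnames = list(c("A", "B", "C", "D", "E"), "s1"))
  sc <- ssgsea_score(expr, list(S = c("A", "C")), alpha = 0.25,
                     normalize = FALSE)
  w <- c(5, 4, 3, 2, 1)^0.25
  ein <- cumsum(c(w[1], 0, w[3], 0, 0)) / (w[1] + w[3])
  eout <- cumsum(c(0, 1, 0, 1, 1)) / 3
  expect_equal(unname(sc["S", "s1"]), sum(ein - eout))
})

test_that("ssGSEA is rank-based and ignores unexpressed set members", {
  set.seed(8)
  d <- make_expr(8, n_genes = 100L, n = 10L)
  sets <- list(S1 = rownames(d$expr)[1:10], S2 = rownames(d$expr)[41:60])
  a <- ssgsea_score(d$expr, sets)
  # monotone per-sample transform leaves scores unchanged
  b <- ssgsea_score(exp(d$expr * 2) + 5, sets)
  expect_equal(a, b)
  # appending an absent gene changes nothing
  sets2 <- list(S1 = c(sets$S1, "NOT_MEASURED"), S2 = sets$S2)
  expect_equal(unname(ssgsea_score(d$expr, sets2)), unname(a))
  # sets below the overlap floor are skipped with a warning
  expect_warning(ssgsea_score(d$expr, c(sets, list(BAD = "NOPE"))),
                 "skipping")
})

test_that("top-ranked set members maximize a sample's ssGSEA score", {
  set.seed(9)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("E%02d", 1:20), sprintf("S%02d", 1:10)))
  m[1:4, 1] <- 100 + 1:4                   # set occupies top ranks in S01
  sc <- ssgsea_score(m, list(S = rownames(m)[1:4]), normalize = FALSE)
  expect_equal(which.max(sc["S", ]), c(S01 = 1L))
})

test_that("pathway-score survival recovers a planted protective score", {
  set.seed(10)
  hits <- replicate(30, {
    n <- 49
    score <- rnorm(n)
    grp <- score > median(score)
    t <- rexp(n, 0.05 * exp(log(0.3) * grp)) + 0.01
    e <- rbinom(n, 1, 0.7); if (sum(e) < 2) e[1:2] <- 1
    cl <- clinical_table(sprintf("S%03d", 1:n), t, e)
    sc <- matrix(score, 1, n,
                 dimnames = list("PATH", sprintf("S%03d", 1:n)))
    ps <- pathway_score_survival(sc, cl, "PATH")
    unname(ps$cox$hr[1]) < 1
  })
  expect_gte(mean(hits), 0.9)
  # constant score column must refuse to split
  cl <- toy_clinical()
  flat <- matrix(1, 1, 12, dimnames = list("P", cl$sample_id))
  expect_error(suppressWarnings(pathway_score_survival(flat, cl, "P")),
               "degenerate")
})

test_that("differential pathway expression finds a planted score shift", {
  set.seed(11)
  n <- 40
  s <- sprintf("S%03d", 1:n)
  grp <- factor(rep(c("mut_low", "mut_high"), each = n / 2),
                levels = c("mut_low", "mut_high"))
  names(grp) <- s
  sc <- rbind(SHIFTED = rnorm(n) + (grp == "mut_high"),
              FLAT = rnorm(n))
  colnames(sc) <- s
  out <- diff_pathway_expression(sc, grp)
  expect_equal(nrow(out), 2L)              # one row per scored set
  expect_lt(out$p[out$set_name == "SHIFTED"], 0.01)
  expect_gt(out$p[out$set_name == "FLAT"], 0.01)
  expect_gt(out$t[out$set_name == "SHIFTED"], 0)
})
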