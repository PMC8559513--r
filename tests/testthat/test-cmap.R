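# build a rank matrix whose columns are permutations of 1..n
make_refs <- function(n = 100L, m = 12L, seed = 1) {
  set.seed(seed)
  feats <- sprintf("F%03d", seq_len(n))
  refs <- vapply(seq_len(m), function(j) sample.int(n), integer(n))
  rownames(refs) <- feats
  colnames(refs) <- sprintf("inst_%02d", seq_len(m))
  refs
}

test_that("ks_tag_score evaluates the two-sided statistic exactly", {
  # t tags at the very top: a = 1 - (t-1)/n
  expect_equal(ks_tag_score(1:2, 100), 0.98)
  # tags at the very bottom: b = V(1)/n - 0 dominates
  expect_equal(ks_tag_score(99:100, 100), -0.99)
  # a = b tie resolves positive: single tag at n/2
  expect_equal(ks_tag_score(50, 100), 0.5)
  expect_error(ks_tag_score(integer(), 10))
  expect_error(ks_tag_score(1:10, 10))
  expect_error(ks_tag_score(c(3, 3), 10), "distinct")
})

test_that("ks_tag_score matches the direct-loop oracle for t <= 50", {
  set.seed(2)
  for (i in 1:60) {
    n <- sample(20:400, 1)
    t <- sample(1:min(50, n - 1), 1)
    pos <- sample.int(n, t)
    expect_equal(ks_tag_score(pos, n), loop_ks(pos, n),
                 info = paste("n =", n, "t =", t))
  }
})

test_that("connectivity scores scale to [-1,1] with extremal instances", {
  refs <- make_refs(100, 10, seed = 3)
  up <- rownames(refs)[1:5]; dn <- rownames(refs)[6:10]
  # plant a perfectly concordant instance: up tags at top, down at bottom
  ideal <- integer(100)
  names(ideal) <- rownames(refs)
  ideal[up] <- 1:5
  ideal[dn] <- 96:100
  ideal[setdiff(rownames(refs), c(up, dn))] <- 6:95
  refs <- cbind(refs, ideal = ideal)
  res <- connectivity_score(up, dn, refs, n_perm = 200, seed = 4)
  expect_true(all(res$instances$score >= -1 & res$instances$score <= 1))
  expect_equal(res$instances$score[res$instances$instance == "ideal"], 1)
  expect_lt(res$instances$p[res$instances$instance == "ideal"], 0.05)
  # raw s is zero whenever the two tag scores share a sign
  same <- sign(res$instances$ks_up) == sign(res$instances$ks_down)
  expect_true(all(res$instances$s[same] == 0))
})

test_that("swapping up and down tags negates every raw score", {
  refs <- make_refs(80, 8, seed = 5)
  up <- rownames(refs)[1:4]; dn <- rownames(refs)[70:75]
  a <- connectivity_score(up, dn, refs, n_perm = 50, seed = 6)
  b <- connectivity_score(dn, up, refs, n_perm = 50, seed = 6)
  expect_equal(a$instances$s, -b$instances$s)
})

test_that("random tag placement gives small scores and calibrated p", {
  refs <- make_refs(200, 40, seed = 7)
  set.seed(8)
  up <- sample(rownames(refs), 10)
  dn <- sample(setdiff(rownames(refs), up), 10)
  res <- connectivity_score(up, dn, refs, n_perm = 400, seed = 9)
  expect_lt(mean(abs(res$instances$s)), 0.5)
  expect_gt(mean(res$instances$p), 0.2)    # roughly uniform p under the null
  # fixed seed gives identical permutation p
  res2 <- connectivity_score(up, dn, refs, n_perm = 400, seed = 9)
  expect_identical(res$instances$p, res2$instances$p)
})

test_that("unmapped tags warn and fully unmapped signatures fail", {
  refs <- make_refs(50, 5, seed = 10)
  expect_warning(
    connectivity_score(c(rownames(refs)[1:3], "NOPE"), rownames(refs)[10:12],
                       refs, n_perm = 20, seed = 1),
    "absent")
  expect_error(
    suppressWarnings(connectivity_score("NOPE1", "NOPE2", refs,
                                        n_perm = 20)),
    "no mapped tags")
  expect_error(connectivity_score(c("A", "B"), c("B", "C"), refs), "disjoint")
})

test_that("planted concordant profiles top the MoA summary", {
  set.seed(11)
  n <- 150
  feats <- sprintf("F%03d", 1:n)
  up <- feats[1:8]; dn <- feats[9:16]
  mid <- setdiff(feats, c(up, dn))
  concordant_col <- function(noise) {
    # up tags near the top, down tags near the bottom, rest shuffled
    r <- integer(n); names(r) <- feats
    r[up] <- sample(1:20, 8)
    r[dn] <- sample((n - 19):n, 8)
    r[mid] <- sample(setdiff(1:n, r[c(up, dn)]))
    r
  }
  refs <- cbind(
    vapply(1:4, function(i) concordant_col(), integer(n)),   # ATPase-like
    vapply(1:8, function(i) sample.int(n), integer(n)))      # random
  rownames(refs) <- feats
  colnames(refs) <- c(paste0("atp_", 1:4), paste0("rand_", 1:8))
  meta <- data.frame(instance = colnames(refs), compound = colnames(refs))
  res <- connectivity_score(up, dn, refs, meta = meta, n_perm = 300,
                            seed = 12)
  top4 <- res$compounds$compound[order(-res$compounds$score)][1:4]
  expect_setequal(top4, paste0("atp_", 1:4))
  moa <- moa_aggregate(res, data.frame(
    compound = colnames(refs),
    moa = c(rep("ATPase inhibitor", 4), rep("other", 8))),
    score_cut = 0.8, p_cut = 0.05)
  expect_equal(moa$n_positive[moa$moa == "ATPase inhibitor"], 4L)
  # raising the score cut never increases any MoA count
  moa2 <- moa_aggregate(res, data.frame(
    compound = colnames(refs),
    moa = c(rep("ATPase inhibitor", 4), rep("other", 8))),
    score_cut = 0.95, p_cut = 0.05)
  n2 <- moa2$n_positive[moa2$moa == "ATPase inhibitor"]
  expect_lte(if (length(n2)) n2 else 0L,
             moa$n_positive[moa$moa == "ATPase inhibitor"])
})

test_that("no compound passing the cuts yields an empty summary", {
  refs <- make_refs(60, 4, seed = 13)
  res <- connectivity_score(rownames(refs)[1:3], rownames(refs)[50:52],
                            refs, n_perm = 50, seed = 14)
  out <- moa_aggregate(res, data.frame(compound = character(),
                                       moa = character()),
                       score_cut = 2, p_cut = 1e-9)
  expect_equal(nrow(out), 0L)
})
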