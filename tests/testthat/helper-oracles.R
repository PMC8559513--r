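# Independent oracles used by the tests.  These deliberately reimplement
# the statistics in the most direct (naive / enumerative) way possible so
# they share no code path with the package.

# naive Efron (or Breslow) log partial likelihood for a single covariate
naive_cox_loglik <- function(beta, x, time, event, ties = "efron") {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (tt in unique(time[event == 1])) {
    ev <- which(time == tt & event == 1)
    risk <- which(time >= tt)
    d <- length(ev)
    s0d <- sum(w[ev]); S0 <- sum(w[risk])
    phi <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    ll <- ll + sum(eta[ev]) - sum(log(S0 - phi * s0d))
  }
  ll
}

# two-stage grid maximization (coarse 0.01 over [-5, 5], then 1e-4 around
# the coarse optimum): a brute-force maximizer accurate to 1e-4
grid_cox_beta <- function(x, time, event, ties = "efron") {
  coarse <- seq(-5, 5, by = 0.01)
  ll <- vapply(coarse, naive_cox_loglik, 1, x = x, time = time,
               event = event, ties = ties)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  llf <- vapply(fine, naive_cox_loglik, 1, x = x, time = time,
                event = event, ties = ties)
  fine[which.max(llf)]
}

# Fisher two-sided p by full hypergeometric enumeration (fixed margins)
enum_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact Wilcoxon two-sided p by full enumeration of group assignments
# (doubled single tail, capped at 1 -- the exact-test convention)
enum_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  pl <- mean(ws <= w_obs); pu <- mean(ws >= w_obs)
  min(1, 2 * min(pl, pu))
}

# direct-loop two-sided KS tag statistic
loop_ks <- function(positions, n) {
  v <- sort(positions); t <- length(v)
  a <- -Inf; b <- -Inf
  for (i in seq_len(t)) {
    a <- max(a, i / t - v[i] / n)
    b <- max(b, v[i] / n - (i - 1) / t)
  }
  if (a >= b) a else -b
}

# classic (weight 0) GSEA running-sum ES by direct loop
loop_gsea_es <- function(ranked_genes, set) {
  n <- length(ranked_genes)
  hit <- ranked_genes %in% set
  t <- sum(hit)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) 1 / t else -1 / (n - t)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# small deterministic survival fixture with ties and censoring
toy_clinical <- function() {
  clinical_table(
    sample_id = paste0("s", 1:12),
    time = c(2, 2, 3, 5, 5, 5, 7, 8, 8, 10, 12, 15),
    event = c(1, 0, 1, 1, 1, 0, 1, 0, 1, 1, 0, 1),
    covariates = data.frame(
      grp = rep(c("a", "b"), 6),
      age = c(50, 61, 55, 47, 68, 59, 63, 52, 70, 58, 66, 49),
      stringsAsFactors = FALSE))
}

# tiny mutation table shared across burden/assoc tests
toy_mutations <- function() {
  mutation_table(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3", "s3", "s3", "s4"),
    gene = c("FASN", "FASN", "ACACA", "TP53", "PTGIS", "FASN", "TP53",
             "RB1", "SILENTONLY"),
    variant_class = c("Missense_Mutation", "Nonsense_Mutation",
                      "Missense_Mutation", "Missense_Mutation",
                      "Frame_Shift_Del", "Splice_Site",
                      "Missense_Mutation", "Missense_Mutation", "Silent"))
}
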