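test_that("KM product-limit matches hand-computed step functions", {
  # all events: steps 0.8, 0.6, 0.4, 0.2, 0; median 3
  km <- km_fit(1:5, rep(1, 5))
  expect_equal(km$strata$all$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median$median, 3)
  # all censored: S = 1 throughout, median not reached
  km2 <- km_fit(1:5, rep(0, 5))
  expect_true(all(km2$strata$all$surv == 1))
  expect_true(is.na(km2$median$median))
  # censoring interleaved: S(1)=0.8, S(3)=0.8*(1-1/3)=0.5333, S(5)=0
  km3 <- km_fit(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  s <- km3$strata$all
  expect_equal(s$surv[s$time == 1], 0.8)
  expect_equal(s$surv[s$time == 3], 0.8 * (1 - 1 / 3))
  expect_equal(s$surv[s$time == 5], 0)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(5)
  t <- sample(1:40, 25, replace = TRUE)
  km <- km_fit(t, rep(1, 25))
  s <- km$strata$all
  emp <- vapply(s$time, function(tt) mean(t > tt), 1)
  expect_equal(s$surv, emp)
})

test_that("KM agrees with the survival package including log-log CIs", {
  cl <- toy_clinical()
  km <- km_fit(cl$time, cl$event, cl$grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp, data = cl,
                          conf.type = "log-log")
  ss <- summary(sf)
  ours <- summary(km)
  ours <- ours[ours$n_event > 0, ]        # survfit summary lists event times
  expect_equal(ours$surv, ss$surv, tolerance = 1e-10)
  expect_equal(ours$lower, ss$lower, tolerance = 1e-10)
  expect_equal(ours$upper, ss$upper, tolerance = 1e-10)
})

test_that("log-rank test matches survdiff and behaves at the null", {
  cl <- toy_clinical()
  lr <- logrank_test(cl$time, cl$event, cl$grp)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = cl)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
  # identical data in both groups: chi2 = 0, p = 1
  t2 <- c(cl$time, cl$time); e2 <- c(cl$event, cl$event)
  g2 <- rep(c("x", "y"), each = nrow(cl))
  lr0 <- logrank_test(t2, e2, g2)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p.value, 1)
  # complete separation of event patterns is detected for n >= 10 per arm
  t3 <- c(1:10, 21:30); e3 <- c(rep(1, 10), rep(0, 10))
  g3 <- rep(c("early", "none"), each = 10)
  expect_lt(logrank_test(t3, e3, g3)$p.value, 0.05)
  expect_error(logrank_test(cl$time, cl$event, rep("a", 12)), "two groups")
})

test_that("cox_fit maximizes the Efron partial likelihood (grid oracle)", {
  set.seed(17)
  for (i in 1:6) {
    n <- sample(8:12, 1)
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) == 1L) x[1:2] <- c(0, 1)
    t <- sample(1:8, n, replace = TRUE)   # forces ties
    e <- rbinom(n, 1, 0.8); if (sum(e) < 2) e[1:2] <- 1
    cl <- clinical_table(paste0("s", 1:n), t, e,
                         data.frame(g = x))
    fit <- tryCatch(suppressWarnings(cox_fit(cl, "g")),
                    error = function(e) NULL)
    if (is.null(fit) || fit$diverged) next
    b_grid <- grid_cox_beta(x, t, e, "efron")
    expect_lt(abs(unname(coef(fit)) - b_grid), 1e-4)
  }
})

test_that("cox_fit agrees with survival::coxph for both tie methods", {
  set.seed(23)
  n <- 80
  x <- rbinom(n, 1, 0.4); age <- rnorm(n, 60, 8)
  t <- round(rexp(n, 0.05 * exp(0.6 * x - 0.02 * age + 1.2)), 1) + 0.1
  e <- rbinom(n, 1, 0.7)
  cl <- clinical_table(paste0("s", 1:n), t, e, data.frame(g = x, age = age))
  for (ti in c("efron", "breslow")) {
    ours <- cox_fit(cl, c("g", "age"), ties = ti)
    ref <- survival::coxph(survival::Surv(t, e) ~ x + age, ties = ti)
    expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-7)
    expect_equal(as.numeric(logLik(ours)), as.numeric(logLik(ref)),
                 tolerance = 1e-7)
  }
})

test_that("cox reparameterization and time-scaling symmetries hold", {
  cl <- toy_clinical()
  f1 <- cox_fit(cl, "grp")
  cl2 <- cl
  cl2$grp <- factor(cl2$grp, levels = c("b", "a"))   # flip the coding
  f2 <- cox_fit(cl2, "grp")
  expect_equal(unname(coef(f1)), -unname(coef(f2)), tolerance = 1e-9)
  expect_equal(unname(f1$hr), 1 / unname(f2$hr), tolerance = 1e-9)
  cl3 <- cl
  cl3$time <- cl3$time * 7.3                         # beta scale-invariant
  f3 <- cox_fit(cl3, "grp")
  expect_equal(unname(coef(f1)), unname(coef(f3)), tolerance = 1e-9)
})

test_that("Efron and Breslow agree exactly without tied event times", {
  set.seed(3)
  n <- 30
  t <- sort(runif(n, 1, 100))                        # distinct times
  e <- rbinom(n, 1, 0.7); x <- rbinom(n, 1, 0.5)
  cl <- clinical_table(paste0("s", 1:n), t, e, data.frame(g = x))
  expect_equal(coef(cox_fit(cl, "g", ties = "efron")),
               coef(cox_fit(cl, "g", ties = "breslow")), tolerance = 1e-10)
})

test_that("Wald CI excludes 1 exactly when p < 0.05", {
  set.seed(29)
  for (i in 1:20) {
    n <- 40
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, exp(runif(1, -1, 1) * x)) + 0.01
    e <- rbinom(n, 1, 0.8); if (sum(e) < 2) next
    cl <- clinical_table(paste0("s", 1:n), t, e, data.frame(g = x))
    f <- tryCatch(suppressWarnings(cox_fit(cl, "g")),
                  error = function(e) NULL)
    if (is.null(f) || f$diverged) next
    excl <- f$ci[1, "lower"] > 1 || f$ci[1, "upper"] < 1
    expect_equal(excl, unname(f$p[1] < 0.05))
  }
})

test_that("permuted group labels give a null fit", {
  set.seed(41)
  n <- 100
  t <- rexp(n, 0.05); e <- rbinom(n, 1, 0.7)
  betas <- replicate(30, {
    x <- sample(rep(0:1, n / 2))
    cl <- clinical_table(paste0("s", 1:n), t, e, data.frame(g = x))
    unname(coef(suppressWarnings(cox_fit(cl, "g"))))
  })
  expect_lt(abs(mean(betas)), 0.15)
})

test_that("separation is flagged and capped rather than diverging silently", {
  # group a has all early events, group b all late censorings
  cl <- clinical_table(paste0("s", 1:10),
                       c(1:5, 51:55), c(rep(1, 5), rep(0, 5)),
                       data.frame(g = rep(c("a", "b"), each = 5)))
  expect_warning(f <- cox_fit(cl, "g"), "monotone")
  expect_true(f$diverged)
  expect_lte(max(abs(coef(f))), 15)
})

test_that("multivariate fit handles confounding and detects collinearity", {
  set.seed(53)
  n <- 150
  stage <- rbinom(n, 1, 0.5)
  grp <- ifelse(runif(n) < 0.8, stage, 1 - stage)   # correlated with stage
  t <- rexp(n, 0.05 * exp(1 * stage)) + 0.01        # only stage is causal
  e <- rbinom(n, 1, 0.8)
  cl <- clinical_table(paste0("s", 1:n), t, e,
                       data.frame(grp = grp, stage = stage))
  f <- cox_multivariate(cl, c("grp", "stage"))
  ref <- survival::coxph(survival::Surv(t, e) ~ grp + stage)
  expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-7)
  # single-term multivariate is identical to the univariate fit
  expect_equal(coef(cox_multivariate(cl, "stage")),
               coef(cox_fit(cl, "stage")))
  cl$stage2 <- cl$stage
  expect_error(cox_multivariate(cl, c("stage", "stage2")), "collinear")
})

test_that("adjusted HR covers 1 under confounding in most replicates", {
  set.seed(59)
  cover <- replicate(60, {
    n <- 100
    stage <- rbinom(n, 1, 0.5)
    grp <- ifelse(runif(n) < 0.8, stage, 1 - stage)
    t <- rexp(n, 0.05 * exp(0.9 * stage)) + 0.01
    e <- rbinom(n, 1, 0.8)
    cl <- clinical_table(paste0("s", 1:n), t, e,
                         data.frame(grp = grp, stage = stage))
    f <- tryCatch(suppressWarnings(cox_multivariate(cl, c("grp", "stage"))),
                  error = function(e) NULL)
    if (is.null(f)) return(NA)
    f$ci["grp", "lower"] <= 1 && f$ci["grp", "upper"] >= 1
  })
  expect_gte(mean(cover, na.rm = TRUE), 0.9)
})

test_that("stage collapsing builds an advanced-vs-early contrast", {
  x <- c("I", "II", "III", "IV", "III")
  out <- collapse_levels(x, list(early = c("I", "II"),
                                 advanced = c("III", "IV")))
  expect_equal(as.character(out),
               c("early", "early", "advanced", "advanced", "advanced"))
  expect_equal(levels(out), c("early", "advanced"))
  expect_error(collapse_levels(c(x, "V"), list(early = "I",
                                               advanced = c("II", "III", "IV"))),
               "unmapped")
})

test_that("cox methods expose prediction and martingale residuals", {
  cl <- toy_clinical()
  cl$time <- cl$time + seq(0.01, 0.12, by = 0.01)   # tie-free for the oracle
  f <- cox_fit(cl, c("grp", "age"))
  lp <- predict(f)
  expect_length(lp, 12)
  expect_equal(predict(f, type = "risk"), exp(lp))
  r <- residuals(f)
  expect_equal(sum(r), 0, tolerance = 1e-9)   # martingale residuals sum to 0
  expect_true(all(r <= 1))
  ref <- survival::coxph(survival::Surv(time, event) ~ grp + age, data = cl,
                         ties = "efron")
  expect_equal(unname(r), unname(residuals(ref, type = "martingale")),
               tolerance = 1e-6)
})
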