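# Survival machinery: Kaplan-Meier product-limit estimation, the log-rank
# test, and Cox proportional-hazards fitting by Newton-Raphson on the
# partial likelihood (Efron or Breslow tie handling).  Written against the
# likelihood directly so the tie corrections, convergence rules and
# divergence handling are explicit and testable.

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive survival times.
#' @param event 0/1 event indicator (1 = event, 0 = right-censored).
#' @param group optional grouping factor; one curve per level.
#' @param conf_level confidence level for the pointwise log-log interval.
#' @return Object of class `"km_fit"`: per-group step functions (`time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `lower`, `upper`), and a
#'   `median` table with the median survival time (smallest `t` with
#'   `S(t) <= 0.5`; `NA` = not reached) and its log-log confidence bounds.
#' @export
km_fit <- function(time, event, group = NULL, conf_level = 0.95) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  if (is.null(group)) group <- factor(rep("all", length(time)))
  group <- droplevels(as.factor(group))
  if (any(table(group) == 0L)) stop("empty group")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  strata <- lapply(levels(group), function(g) {
    t_g <- time[group == g]
    e_g <- event[group == g]
    ut <- sort(unique(t_g))
    n_risk <- vapply(ut, function(t) sum(t_g >= t), 1)
    n_event <- vapply(ut, function(t) sum(t_g == t & e_g == 1), 1)
    n_censor <- vapply(ut, function(t) sum(t_g == t & e_g == 0), 1)
    surv <- cumprod(1 - n_event / n_risk)
    # Greenwood variance of log S, then log-log interval
    gw <- cumsum(ifelse(n_risk > n_event,
                        n_event / (n_risk * (n_risk - n_event)), 0))
    ll_se <- ifelse(surv > 0 & surv < 1, sqrt(gw) / abs(log(surv)), NA)
    lower <- ifelse(is.na(ll_se), NA, surv^exp(z * ll_se))
    upper <- ifelse(is.na(ll_se), NA, surv^exp(-z * ll_se))
    lower[surv == 1] <- 1; upper[surv == 1] <- 1
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, surv = surv,
               lower = lower, upper = upper)
  })
  names(strata) <- levels(group)
  first_leq <- function(t, s, cut = 0.5) {
    i <- which(!is.na(s) & s <= cut)
    if (length(i)) t[min(i)] else NA_real_
  }
  med <- do.call(rbind, lapply(names(strata), function(g) {
    d <- strata[[g]]
    data.frame(group = g,
               n = sum(group == g), events = sum(d$n_event),
               median = first_leq(d$time, d$surv),
               lower = first_leq(d$time, d$lower),
               upper = first_leq(d$time, d$upper),
               stringsAsFactors = FALSE)
  }))
  structure(list(strata = strata, median = med, conf_level = conf_level),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit (", length(x$strata), " group(s), ",
      round(100 * x$conf_level), "% log-log CI)\n", sep = "")
  med <- x$median
  med$median <- ifelse(is.na(med$median), "not reached",
                       format(med$median, digits = 4))
  print(med, row.names = FALSE)
  invisible(x)
}

#' @export
summary.km_fit <- function(object, ...) {
  do.call(rbind, lapply(names(object$strata), function(g) {
    cbind(group = g, object$strata[[g]])
  }))
}

#' @export
plot.km_fit <- function(x, col = seq_along(x$strata), xlab = "Time (months)",
                        ylab = "Survival probability", ...) {
  graphics::plot(NA, xlim = c(0, max(unlist(lapply(x$strata, `[[`, "time")))),
                 ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x$strata)) {
    d <- x$strata[[i]]
    graphics::lines(stats::stepfun(d$time, c(1, d$surv)), col = col[i],
                    do.points = FALSE)
  }
  graphics::legend("topright", legend = names(x$strata), col = col, lty = 1)
  invisible(x)
}

#' Log-rank test
#'
#' Standard observed-minus-expected chi-square over the pooled event times,
#' with the hypergeometric variance (tie-corrected).
#'
#' @param time,event as in [km_fit()].
#' @param group grouping factor with at least two levels.
#' @return Object of class `"logrank_test"`: `statistic`, `df`, `p.value`,
#'   per-group observed and expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2L) stop("log-rank test needs at least two groups")
  if (sum(event) == 0) stop("no events in the data")
  ut <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g), 1)
    dg <- vapply(levels(group),
                 function(g) sum(time == t & event == 1 & group == g), 1)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      frac <- ng / n
      V <- V + d * (n - d) / (n - 1) * (diag(frac, k) - outer(frac, frac))
    }
  }
  i <- seq_len(k - 1L)
  stat <- drop(t(O[i] - E[i]) %*% solve(V[i, i, drop = FALSE], (O - E)[i]))
  p <- stats::pchisq(stat, df = k - 1L, lower.tail = FALSE)
  structure(list(statistic = stat, df = k - 1L, p.value = p,
                 observed = stats::setNames(O, levels(group)),
                 expected = stats::setNames(E, levels(group))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chi-square = ", format(x$statistic, digits = 4),
      " on ", x$df, " df, p = ", format.pval(x$p.value, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# ---- Cox partial likelihood core -------------------------------------------

# Beta-independent preparation for the partial likelihood: sorted order,
# tie blocks of equal time (descending), event membership, and the
# expanded per-event tie index l = 0..d_k-1 used by the Efron correction.
# The risk set of an event at time t is every row up to the end of t's
# block (censored at t remain at risk).
cox_prep <- function(time, event) {
  ord <- order(time, decreasing = TRUE)
  stime <- time[ord]; sevent <- event[ord]
  r <- rle(stime)
  ends <- cumsum(r$lengths)
  evb <- lapply(seq_along(ends), function(b) {
    idx <- (ends[b] - r$lengths[b] + 1L):ends[b]
    idx[sevent[idx] == 1]
  })
  keep <- lengths(evb) > 0L
  if (!any(keep)) stop("no events in the data")
  evb <- evb[keep]
  d <- lengths(evb)
  B <- length(d)
  list(ord = ord, eta_n = length(time),
       mb = ends[keep],                      # risk-set cut per event block
       ev_all = unlist(evb),                 # event rows (sorted frame)
       bid_ev = rep.int(seq_len(B), d),      # block of each event
       bid_l = rep.int(seq_len(B), d),       # block of each tie index l
       phi_efron = unlist(lapply(d, function(k) (seq_len(k) - 1) / k)),
       B = B, n_events = sum(d))
}

# Newton-Raphson maximization of the Cox partial likelihood.
# X: n x p design (no intercept); returns beta, var, loglik, diagnostics.
# The Efron correction enters through the per-event-block scalar sums
# c1 = sum 1/D_l, cphi = sum phi_l/D_l, etc. with D_l = S0 - phi_l*s0d,
# phi_l = l/d: score and information have closed forms per block, and all
# blocks are handled at once through rowsum() over the expanded tie index.
coxph_core <- function(X, time, event, ties = c("efron", "breslow"),
                       max_iter = 50L, tol_score = 1e-9, tol_ll = 1e-10,
                       prep = NULL) {
  ties <- match.arg(ties)
  n <- nrow(X); p <- ncol(X)
  if (is.null(prep)) prep <- cox_prep(time, event)
  SX <- X[prep$ord, , drop = FALSE]
  mb <- prep$mb; ev <- prep$ev_all
  bid_ev <- prep$bid_ev; bid_l <- prep$bid_l; B <- prep$B
  phi <- if (ties == "efron") prep$phi_efron else numeric(length(bid_l))
  Xev <- SX[ev, , drop = FALSE]
  sum_xev <- colSums(Xev)
  pp <- (p * (p + 1L)) %/% 2L
  iu <- which(upper.tri(diag(p), diag = TRUE))        # packed p x p index
  jj <- ((iu - 1L) %/% p) + 1L; kk <- ((iu - 1L) %% p) + 1L
  unpack <- function(v) {
    m <- matrix(0, p, p)
    m[cbind(kk, jj)] <- v; m[cbind(jj, kk)] <- v
    m
  }

  eval_all <- function(beta) {
    eta <- drop(SX %*% beta)
    w <- exp(eta)
    S0 <- cumsum(w)[mb]
    wX <- SX * w
    CS1 <- wX
    for (j in seq_len(p)) CS1[, j] <- cumsum(wX[, j])
    S1 <- CS1[mb, , drop = FALSE]
    XX <- wX[, jj, drop = FALSE] * SX[, kk, drop = FALSE]
    CS2 <- XX
    for (j in seq_len(pp)) CS2[, j] <- cumsum(XX[, j])
    S2 <- CS2[mb, , drop = FALSE]
    wev <- w[ev]
    s0d <- rowsum(wev, bid_ev, reorder = FALSE)[, 1L]
    s1d <- rowsum(Xev * wev, bid_ev, reorder = FALSE)
    s2d <- rowsum(XX[ev, , drop = FALSE], bid_ev, reorder = FALSE)
    D <- S0[bid_l] - phi * s0d[bid_l]
    iD <- 1 / D
    c1 <- rowsum(iD, bid_l, reorder = FALSE)[, 1L]
    cphi <- rowsum(phi * iD, bid_l, reorder = FALSE)[, 1L]
    c2 <- rowsum(iD * iD, bid_l, reorder = FALSE)[, 1L]
    cphi2 <- rowsum(phi * iD * iD, bid_l, reorder = FALSE)[, 1L]
    cphi22 <- rowsum(phi * phi * iD * iD, bid_l, reorder = FALSE)[, 1L]
    ll <- sum(eta[ev]) - sum(log(D))
    U <- sum_xev - colSums(S1 * c1 - s1d * cphi)
    Ifull <- unpack(colSums(S2 * c1 - s2d * cphi)) -
      (crossprod(S1, S1 * c2) -
         crossprod(S1, s1d * cphi2) - crossprod(s1d, S1 * cphi2) +
         crossprod(s1d, s1d * cphi22))
    list(ll = ll, U = U, I = Ifull)
  }

  beta <- numeric(p)
  ev0 <- eval_all(beta)
  ll0 <- ev0$ll                      # null log partial likelihood
  cur <- ev0
  converged <- FALSE; diverged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    halves <- 0L
    repeat {
      cand <- beta + step
      new <- eval_all(cand)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
      step <- step / 2
      halves <- halves + 1L
      if (halves > 30L) break
    }
    dll <- new$ll - cur$ll
    beta <- cand; cur <- new
    if (any(abs(beta) > 15)) {        # monotone likelihood / separation
      diverged <- TRUE
      beta <- pmin(pmax(beta, -15), 15)
      cur <- eval_all(beta)
      break
    }
    if (max(abs(cur$U)) < tol_score || abs(dll) < tol_ll) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !diverged) {
    stop("Cox fit failed to converge in ", max_iter,
         " iterations (last |score| = ", format(max(abs(cur$U))), ")")
  }
  if (diverged) {
    warning("monotone partial likelihood (possible separation); ",
            "coefficients capped at |beta| <= 15")
  }
  var <- tryCatch(solve(cur$I), error = function(e) {
    matrix(NA_real_, p, p)
  })
  list(beta = beta, var = var, loglik = c(ll0, cur$ll), iter = iter,
       converged = converged, diverged = diverged,
       n = n, n_events = sum(event))
}

# build a no-intercept design matrix for the given terms of a clinical table
build_design <- function(clinical, terms) {
  miss <- setdiff(terms, names(clinical))
  if (length(miss)) stop("term(s) not in clinical table: ",
                         paste(miss, collapse = ", "))
  dat <- as.data.frame(clinical)[terms]
  for (j in names(dat)) {
    if (is.character(dat[[j]]) || is.logical(dat[[j]])) {
      dat[[j]] <- factor(dat[[j]])
    }
    if (is.factor(dat[[j]])) {
      dat[[j]] <- droplevels(dat[[j]])
      if (nlevels(dat[[j]]) < 2L) {
        stop("term '", j, "' has a single level")
      }
    } else if (stats::var(dat[[j]]) == 0) {
      stop("continuous term '", j, "' is constant")
    }
  }
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, dat)[, -1L, drop = FALSE]
  asg <- attr(stats::model.matrix(f, dat), "assign")[-1L]
  attr(X, "term_of") <- terms[asg]
  X
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the partial likelihood by Newton-Raphson with step-halving;
#' ties handled by the Efron correction (default) or Breslow.  Convergence
#' when the score falls below `1e-9` or the log-likelihood change below
#' `1e-10`; a monotone likelihood (perfect separation) is flagged and the
#' coefficient capped at `|beta| <= 15` with a warning.
#'
#' @param clinical a [clinical_table()] (columns `time` and `event` plus
#'   covariates), or any data.frame with those columns.
#' @param terms character vector of covariate column names; factors are
#'   expanded against their first (reference) level.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level confidence level of the Wald interval (exact normal
#'   quantile, not the 1.96 approximation).
#' @return Object of class `"cox_fit"` with per-term `coefficients`
#'   (log hazard ratios), `se`, `hr`, Wald `ci`, `z`, `p`, the model
#'   log-likelihoods, and convergence diagnostics.
#' @examples
#' cl <- clinical_table(paste0("s", 1:8), time = c(1, 2, 3, 4, 5, 6, 7, 8),
#'                      event = c(1, 1, 1, 1, 1, 1, 0, 0),
#'                      covariates = data.frame(grp = rep(c("a", "b"), 4)))
#' cox_fit(cl, "grp")
#' @export
cox_fit <- function(clinical, terms, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(clinical)))
  cc <- stats::complete.cases(as.data.frame(clinical)[c("time", "event",
                                                        terms)])
  clinical <- clinical[cc, , drop = FALSE]
  if (sum(clinical$event) < 1) stop("no events in the data")
  X <- build_design(clinical, terms)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qx$rank)]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- coxph_core(X, clinical$time, clinical$event, ties = ties)
  se <- sqrt(diag(fit$var))
  z <- fit$beta / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(lower = exp(fit$beta - q * se), upper = exp(fit$beta + q * se))
  rownames(ci) <- colnames(X)
  structure(list(coefficients = stats::setNames(fit$beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 hr = stats::setNames(exp(fit$beta), colnames(X)),
                 ci = ci, z = z, p = stats::setNames(p, colnames(X)),
                 n = fit$n, n_events = fit$n_events,
                 loglik = fit$loglik, iter = fit$iter,
                 converged = fit$converged, diverged = fit$diverged,
                 ties = ties, conf_level = conf_level,
                 terms = terms, term_of = attr(X, "term_of"),
                 X = X, time = clinical$time, event = clinical$event),
            class = "cox_fit")
}

#' Multivariate Cox model over several terms
#'
#' Joint fit of all `terms` (a single term reduces exactly to [cox_fit()]);
#' rank deficiency among the expanded columns is a fatal error naming the
#' collinear terms.  Categorical terms are expanded against their reference
#' level; collapse levels beforehand (e.g. early vs advanced stage) with
#' [collapse_levels()].
#'
#' @inheritParams cox_fit
#' @return A `"cox_fit"` object with one row per expanded term.
#' @export
cox_multivariate <- function(clinical, terms, ties = c("efron", "breslow"),
                             conf_level = 0.95) {
  cox_fit(clinical, terms, ties = match.arg(ties), conf_level = conf_level)
}

#' Collapse factor levels
#'
#' Utility for grouping clinical categories, e.g. TNM stage III+IV into an
#' advanced-disease level against early-stage I+II.
#'
#' @param x factor or character vector.
#' @param mapping named list: new level -> old levels.
#' @return Factor with levels in the order of `mapping`.
#' @export
collapse_levels <- function(x, mapping) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  for (new in names(mapping)) out[x %in% mapping[[new]]] <- new
  if (anyNA(out)) stop("unmapped level(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  factor(out, levels = names(mapping))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(summary(x), digits = 4)
  if (x$diverged) cat("warning: monotone likelihood; estimates capped\n")
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) {
  data.frame(coef = object$coefficients, se = object$se,
             HR = object$hr, lower = object$ci[, "lower"],
             upper = object$ci[, "upper"], z = object$z, p = object$p)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) {
  # refit information inverse is stored implicitly through se for p = 1;
  # recompute from the stored design for completeness
  fit <- coxph_core(object$X, object$time, object$event, ties = object$ties)
  v <- fit$var
  dimnames(v) <- list(names(object$coefficients), names(object$coefficients))
  v
}

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$coefficients - q * object$se,
               object$coefficients + q * object$se)
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik[2L], df = length(object$coefficients),
            class = "logLik")
}

#' @export
predict.cox_fit <- function(object, newdata = NULL,
                            type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else {
    build_design(newdata, object$terms)
  }
  lp <- drop(X %*% object$coefficients)
  if (type == "risk") exp(lp) else lp
}

#' @export
residuals.cox_fit <- function(object, type = "martingale", ...) {
  type <- match.arg(type, "martingale")
  # Breslow cumulative baseline hazard at each subject's time
  lp <- drop(object$X %*% object$coefficients)
  w <- exp(lp)
  ut <- sort(unique(object$time[object$event == 1]))
  dH0 <- vapply(ut, function(t) {
    sum(object$event[object$time == t]) / sum(w[object$time >= t])
  }, 1)
  H0 <- vapply(object$time, function(t) sum(dH0[ut <= t]), 1)
  object$event - H0 * w
}
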