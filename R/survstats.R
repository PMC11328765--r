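# Survival-statistics machinery used to validate the morphometric
# markers: Kaplan-Meier, log-rank, Cox proportional hazards (Breslow
# ties) with backward selection, Schoenfeld residual checks,
# IPCW time-dependent ROC, restricted cubic spline hazard curves and
# Pearson correlation.  Standard fits go through the survival package;
# the time-dependent ROC estimator is implemented here (no estimator for
# it ships with the stack) and is pinned by an exact no-censoring
# equivalence to pair counting.

# validate a survival sample: data.frame with time/event plus covariates
.checkSurvivalSample <- function(sample, needEvents = 1L) {
  if (!is.data.frame(sample))
    stop("a survival sample must be a data.frame")
  for (col in c("time", "event"))
    if (!col %in% names(sample))
      stop(sprintf("survival sample is missing the '%s' column", col))
  if (any(sample$time < 0))
    stop("negative survival times are not allowed")
  ev <- as.integer(sample$event)
  if (any(!ev %in% 0:1))
    stop("event must be coded 0/1 (or logical)")
  if (sum(ev) < needEvents)
    stop(sprintf("at least %d event(s) required, found %d", needEvents,
                 sum(ev)))
  sample$event <- ev
  sample
}

#' Kaplan-Meier estimate of freedom from event
#'
#' Product-limit estimator of the survival (freedom-from-PPVS) function.
#'
#' @param sample `data.frame` with columns `time` (months, >= 0) and
#'   `event` (0/1 or logical).
#' @return A list of class `kmEstimate`: `table` (event-time table with
#'   `time, n.risk, n.event, n.censor, surv`), `survAt` (right-continuous
#'   step function, `survAt(0) = 1`), and `n`.
#' @examples
#' km <- kmEstimate(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
#' km$survAt(c(0, 1, 3))  # 1, 2/3, 0
#' @export
kmEstimate <- function(sample) {
  sample <- .checkSurvivalSample(sample, needEvents = 0L)
  if (nrow(sample) < 1L) stop("empty sample")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sample)
  tab <- data.frame(time = fit$time, n.risk = fit$n.risk,
                    n.event = fit$n.event, n.censor = fit$n.censor,
                    surv = fit$surv)
  sfun <- stats::stepfun(tab$time, c(1, tab$surv), right = FALSE)
  structure(list(table = tab, survAt = sfun, n = nrow(sample)),
            class = "kmEstimate")
}

#' @export
print.kmEstimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, %d events\n", x$n,
              sum(x$table$n.event)))
  print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param sampleA,sampleB Survival samples (`time`, `event`), both
#'   nonempty with at least one event overall.
#' @return List with `chisq` (1 df), `p`, and the observed/expected event
#'   counts per group.
#' @export
logrankTest <- function(sampleA, sampleB) {
  if (!nrow(sampleA) || !nrow(sampleB))
    stop("both groups must be nonempty")
  sampleA <- .checkSurvivalSample(sampleA, needEvents = 0L)
  sampleB <- .checkSurvivalSample(sampleB, needEvents = 0L)
  if (sum(sampleA$event) + sum(sampleB$event) < 1L)
    stop("the log-rank test needs at least one event")
  pooled <- rbind(
    data.frame(time = sampleA$time, event = sampleA$event, group = "A"),
    data.frame(time = sampleB$time, event = sampleB$event, group = "B"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = pooled)
  chisq <- as.numeric(sd$chisq)
  list(chisq = chisq, p = pchisq(chisq, df = 1L, lower.tail = FALSE),
       observed = as.numeric(sd$obs), expected = as.numeric(sd$exp))
}

#' Cox proportional hazards fit
#'
#' Maximizes the Breslow partial likelihood over the named covariates and
#' reports hazard ratios with Wald 95% confidence intervals and p-values.
#' Supports multivariable adjustment by listing several covariates.
#'
#' @param sample `data.frame` with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return A list of class `coxFit`: `coefficients` (data.frame with
#'   `term, beta, se, hr, lo, hi, p`), `loglik`, `converged`, `n`,
#'   `nevent`, and the underlying `model`.
#' @export
coxFit <- function(sample, covariates) {
  sample <- .checkSurvivalSample(sample, needEvents = 2L)
  missing <- setdiff(covariates, names(sample))
  if (length(missing))
    stop(sprintf("covariate(s) not in sample: %s",
                 paste(missing, collapse = ", ")))
  for (cv in covariates) {
    v <- sample[[cv]]
    if (is.logical(v)) sample[[cv]] <- as.numeric(v)
    if (length(unique(sample[[cv]])) < 2L)
      stop(sprintf("covariate '%s' is constant", cv))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  warned <- NULL
  model <- withCallingHandlers(
    survival::coxph(fml, data = sample, ties = "breslow",
                    control = survival::coxph.control(iter.max = 100L),
                    x = TRUE),
    warning = function(w) {
      warned <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (!is.null(warned) && grepl("converge|infinite|beta", warned,
                                ignore.case = TRUE)) {
    grad <- tryCatch(
      sqrt(sum(colSums(as.matrix(
        stats::residuals(model, type = "score")))^2)),
      error = function(e) NA_real_)
    stop(sprintf(
      "Cox fit did not converge in 100 iterations (%s; final score norm %.3g)",
      warned, grad))
  }
  beta <- coef(model)
  se <- sqrt(diag(vcov(model)))
  z <- qnorm(0.975)
  coefs <- data.frame(term = names(beta), beta = as.numeric(beta),
                      se = as.numeric(se), hr = exp(as.numeric(beta)),
                      lo = exp(as.numeric(beta) - z * se),
                      hi = exp(as.numeric(beta) + z * se),
                      p = 2 * stats::pnorm(-abs(as.numeric(beta) / se)),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, loglik = model$loglik,
                 converged = TRUE, n = model$n, nevent = model$nevent,
                 model = model, data = sample),
            class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (Breslow ties): n = %d, %d events\n",
              x$n, x$nevent))
  df <- x$coefficients
  df$hr <- sprintf("%.3f (%.3f-%.3f)", df$hr, df$lo, df$hi)
  print(df[, c("term", "beta", "se", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' Schoenfeld residual check of proportional hazards
#'
#' Correlates the scaled Schoenfeld residuals of each covariate with the
#' rank of the event times; under proportional hazards the correlation is
#' zero.  The p-value is the rank-transform Schoenfeld test
#' ([survival::cox.zph()]).
#'
#' @param fit A `coxFit` from [coxFit()] fitted on >= 3 events.
#' @return `data.frame` with one row per covariate: `term, rho, chisq,
#'   p`.
#' @export
schoenfeldCheck <- function(fit) {
  stopifnot(inherits(fit, "coxFit"))
  if (fit$nevent < 3L)
    stop("the Schoenfeld check needs at least 3 events")
  zph <- survival::cox.zph(fit$model, transform = "rank")
  sres <- stats::residuals(fit$model, type = "scaledsch")
  sres <- as.matrix(sres)
  terms <- fit$coefficients$term
  etimes <- sort(fit$data$time[fit$data$event == 1L])
  rho <- vapply(seq_along(terms), function(k)
    cor(rank(etimes), sres[, k]), numeric(1))
  tab <- zph$table
  data.frame(term = terms, rho = rho,
             chisq = tab[terms, "chisq"], p = tab[terms, "p"],
             stringsAsFactors = FALSE, row.names = NULL)
}

# left-continuous censoring-survival function G(t-) from the
# Kaplan-Meier estimate of the censoring distribution
.censoringKM <- function(time, event) {
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- cfit$time; ss <- cfit$surv
  function(t, leftLimit = TRUE) {
    vapply(t, function(ti) {
      idx <- if (leftLimit) which(tt < ti) else which(tt <= ti)
      if (!length(idx)) 1 else ss[max(idx)]
    }, numeric(1))
  }
}

# cumulative-case/dynamic-control IPCW AUC at horizon t
.ipcwAUC <- function(time, event, marker, horizon) {
  G <- .censoringKM(time, event)
  cases <- which(time <= horizon & event == 1L)
  controls <- which(time > horizon)
  if (!length(cases))
    stop("no events by the requested horizon")
  if (!length(controls))
    stop("no subjects remain at risk beyond the horizon")
  wCase <- 1 / G(time[cases], leftLimit = TRUE)
  wCtrl <- rep(1 / G(horizon, leftLimit = FALSE), length(controls))
  mc <- marker[cases]; mk <- marker[controls]
  conc <- outer(mc, mk, ">") + 0.5 * outer(mc, mk, "==")
  num <- as.numeric(t(wCase) %*% conc %*% wCtrl)
  num / (sum(wCase) * sum(wCtrl))
}

#' Time-dependent ROC AUC for a prognostic marker
#'
#' Cumulative-case / dynamic-control AUC at a fixed horizon with inverse
#' probability of censoring weights from the Kaplan-Meier estimate of the
#' censoring distribution: cases are subjects with an event by the
#' horizon, controls are subjects still event-free beyond it.  With no
#' censoring the estimator reduces exactly to pair counting of the binary
#' outcome "event by the horizon".  The confidence interval is a seeded
#' percentile bootstrap over subjects.
#'
#' @param sample `data.frame` with `time` and `event`.
#' @param marker Numeric marker vector, one value per subject (higher =
#'   more at risk).
#' @param horizon Evaluation time (months).
#' @param nboot Bootstrap resamples for the CI (default 500; 0 skips the
#'   CI).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return A list of class `tdRoc`: `horizon`, `auc`, `ciLow`, `ciHigh`,
#'   `nCases`, `nControls`, `nboot`, `weighting`.
#' @export
tdRoc <- function(sample, marker, horizon, nboot = 500L, seed = NULL,
                  level = 0.95) {
  sample <- .checkSurvivalSample(sample, needEvents = 1L)
  if (length(marker) != nrow(sample))
    stop("marker length must match the sample")
  if (any(!is.finite(marker))) stop("marker must be finite")
  auc <- .ipcwAUC(sample$time, sample$event, marker, horizon)
  ciLow <- ciHigh <- NA_real_
  if (nboot > 0L) {
    n <- nrow(sample)
    boots <- .withSeed(seed, {
      vapply(seq_len(nboot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(.ipcwAUC(sample$time[idx], sample$event[idx],
                          marker[idx], horizon),
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                   na.rm = TRUE, names = FALSE)
    ciLow <- max(0, qs[1]); ciHigh <- min(1, qs[2])
  }
  structure(list(horizon = horizon, auc = auc, ciLow = ciLow,
                 ciHigh = ciHigh,
                 nCases = sum(sample$time <= horizon & sample$event == 1L),
                 nControls = sum(sample$time > horizon), nboot = nboot,
                 weighting = "IPCW cumulative/dynamic"),
            class = "tdRoc")
}

#' @export
print.tdRoc <- function(x, ...) {
  cat(sprintf("Time-dependent AUC at t = %g: %.3f", x$horizon, x$auc))
  if (!is.na(x$ciLow))
    cat(sprintf(" (%d%% CI %.3f-%.3f, %d bootstrap resamples)",
                95L, x$ciLow, x$ciHigh, x$nboot))
  cat(sprintf("\n  %d cumulative cases, %d dynamic controls, %s weights\n",
              x$nCases, x$nControls, x$weighting))
  invisible(x)
}

#' Restricted cubic spline hazard curve for a marker
#'
#' Fits a Cox model on a natural (restricted) cubic spline basis of the
#' marker with 4 knots at the 5th, 35th, 65th and 95th percentiles
#' (linear-interpolation quantiles) and returns the hazard-ratio curve
#' normalized to HR = 1 at the reference marker value (the cohort median
#' by default), with pointwise Wald confidence bands.
#'
#' @param sample `data.frame` with `time`, `event`; needs >= 20 subjects
#'   and >= 5 events.
#' @param marker Numeric marker vector (non-constant).
#' @param reference Reference marker value anchoring HR = 1; default the
#'   cohort median.
#' @param gridLength Number of marker values on the returned curve.
#' @return A list of class `splineCurve`: `knots`, `reference`, `curve`
#'   (`data.frame` with `marker, loghr, hr, lo, hi`), `coef`, and the
#'   underlying `fit`.
#' @export
rcsHazardCurve <- function(sample, marker, reference = NULL,
                           gridLength = 100L) {
  sample <- .checkSurvivalSample(sample, needEvents = 5L)
  if (nrow(sample) < 20L)
    stop("the spline curve needs at least 20 subjects")
  if (length(marker) != nrow(sample))
    stop("marker length must match the sample")
  if (length(unique(marker)) < 2L) stop("marker is constant")
  knots <- quantile(marker, c(0.05, 0.35, 0.65, 0.95), type = 7,
                    names = FALSE)
  if (is.null(reference)) reference <- median(marker)
  basis <- function(x)
    splines::ns(x, knots = knots[2:3], Boundary.knots = knots[c(1, 4)])
  X <- basis(marker)
  df <- cbind(sample[c("time", "event")], as.data.frame(unclass(X)))
  names(df)[-(1:2)] <- paste0("b", seq_len(ncol(X)))
  fit <- coxFit(df, paste0("b", seq_len(ncol(X))))
  beta <- fit$coefficients$beta
  V <- vcov(fit$model)
  grid <- seq(min(marker), max(marker), length.out = gridLength)
  Bg <- basis(grid)
  Br <- basis(reference)
  D <- sweep(Bg, 2L, as.numeric(Br), "-")
  loghr <- as.numeric(D %*% beta)
  sehr <- sqrt(rowSums((D %*% V) * D))
  z <- qnorm(0.975)
  structure(list(knots = knots, reference = reference,
                 coef = beta,
                 curve = data.frame(marker = grid, loghr = loghr,
                                    hr = exp(loghr),
                                    lo = exp(loghr - z * sehr),
                                    hi = exp(loghr + z * sehr)),
                 hrAt = function(x) {
                   Dx <- sweep(basis(x), 2L, as.numeric(Br), "-")
                   exp(as.numeric(Dx %*% beta))
                 },
                 fit = fit),
            class = "splineCurve")
}

#' @export
print.splineCurve <- function(x, ...) {
  cat("Restricted cubic spline hazard curve\n")
  cat("  knots (5/35/65/95th percentiles):",
      paste(format(x$knots, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  HR = 1 at reference marker value %.4g\n", x$reference))
  invisible(x)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both
#'   non-constant.
#' @return List with `r`, `p` and `n`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("Pearson correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Backward covariate selection for the Cox model
#'
#' Univariable screen at `alphaEnter`, then repeated multivariable fits
#' dropping the largest-p covariate until all remaining p-values are
#' below `alphaStay`.
#'
#' @param sample `data.frame` with `time`, `event` and covariates.
#' @param candidates Character vector of candidate covariate names.
#' @param alphaEnter,alphaStay Significance thresholds (default 0.05).
#' @return List with `final` (a `coxFit`, or `NULL` when nothing
#'   survives), `selected`, and `steps` (a character log).
#' @export
coxBackward <- function(sample, candidates, alphaEnter = 0.05,
                        alphaStay = 0.05) {
  steps <- character(0)
  uni <- vapply(candidates, function(cv) {
    f <- tryCatch(coxFit(sample, cv), error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$coefficients$p[1]
  }, numeric(1))
  keep <- candidates[!is.na(uni) & uni < alphaEnter]
  steps <- c(steps, sprintf("univariable screen kept: %s",
                            if (length(keep)) paste(keep, collapse = ", ")
                            else "(none)"))
  if (!length(keep))
    return(list(final = NULL, selected = character(0), steps = steps))
  repeat {
    fit <- coxFit(sample, keep)
    p <- setNames(fit$coefficients$p, fit$coefficients$term)
    if (all(p < alphaStay) || length(keep) == 1L) break
    drop <- names(which.max(p))
    # map a factor/logical expansion back to its covariate name
    drop <- keep[vapply(keep, function(k) startsWith(drop, k), logical(1))][1]
    keep <- setdiff(keep, drop)
    steps <- c(steps, sprintf("dropped '%s' (p = %.3g)", drop, max(p)))
    if (!length(keep))
      return(list(final = NULL, selected = character(0), steps = steps))
  }
  steps <- c(steps, sprintf("final model: %s", paste(keep, collapse = ", ")))
  list(final = fit, selected = keep, steps = steps)
}
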