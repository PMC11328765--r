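# Survival machinery: product-limit estimates, log-rank, Cox fits,
# Schoenfeld checks, time-dependent ROC, spline hazard curves, Pearson.

test_that("Kaplan-Meier matches hand product-limit calculations", {
  # all censored: S stays 1
  km0 <- kmEstimate(data.frame(time = c(2, 5, 9), event = c(0, 0, 0)))
  expect_true(all(km0$survAt(c(0, 2, 5, 9, 20)) == 1))

  # {1 event, 2 censored, 3 event}: S(1) = 2/3, S(3) = 0
  km <- kmEstimate(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km$survAt(1), 2 / 3)
  expect_equal(km$survAt(3), 0)
  expect_equal(km$survAt(0), 1)

  # single subject, event at 5: step 1 -> 0
  km1 <- kmEstimate(data.frame(time = 5, event = 1))
  expect_equal(km1$survAt(4.999), 1)
  expect_equal(km1$survAt(5), 0)

  expect_error(kmEstimate(data.frame(time = -1, event = 1)), "negative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(31)
  t <- round(rexp(40, 0.2), 1) + 0.1
  km <- kmEstimate(data.frame(time = t, event = 1))
  for (tt in quantile(t, c(0.2, 0.5, 0.9)))
    expect_equal(km$survAt(tt), mean(t > tt))
})

test_that("the log-rank test agrees with the hand O-E/V computation", {
  identical_g <- data.frame(time = c(1, 3, 5, 7), event = c(1, 0, 1, 1))
  res <- logrankTest(identical_g, identical_g)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)

  A <- data.frame(time = c(1, 2), event = c(1, 1))
  B <- data.frame(time = c(10, 11), event = c(1, 1))
  res2 <- logrankTest(A, B)
  expect_equal(res2$chisq, handLogrank(A$time, A$event, B$time, B$event),
               tolerance = 1e-10)

  expect_error(logrankTest(data.frame(time = 1, event = 0),
                           data.frame(time = 2, event = 0)),
               "at least one event")
  expect_error(logrankTest(data.frame(time = numeric(0),
                                      event = integer(0)), A), "nonempty")
})

test_that("Cox estimates agree with the brute-force partial likelihood", {
  # exchangeable groups: beta ~ 0
  d <- data.frame(time = rep(c(1, 3, 4, 7), 2),
                  event = rep(c(1, 0, 1, 1), 2),
                  x = rep(c(0, 1), each = 4))
  expect_lt(abs(coxFit(d, "x")$coefficients$beta), 1e-6)

  # 8-subject no-ties toy set vs two-stage grid search on [-5, 5]
  toy <- data.frame(time = c(5, 1, 7, 2, 8, 3, 9, 4),
                    event = c(1, 1, 0, 1, 1, 0, 1, 1),
                    x = c(0.2, -1.3, 0.8, 0.5, -0.4, 1.1, -0.9, 0.3))
  fit <- coxFit(toy, "x")
  expect_lt(abs(fit$coefficients$beta -
                  gridCoxBeta(toy$time, toy$event, toy$x)), 1e-4)

  # score vanishes at the maximizer
  expect_lt(abs(sum(residuals(fit$model, type = "score"))), 1e-8)

  # CI brackets the HR and HR = exp(beta) exactly
  cf <- fit$coefficients
  expect_identical(cf$hr, exp(cf$beta))
  expect_true(cf$lo <= cf$hr && cf$hr <= cf$hi)

  expect_error(coxFit(data.frame(time = 1:4, event = c(1, 0, 0, 0),
                                 x = rnorm(4)), "x"), "2 event")
  expect_error(coxFit(data.frame(time = 1:5, event = c(1, 1, 1, 0, 0),
                                 x = rep(2, 5)), "x"), "constant")
})

test_that("Cox recovery from morphology-linked cohorts is unbiased", {
  est <- vapply(1:10, function(s) {
    sc <- makeSyntheticCohort(400, effectItvlc = -0.15, effectRatio = 0,
                              censorRate = 0.3, seed = 100 + s)
    coxFit(cohortSample(sc), "itvlc")$coefficients$beta
  }, numeric(1))
  expect_lt(abs(mean(est) + 0.15), 0.05)
})

test_that("the Schoenfeld check flags time-varying effects and not PH data", {
  sc <- makeSyntheticCohort(300, seed = 17)
  fit <- coxFit(cohortSample(sc), "itvlc")
  chk <- schoenfeldCheck(fit)
  expect_identical(chk$term, "itvlc")
  expect_true(is.finite(chk$rho) && is.finite(chk$p))

  # effect flips sign mid-study: high rejection power
  rej <- vapply(1:20, function(s) {
    set.seed(700 + s); n <- 300
    x <- rnorm(n); b <- 1.2; h <- 0.08; tFlip <- 8
    l1 <- h * exp(b * x); l2 <- h * exp(-b * x)
    u <- -log(runif(n))
    tt <- ifelse(u < l1 * tFlip, u / l1, tFlip + (u - l1 * tFlip) / l2)
    cmax <- quantile(tt, 0.9)
    d <- data.frame(time = pmin(tt, cmax),
                    event = as.integer(tt <= cmax), x = x)
    schoenfeldCheck(coxFit(d, "x"))$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.5)

  tiny <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                     x = c(0, 1, 0, 1))
  expect_error(schoenfeldCheck(coxFit(tiny, "x")), "3 events")
})

test_that("time-dependent AUC equals pair counting without censoring", {
  set.seed(21)
  n <- 80
  t <- rexp(n, 0.15); marker <- -t + rnorm(n, 0, 2)
  d <- data.frame(time = t, event = 1L)
  horizon <- median(t)
  r <- tdRoc(d, marker, horizon, nboot = 0)
  expect_equal(r$auc,
               pairCountAuc(as.integer(t <= horizon), marker))

  # a marker that perfectly separates cases gives AUC = 1
  perfect <- ifelse(t <= horizon, 1, 0) * 10 + seq_len(n) * 1e-9
  expect_equal(tdRoc(d, perfect, horizon, nboot = 0)$auc, 1)

  expect_error(tdRoc(d, marker, horizon = 1e-9, nboot = 0), "no events")
})

test_that("time-dependent AUC is invariant under monotone marker transforms", {
  sc <- makeSyntheticCohort(250, seed = 5)
  d <- cohortSample(sc)
  base <- tdRoc(d, -d$itvlc, horizon = 12, nboot = 0)$auc
  expect_identical(tdRoc(d, exp(-d$itvlc / 10), 12, nboot = 0)$auc, base)
  expect_identical(tdRoc(d, rank(-d$itvlc), 12, nboot = 0)$auc, base)
})

test_that("bootstrap CIs are seeded, reproducible and inside [0, 1]", {
  sc <- makeSyntheticCohort(150, seed = 9)
  d <- cohortSample(sc)
  r1 <- tdRoc(d, -d$itvlc, 12, nboot = 100, seed = 4)
  r2 <- tdRoc(d, -d$itvlc, 12, nboot = 100, seed = 4)
  expect_identical(r1$ciLow, r2$ciLow)
  expect_true(r1$ciLow >= 0 && r1$ciHigh <= 1 && r1$ciLow <= r1$auc)
})

test_that("spline knots, reference normalization and shape behave", {
  d <- data.frame(time = rexp(100) + 0.1,
                  event = rep(c(1L, 0L), 50))
  sp <- rcsHazardCurve(d, as.numeric(1:100))
  expect_equal(sp$knots, c(5.95, 35.65, 65.35, 95.05))
  expect_identical(sp$hrAt(sp$reference), 1)

  # protective log-linear effect: decreasing HR over the central range
  sc <- makeSyntheticCohort(400, effectItvlc = -0.15, effectRatio = 0,
                            censorRate = 0.3, seed = 11)
  dd <- cohortSample(sc)
  sp2 <- rcsHazardCurve(dd, dd$itvlc)
  rng <- quantile(dd$itvlc, c(0.05, 0.95))
  ctr <- sp2$curve[sp2$curve$marker >= rng[1] &
                     sp2$curve$marker <= rng[2], ]
  expect_true(all(diff(ctr$hr) < 0))

  expect_error(rcsHazardCurve(d, rep(1, 100)), "constant")
  expect_error(rcsHazardCurve(d[1:10, ], as.numeric(1:10)), "20 subjects")
})

test_that("Pearson correlation matches the closed form", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonR(x, 2 * x)$r, 1)
  expect_equal(pearsonR(x, -x + 10)$r, -1)
  expect_equal(pearsonR(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearsonR(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("backward selection keeps real effects and drops noise", {
  set.seed(77)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(0.8 * x1))
  cmax <- quantile(tt, 0.8)
  d <- data.frame(time = pmin(tt, cmax), event = as.integer(tt <= cmax),
                  x1 = x1, x2 = x2)
  sel <- coxBackward(d, c("x1", "x2"))
  expect_true("x1" %in% sel$selected)
  expect_false("x2" %in% sel$selected)
})

test_that("high-iTVLC strata enjoy higher freedom from event", {
  sc <- makeSyntheticCohort(300, effectItvlc = -0.15, effectRatio = 0,
                            censorRate = 0.3, seed = 23)
  d <- cohortSample(sc)
  hi <- d$itvlc >= median(d$itvlc)
  kmHi <- kmEstimate(d[hi, c("time", "event")])
  kmLo <- kmEstimate(d[!hi, c("time", "event")])
  expect_gt(kmHi$survAt(12), kmLo$survAt(12))
  lr <- logrankTest(d[hi, c("time", "event")], d[!hi, c("time", "event")])
  expect_lt(lr$p, 0.01)
})
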