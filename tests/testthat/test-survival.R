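test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  # event at t=1 (3 at risk) -> 2/3; censor at 2 (no step); event at t=3
  # with 1 at risk -> 0
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 3], 0, tolerance = 1e-12)

  # all censored: flat at 1
  km0 <- kmEstimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # duplicating every subject leaves the curve unchanged
  h <- handSurvival()
  a <- kmEstimate(h$time, h$event)
  b <- kmEstimate(rep(h$time, 2), rep(h$event, 2))
  expect_equal(a$surv, b$surv, tolerance = 1e-12)
  expect_equal(a$time, b$time)

  # no censoring: KM equals the empirical survival function
  tt <- c(2, 4, 4, 7, 9)
  km2 <- kmEstimate(tt, rep(1, 5))
  ecdfS <- vapply(km2$time, function(u) mean(tt > u), numeric(1))
  expect_equal(km2$surv, ecdfS, tolerance = 1e-12)
  expect_error(kmEstimate(numeric(), numeric()), "empty")
})

test_that("log-rank equals the brute-force hypergeometric O-E summation", {
  h <- handSurvival()
  lr <- logrankTest(h$time, h$event, h$group)
  oracle <- oracleLogrankZ(h$time, h$event, h$group == "b")
  expect_equal(lr$statistic, oracle$chisq, tolerance = 1e-12)
  expect_identical(lr$df, 1L)
  # label swap leaves the two-group statistic unchanged
  swapped <- logrankTest(h$time, h$event, ifelse(h$group == "a", "b", "a"))
  expect_equal(swapped$statistic, lr$statistic, tolerance = 1e-12)

  # identical groups: statistic 0, p 1
  lr0 <- logrankTest(rep(h$time, 2), rep(h$event, 2),
                     rep(c("x", "y"), each = 6))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # three groups use two degrees of freedom
  lr3 <- logrankTest(rep(h$time, 3), rep(h$event, 3),
                     rep(c("x", "y", "z"), each = 6))
  expect_identical(lr3$df, 2L)
  expect_error(logrankTest(h$time, h$event, rep("only", 6)), ">= 2")
})

test_that("Cox recovers a planted log-hazard on a continuous covariate", {
  set.seed(17)
  n <- 500
  z <- rnorm(n)
  tEvent <- rexp(n, rate = 0.01 * exp(0.7 * z))
  cens <- rexp(n, rate = 0.004)
  time <- pmin(tEvent, cens); event <- as.integer(tEvent <= cens)
  fit <- coxFit(time, event, data.frame(z = z))
  expect_lt(abs(fit$beta - 0.7), 3 * fit$se)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$lower95 < fit$hr & fit$hr < fit$upper95)
  expect_error(coxFit(time, event, data.frame(z = rep(1, n))), "constant")
  expect_error(coxFit(time, rep(0, n), data.frame(z = z)), "no events")
})

test_that("null covariates stay within nominal Wald coverage", {
  set.seed(23)
  inside <- vapply(1:100, function(i) {
    n <- 120
    z <- rnorm(n)
    time <- rexp(n, 0.01); event <- rbinom(n, 1, 0.8)
    abs(coxFit(time, event, data.frame(z = z))$z) < qnorm(0.975)
  }, logical(1))
  expect_gte(mean(inside), 0.93)
})

test_that("Efron and Breslow tie handling agree when there are no ties", {
  set.seed(31)
  n <- 60
  z <- rnorm(n)
  time <- rexp(n, 0.01 * exp(0.5 * z))   # continuous: no ties
  event <- rbinom(n, 1, 0.85)
  a <- coxFit(time, event, data.frame(z = z), ties = "efron")
  b <- coxFit(time, event, data.frame(z = z), ties = "breslow")
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
  expect_equal(a$se, b$se, tolerance = 1e-10)
})

test_that("cutpoint scan equals brute-force log-rank recomputation at every candidate", {
  set.seed(41)
  n <- 40
  score <- rnorm(n)
  time <- rexp(n, 0.02 * exp(0.8 * (score > 0)))
  event <- rbinom(n, 1, 0.9)
  cp <- optimalCutpoint(score, time, event, minprop = 0.1)
  for (i in seq_len(nrow(cp@scanTable))) {
    ct <- cp@scanTable$cutpoint[i]
    expect_equal(cp@scanTable$statistic[i],
                 oracleLogrankZ(time, event, score > ct)$z,
                 tolerance = 1e-12)
  }
  best <- which.max(abs(cp@scanTable$statistic))
  expect_equal(cp@cutpoint, cp@scanTable$cutpoint[best])
  # cutpoint respects the minprop window
  expect_gte(mean(score <= cp@cutpoint), 0.1)
  expect_gte(mean(score > cp@cutpoint), 0.1)
})

test_that("perfect separation keeps every truly-high sample in the high group", {
  # low scores die early, high scores are long-term censored. Note the
  # standardized statistic peaks at, or slightly inside, the low-score
  # block (its variance shrinks faster than O-E as the split unbalances),
  # so the guarantee is that the cut never climbs into the high block.
  score <- c(rep(0:4 / 10, 2), rep(5:9 / 10 + 1, 2))
  time <- c(rep(1:5, 2), rep(100:104, 2))
  event <- c(rep(1, 10), rep(0, 10))
  cp <- optimalCutpoint(score, time, event, minprop = 0.1)
  expect_lt(cp@cutpoint, 1.5)
  expect_true(all(score[score >= 1.5] > cp@cutpoint))
  # the clean boundary split is near-maximal
  zBoundary <- abs(cp@scanTable$statistic[cp@scanTable$cutpoint == 0.4])
  expect_gt(zBoundary, 0.9 * abs(cp@statistic))
  expect_gt(abs(cp@statistic),
            max(abs(cp@scanTable$statistic)) - 1e-12)
  expect_error(optimalCutpoint(rep(1, 10), time[1:10], event[1:10]),
               "constant")
})

test_that("a planted hazard step is recovered near the true threshold", {
  hits <- vapply(1:8, function(s) {
    set.seed(500 + s)
    n <- 400
    score <- rnorm(n)
    time <- rexp(n, 0.01 * exp(log(2) * (score > 0)))
    event <- rep(1L, n)
    cp <- optimalCutpoint(score, time, event, minprop = 0.1)
    band <- quantile(score, c(0.4, 0.6))
    cp@cutpoint >= band[1] && cp@cutpoint <= band[2]
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("the optional permutation p-value is honest under the null", {
  set.seed(61)
  n <- 60
  score <- rnorm(n)
  time <- rexp(n, 0.02); event <- rbinom(n, 1, 0.9)
  cp <- optimalCutpoint(score, time, event, permutationP = 99, seed = 3)
  permP <- attr(cp@scanTable, "permP")
  expect_gte(permP, 0.01)
  expect_lte(permP, 1)
})
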