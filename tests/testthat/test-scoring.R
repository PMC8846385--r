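test_that("signature building filters by Cox p and handles threshold saturation", {
  co <- smallCohort()
  x <- exprsMatrix(co); tr <- groundTruth(co); oc <- survivalOutcome(co)
  cand <- tr$degGenes[1:30]
  # threshold 1.0 keeps every candidate
  sigAll <- buildSignature(x, cand, oc$time, oc$event, coxPThreshold = 1.0)
  expect_setequal(sigAll@genes, cand)
  expect_equal(unname(colSums(sigAll@loadings^2)), c(1, 1), tolerance = 1e-9)
  expect_error(buildSignature(x, c("NOPE1", "NOPE2"), oc$time, oc$event),
               "no signature genes")
})

test_that("planted prognostic genes survive the Cox filter, nulls mostly do not", {
  set.seed(19)
  n <- 400
  z <- rnorm(n)                      # latent risk
  nNull <- 200; nProg <- 20
  x <- matrix(rnorm((nNull + nProg) * n), ncol = n,
              dimnames = list(c(sprintf("p%02d", 1:nProg),
                                sprintf("n%03d", 1:nNull)),
                              sprintf("s%03d", 1:n)))
  x[1:nProg, ] <- x[1:nProg, ] + matrix(z, nProg, n, byrow = TRUE)
  tEvent <- rexp(n, 0.01 * exp(0.5 * z))
  cens <- rexp(n, 0.004)
  time <- pmin(tEvent, cens); event <- as.integer(tEvent <= cens)
  sig <- buildSignature(x, rownames(x), time, event, coxPThreshold = 0.05)
  planted <- sprintf("p%02d", 1:nProg)
  expect_gte(mean(planted %in% sig@genes), 0.8)
  expect_lte(mean(sprintf("n%03d", 1:nNull) %in% sig@genes), 0.1)
})

test_that("rank-1 training matrices degrade gracefully to a PC1-only model", {
  set.seed(7)
  base <- rnorm(12)
  x <- outer(c(1, 2, 3), base) + 5    # exact rank 1 after centering
  rownames(x) <- paste0("g", 1:3); colnames(x) <- paste0("s", 1:12)
  time <- rexp(12, 0.1); event <- rep(1L, 12)
  expect_warning(
    sig <- buildSignature(x, rownames(x), time, event, coxPThreshold = 1.0),
    "rank 1")
  expect_true(sig@degenerate)
  expect_equal(sig@varExplained[1], 1, tolerance = 1e-9)
  expect_true(all(sig@loadings[, 2] == 0))
  sc <- m6aScore(sig, x)
  expect_true(all(is.finite(sc$score)))
})

test_that("scores are centered projections with a hand-checkable geometry", {
  co <- smallCohort()
  x <- exprsMatrix(co); tr <- groundTruth(co); oc <- survivalOutcome(co)
  sig <- buildSignature(x, tr$degGenes, oc$time, oc$event,
                        coxPThreshold = 1.0)
  sc <- m6aScore(sig, x)
  # training-cohort scores average zero (PCA centering identity)
  expect_equal(mean(sc$score), 0, tolerance = 1e-9)
  # a synthetic sample sitting exactly at the training mean scores zero
  meanCol <- x[, 1]
  meanCol[sig@genes] <- sig@center[sig@genes]
  xm <- cbind(x, meanSample = meanCol)
  scm <- m6aScore(sig, xm)
  expect_equal(scm$score[scm$sample_id == "meanSample"], 0,
               tolerance = 1e-9)
  # appending non-signature genes never changes the score
  extra <- rbind(x, NEWGENE = rnorm(ncol(x)))
  expect_equal(m6aScore(sig, extra)$score, sc$score, tolerance = 1e-12)
  # missing signature genes are a hard, named error
  expect_error(m6aScore(sig, x[setdiff(rownames(x), sig@genes[1]), ]),
               sig@genes[1])
})

test_that("a hand-built 2-gene model projects as loading-weighted z sums", {
  model <- new("SignatureModel", genes = c("gA", "gB"),
               center = c(gA = 1, gB = 2), scale = c(gA = 2, gB = 4),
               loadings = cbind(PC1 = c(1, 0), PC2 = c(0, 1)),
               varExplained = c(0.6, 0.4), degenerate = FALSE,
               trainingCohort = "toy")
  # sample with z = (1.5, -0.5): score = 1.5 + (-0.5) = 1.0
  x <- matrix(c(1 + 1.5 * 2, 2 + (-0.5) * 4), ncol = 1,
              dimnames = list(c("gA", "gB"), "s1"))
  expect_equal(m6aScore(model, x)$score, 1.0, tolerance = 1e-12)
})

test_that("rebuilding the signature on identical input is bit-stable", {
  co <- smallCohort()
  x <- exprsMatrix(co); tr <- groundTruth(co); oc <- survivalOutcome(co)
  a <- buildSignature(x, tr$degGenes, oc$time, oc$event)
  b <- buildSignature(x, tr$degGenes, oc$time, oc$event)
  expect_identical(a@loadings, b@loadings)
  expect_identical(m6aScore(a, x)$score, m6aScore(b, x)$score)
  # orientation: each component's loading sum is non-negative
  expect_gte(sum(a@loadings[, 1]), 0)
  expect_gte(sum(a@loadings[, 2]), 0)
})

test_that("the recovered score tracks the generative latent score", {
  co <- simulateM6ACohort(simulationConfig(nSamples = 400, nGenes = 1200,
                                           nDegPerCluster = 50, seed = 31))
  x <- exprsMatrix(co); tr <- groundTruth(co); oc <- survivalOutcome(co)
  fits <- moderatedTFit(x, tr$cluster)
  ov <- overlapDegs(lapply(fits, selectDegs))$overlap
  sig <- buildSignature(x, ov, oc$time, oc$event)
  sc <- m6aScore(sig, x)
  expect_gte(cor(sc$score, tr$latentScore, method = "spearman"), 0.7)
})

test_that("stratification finds score-linked survival differences and honest nulls", {
  co <- simulateM6ACohort(simulationConfig(nSamples = 400, nGenes = 1200,
                                           nDegPerCluster = 50, seed = 31))
  x <- exprsMatrix(co); tr <- groundTruth(co); oc <- survivalOutcome(co)
  sc <- data.frame(sample_id = names(tr$latentScore),
                   score = as.numeric(scale(tr$latentScore)))
  st <- stratifyByScore(sc, oc$time, oc$event)
  expect_lt(st$logrank$p, 0.01)
  expect_setequal(names(st$km), c("high", "low"))
  # negative score->hazard coefficient: the high group survives longer
  medSurv <- vapply(st$km, function(k) {
    i <- which(k$surv <= 0.5)[1]
    if (is.na(i)) Inf else k$time[i]
  }, numeric(1))
  expect_gt(medSurv["high"], medSurv["low"])

  # tiny cohort with an obvious split
  sc4 <- data.frame(sample_id = paste0("t", 1:8),
                    score = c(1, 2, 3, 4, 101, 102, 103, 104))
  st4 <- stratifyByScore(sc4, time = c(1, 2, 3, 4, 50, 60, 70, 80),
                         event = rep(1L, 8), minprop = 0.25)
  expect_true(all(st4$scores$group[st4$scores$score > 100] == "high"))
  expect_identical(st4$scores$group[1], "low")
  expect_lt(st4$cutpoint@cutpoint, 101)
})

test_that("hazard-neutral scores are not over-called once selection is corrected", {
  set.seed(77)
  res <- vapply(1:20, function(i) {
    n <- 80
    score <- rnorm(n)
    time <- rexp(n, 0.01); event <- rbinom(n, 1, 0.8)
    cp <- optimalCutpoint(score, time, event, permutationP = 99, seed = i)
    c(naive = abs(cp@statistic) > qnorm(0.975),
      corrected = attr(cp@scanTable, "permP") < 0.05)
  }, c(naive = TRUE, corrected = TRUE))
  # the naive maximally selected statistic is optimistic by construction;
  # the permutation p restores close-to-nominal behaviour
  expect_gt(mean(res["naive", ]), mean(res["corrected", ]) - 1e-9)
  expect_lte(mean(res["corrected", ]), 0.15)
})

test_that("regulator network classifies planted prognostic regulators", {
  co <- smallCohort()
  x <- exprsMatrix(co); oc <- survivalOutcome(co)
  net <- regulatorNetwork(x, oc$time, oc$event)
  expect_equal(nrow(net$pairs), choose(23, 2))
  expect_true(all(net$prognosis$class %in% c("favorable", "risk", "ns")))
  expect_true(all(abs(net$pairs$rho) <= 1))

  # a duplicated regulator correlates perfectly with its copy
  x2 <- rbind(x, FAKE24 = x["METTL3", ])
  cat24 <- new("RegulatorCatalog",
               roles = c(regulatorRoles(defaultRegulatorCatalog()),
                         FAKE24 = "reader"),
               aliases = c(KIAA1429 = "VIRMA"))
  net2 <- regulatorNetwork(x2, oc$time, oc$event, catalog = cat24)
  pair <- net2$pairs[net2$pairs$a == "METTL3" & net2$pairs$b == "FAKE24" |
                     net2$pairs$a == "FAKE24" & net2$pairs$b == "METTL3", ]
  expect_equal(pair$rho, 1, tolerance = 1e-12)

  # a strongly protective synthetic regulator is called favorable
  set.seed(55)
  n <- 400
  xp <- matrix(rnorm(23 * n), nrow = 23,
               dimnames = list(regulatorSymbols(defaultRegulatorCatalog()),
                               paste0("s", 1:n)))
  tEvent <- rexp(n, 0.01 * exp(-0.6 * xp["FTO", ]))
  fit <- regulatorNetwork(xp, tEvent, rep(1L, n))
  expect_identical(fit$prognosis$class[fit$prognosis$gene == "FTO"],
                   "favorable")
})

test_that("score-phenotype association tests match their closed forms", {
  # three groups of two with values 1..6 and no ties: the hand rank formula
  # gives H = 12/(6*7) * (2*1.5^2 + 2*3.5^2 + 2*5.5^2) - 3*7 = 32/7
  v <- 1:6; g <- rep(c("a", "b", "c"), each = 2)
  kw <- associateScore(v, g, kind = "kruskal")
  expect_equal(kw$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$statistic, oracleKruskalH(v, g), tolerance = 1e-12)

  # perfectly monotone pair: Spearman rho = 1
  sp <- associateScore(1:10, (1:10)^3, kind = "spearman")
  expect_equal(sp$estimate, 1, tolerance = 1e-12)

  # permuted copies of one group: H ~ 0, p ~ 1
  set.seed(3)
  vals <- rep(rnorm(5), 3)
  kw0 <- associateScore(vals, rep(c("x", "y", "z"), each = 5),
                        kind = "kruskal")
  expect_lt(kw0$statistic, 1e-10)

  # anova and wilcoxon dispatch
  av <- associateScore(c(v, v + 10), rep(c("a", "b"), each = 6),
                       kind = "anova")
  expect_lt(av$p, 0.01)
  wx <- associateScore(c(v, v + 10), rep(c("a", "b"), each = 6),
                       kind = "wilcoxon")
  expect_lt(wx$p, 0.01)
  expect_error(associateScore(v, rep("a", 6), kind = "kruskal"), ">= 2")
})
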