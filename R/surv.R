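## Survival statistics used throughout the workflow. Kaplan-Meier, log-rank
## and Cox fits delegate to the survival package (product-limit estimator,
## score test, Efron-tie partial likelihood); the maximally selected
## cutpoint is an exhaustive scan of the standardized two-group log-rank
## statistic over candidate thresholds.

.checkOutcome <- function(time, event) {
  if (!length(time)) stop("empty survival outcome")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(is.na(time)) || any(time < 0)) stop("time must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicator (1 = death observed).
#' @return data.frame: `time` (event-time grid), `surv`, `nRisk`, `nEvent`,
#'   `nCensor`. Survival starts at 1 and is non-increasing; censored times
#'   reduce the risk set without a step.
#' @export
kmEstimate <- function(time, event) {
  .checkOutcome(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
             nEvent = fit$n.event, nCensor = fit$n.censor)
}

#' Log-rank test between two or more groups
#'
#' Standard observed-minus-expected statistic over the pooled event-time
#' grid, `df = groups - 1`, p from the upper chi-square tail.
#'
#' @param time,event survival outcome.
#' @param group per-subject group labels (>= 2 non-empty groups).
#' @return list: `statistic`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  .checkOutcome(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("need >= 2 non-empty groups")
  if (any(table(group) == 0L)) group <- droplevels(group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson with Efron tie handling (Breslow
#' available for cross-checks). Perfect separation / non-convergence is
#' flagged in the `converged` column rather than raised.
#'
#' @param time,event survival outcome.
#' @param covariates data.frame (or named vector for a single covariate) of
#'   finite, non-constant columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return data.frame, one row per covariate: beta, HR, se, z, p, lower95,
#'   upper95, converged.
#' @export
coxFit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .checkOutcome(time, event)
  if (sum(event) < 1L) stop("no events: Cox model unidentifiable")
  if (!is.data.frame(covariates))
    covariates <- data.frame(covariate = covariates)
  for (nm in colnames(covariates)) {
    v <- covariates[[nm]]
    if (any(!is.finite(v))) stop("covariate '", nm, "' has non-finite values")
    if (length(unique(v)) < 2L) stop("covariate '", nm, "' is constant")
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ ., data = covariates,
                    ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50L)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ ., data = covariates,
                        ties = ties,
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 50L)))
      attr(f, "m6aWarning") <- conditionMessage(w)
      f
    })
  s <- summary(fit)
  beta <- s$coefficients[, "coef"]
  se <- s$coefficients[, "se(coef)"]
  converged <- is.null(attr(fit, "m6aWarning")) &&
    all(is.finite(beta)) && all(is.finite(se)) && all(abs(beta) < 20)
  data.frame(
    covariate = rownames(s$coefficients),
    beta = unname(beta), hr = unname(exp(beta)), se = unname(se),
    z = unname(beta / se),
    p = unname(s$coefficients[, "Pr(>|z|)"]),
    lower95 = unname(exp(beta - qnorm(0.975) * se)),
    upper95 = unname(exp(beta + qnorm(0.975) * se)),
    converged = converged,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Univariate Cox screen across many genes
#'
#' Runs one univariate Cox fit per gene row of an expression matrix against
#' the same outcome; the workhorse behind the prognostic DEG filter and the
#' regulator prognostic classification.
#'
#' @param x expression matrix (genes x samples) or [M6ACohort-class].
#' @param time,event survival outcome aligned to the columns of `x`.
#' @param ties passed to [coxFit()].
#' @return data.frame, one row per gene: gene, beta, hr, se, z, p,
#'   converged.
#' @export
uniCoxScreen <- function(x, time, event, ties = "efron") {
  x <- exprsMatrix(x)
  res <- lapply(rownames(x), function(g) {
    v <- x[g, ]
    if (length(unique(v)) < 2L)
      return(data.frame(gene = g, beta = NA_real_, hr = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    ft <- coxFit(time, event, data.frame(expr = v), ties = ties)
    data.frame(gene = g, beta = ft$beta, hr = ft$hr, se = ft$se, z = ft$z,
               p = ft$p, converged = ft$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# standardized log-rank statistic (O - E) / sqrt(V) for a binary split
.standardizedLogrank <- function(time, event, highSide) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ highSide)
  # statistic for the 'TRUE' (high) group; sign > 0 means more events than
  # expected in the high group
  oe <- sd$obs[2L] - sd$exp[2L]
  v <- if (is.matrix(sd$var)) sd$var[2L, 2L] else sd$var
  if (v <= 0) return(0)
  oe / sqrt(v)
}

# standardized log-rank statistic for every candidate threshold at once:
# for each unique event time u and candidate c, the at-risk and death
# counts of the high group (score > c) are joint indicator products,
# assembled by two matrix multiplications
.scanLogrank <- function(time, event, score, candidates) {
  u <- sort(unique(time[event == 1]))
  atRisk <- outer(u, time, `<=`)                   # U x n
  dying <- outer(u, time, `==`) & matrix(event == 1, length(u),
                                         length(time), byrow = TRUE)
  high <- outer(score, candidates, `>`)            # n x C
  nt <- rowSums(atRisk)
  dt <- rowSums(dying)
  n2 <- atRisk %*% high                            # U x C
  d2 <- dying %*% high
  p2 <- n2 / nt
  oMinusE <- colSums(d2 - dt * p2)
  vt <- dt * p2 * (1 - p2) * ifelse(nt > 1, (nt - dt) / (nt - 1), 0)
  v <- colSums(vt)
  ifelse(v > 0, oMinusE / sqrt(v), 0)
}

#' Maximally selected survival cutpoint
#'
#' Scans every distinct score value inside the
#' `[quantile(minprop), quantile(1 - minprop)]` window; at each candidate
#' the cohort is split into high (score > cut) and low (score <= cut) and
#' the standardized two-group log-rank statistic is computed. The cutpoint
#' maximises the absolute statistic; ties resolve to the smaller cutpoint.
#' The selection-maximised statistic is reported without multiple-looks
#' correction (an optional permutation p-value is available).
#'
#' @param score per-sample continuous marker (non-constant).
#' @param time,event survival outcome.
#' @param minprop minimum proportion of samples on each side (default 0.1).
#' @param permutationP number of permutations for an optional
#'   selection-corrected p-value (0 = skip, default).
#' @param seed RNG seed for the permutation p.
#' @return a [CutpointResult-class]; with `permutationP > 0` the scan table
#'   gains an attribute `permP`.
#' @export
optimalCutpoint <- function(score, time, event, minprop = 0.1,
                            permutationP = 0L, seed = 1L) {
  .checkOutcome(time, event)
  if (length(score) != length(time)) stop("score and outcome lengths differ")
  if (length(unique(score)) < 2L) stop("score is constant; no cutpoint exists")
  lo <- quantile(score, minprop, type = 7)
  hi <- quantile(score, 1 - minprop, type = 7)
  cand <- sort(unique(score))
  cand <- cand[cand >= lo & cand <= hi & cand < max(score)]
  if (!length(cand)) stop("no admissible cutpoint inside the minprop window")
  stat <- .scanLogrank(time, event, score, cand)
  best <- which.max(abs(stat))   # first index on ties -> smaller cutpoint
  scan <- data.frame(cutpoint = cand, statistic = stat)
  res <- new("CutpointResult", cutpoint = cand[best],
             statistic = stat[best], scanTable = scan, minprop = minprop)
  if (permutationP > 0L) {
    set.seed(as.integer(seed))
    obs <- abs(stat[best])
    exceed <- 0L
    for (b in seq_len(permutationP)) {
      sp <- sample(score)
      sb <- max(abs(.scanLogrank(time, event, sp, cand)))
      if (sb >= obs) exceed <- exceed + 1L
    }
    attr(res@scanTable, "permP") <- (exceed + 1) / (permutationP + 1)
  }
  res
}

setMethod("show", "CutpointResult", function(object) {
  cat("CutpointResult: cutpoint =", format(object@cutpoint, digits = 7),
      "| standardized log-rank =", round(object@statistic, 3), "\n")
  cat(nrow(object@scanTable), "candidates scanned, minprop =",
      object@minprop, "; high group = score > cutpoint\n")
})
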