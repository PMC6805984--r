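## Statistical pipeline: Spearman correlation structure, univariate
## logistic screening, VIF collinearity exclusion, forward stepwise
## multivariate logistic regression with Hosmer-Lemeshow calibration,
## and the frozen published prediction equations.
##
## Ordinal stratum codes enter all models as numeric scores (one
## coefficient per factor): exponentials of the published equation
## coefficients reproduce the published per-stratum odds ratios, which
## pins down that parameterization.

#' Spearman rank correlations for a list of factor pairs
#'
#' Tie-corrected Spearman correlation with a two-sided p-value from the
#' t approximation, one row per requested pair.
#'
#' @param tab data.frame of numeric columns.
#' @param pairs list of character pairs, or a 2-column matrix; default
#'   all column pairs.
#' @return data.frame with columns `var1`, `var2`, `rs`, `p`.
#' @examples
#' spearmanMatrix(data.frame(x = 1:5, y = c(2, 1, 4, 3, 5)))
#' @export
spearmanMatrix <- function(tab, pairs = NULL) {
  if (is.null(pairs)) {
    nm <- names(tab)
    pairs <- utils::combn(nm, 2, simplify = FALSE)
  } else if (is.matrix(pairs)) {
    pairs <- split(pairs, row(pairs))
  }
  rows <- lapply(pairs, function(pr) {
    x <- tab[[pr[1]]]; y <- tab[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) stop("need >= 3 complete observations for ",
                          pr[1], " vs ", pr[2])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("constant column in pair ", pr[1], " vs ", pr[2],
           ": correlation undefined")
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(var1 = pr[1], var2 = pr[2],
               rs = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

## Wald summary of one glm coefficient.
waldRow <- function(fit, term, level = 0.95) {
  sm <- summary(fit)$coefficients
  b <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(coef = b, se = se, or = exp(b),
       ci = exp(c(b - zq * se, b + zq * se)),
       p = sm[term, "Pr(>|z|)"])
}

separationSuspected <- function(fit, bound = 20) {
  !fit$converged || any(abs(stats::coef(fit)[-1]) > bound)
}

#' Univariate logistic regression of outcome on one ordinal code
#'
#' Maximum-likelihood logistic fit of a binary outcome on a single
#' numeric (coded) predictor; reports the per-stratum odds ratio
#' `exp(slope)` with its Wald 95% CI and p-value. Complete separation is
#' flagged rather than silently returning a diverged fit.
#'
#' @param x numeric predictor (ordinal code).
#' @param y binary outcome (0/1), both classes present.
#' @return list with `factor`, `or`, `ci95`, `p`, `coef`, `separation`.
#' @export
univariateLogistic <- function(x, y) {
  y <- as.integer(y)
  if (length(unique(y[!is.na(y)])) != 2L)
    stop("outcome must contain both classes")
  if (stats::sd(x, na.rm = TRUE) == 0) stop("predictor is constant")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  w <- waldRow(fit, "x")
  sep <- separationSuspected(fit)
  if (sep) warning("possible complete separation in univariate fit")
  list(factor = deparse(substitute(x)), or = w$or, ci95 = w$ci, p = w$p,
       coef = w$coef, separation = sep)
}

#' Univariate screening table for a coded design
#'
#' @param design data.frame of coded predictors.
#' @param outcome binary outcome vector.
#' @return data.frame with one row per factor: `or`, `p`, `ci_low`,
#'   `ci_high`, `separation`.
#' @export
univariateTable <- function(design, outcome) {
  rows <- lapply(names(design), function(nm) {
    u <- univariateLogistic(design[[nm]], outcome)
    data.frame(factor = nm, or = u$or, p = u$p,
               ci_low = u$ci95[1], ci_high = u$ci95[2],
               separation = u$separation)
  })
  do.call(rbind, rows)
}

vifOnce <- function(design) {
  vapply(names(design), function(nm) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(names(design), nm),
                                               nm), data = design))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Collinearity screen by variance inflation factors
#'
#' VIF_j = 1/(1 - R^2_j) from regressing factor j on the remaining
#' factors (no outcome involved). Factors at or above the threshold are
#' excluded one at a time, highest VIF first, re-screening after each
#' exclusion until every remaining VIF is below the threshold — the
#' procedure that removes one member of a near-duplicate volume pair
#' such as coded ATV/RTV. An exactly dependent factor reports an
#' infinite VIF.
#'
#' @param design data.frame of numeric predictors (>= 2 columns, more
#'   rows than columns).
#' @param threshold exclusion threshold (default 10).
#' @return list with `vif` (initial VIFs), `excluded` (in exclusion
#'   order), `kept`, `finalVif`, `threshold`.
#' @export
vifScreen <- function(design, threshold = 10) {
  if (ncol(design) < 2L) stop("need at least 2 factors")
  if (nrow(design) <= ncol(design)) stop("need more rows than factors")
  initial <- vifOnce(design)
  excluded <- character(0)
  current <- design
  repeat {
    v <- vifOnce(current)
    if (max(v) < threshold || ncol(current) <= 2L) break
    worst <- names(which.max(v))
    excluded <- c(excluded, worst)
    current <- current[setdiff(names(current), worst)]
  }
  list(vif = initial, excluded = excluded, kept = names(current),
       finalVif = vifOnce(current), threshold = threshold)
}

#' Forward stepwise logistic regression with likelihood-ratio entry
#'
#' Iteratively adds the candidate with the smallest likelihood-ratio
#' entry p-value below `pEnter`, then removes any included factor whose
#' removal p-value exceeds `pRemove`, until no change. Returns the final
#' maximum-likelihood fit with per-factor odds ratios, Wald 95% CIs and
#' p-values, Hosmer-Lemeshow calibration, and fitted probabilities. If
#' no factor enters, the intercept-only fit is returned with a notice.
#'
#' @param design data.frame of numeric (coded) predictors, typically
#'   post-VIF.
#' @param outcome binary outcome vector.
#' @param pEnter likelihood-ratio entry threshold (default 0.05).
#' @param pRemove removal threshold (default 0.10).
#' @param hlGroups groups for the Hosmer-Lemeshow test (default 10).
#' @return list with `included`, `intercept`, `table` (coef/or/ci/p per
#'   factor), `fit` (the glm), `hl` (statistic/df/p), `fitted`,
#'   `logLikTrace`.
#' @export
forwardStepwiseLogistic <- function(design, outcome, pEnter = 0.05,
                                    pRemove = 0.10, hlGroups = 10) {
  dat <- data.frame(design, check.names = FALSE)
  dat$.y <- as.integer(outcome)
  factors <- names(design)
  included <- character(0)
  refit <- function(terms) {
    f <- if (length(terms)) stats::reformulate(terms, ".y") else
      stats::as.formula(".y ~ 1")
    suppressWarnings(stats::glm(f, family = stats::binomial(), data = dat))
  }
  fit <- refit(included)
  trace <- as.numeric(stats::logLik(fit))
  repeat {
    changed <- FALSE
    cand <- setdiff(factors, included)
    if (length(cand)) {
      a <- stats::add1(fit, scope = stats::reformulate(c(included, cand)),
                       test = "LRT")
      p <- a[["Pr(>Chi)"]][-1]
      names(p) <- rownames(a)[-1]
      if (any(!is.na(p) & p < pEnter)) {
        best <- names(which.min(p))
        included <- c(included, best)
        fit <- refit(included)
        trace <- c(trace, as.numeric(stats::logLik(fit)))
        changed <- TRUE
      }
    }
    if (length(included)) {
      d <- stats::drop1(fit, test = "LRT")
      p <- d[["Pr(>Chi)"]][-1]
      names(p) <- rownames(d)[-1]
      if (any(!is.na(p) & p > pRemove)) {
        worst <- names(which.max(p))
        included <- setdiff(included, worst)
        fit <- refit(included)
        trace <- c(trace, as.numeric(stats::logLik(fit)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(included))
    message("no factor met the entry criterion; returning intercept-only fit")
  tab <- NULL
  if (length(included)) {
    rows <- lapply(included, function(tm) {
      w <- waldRow(fit, tm)
      data.frame(factor = tm, coef = w$coef, or = w$or,
                 ci_low = w$ci[1], ci_high = w$ci[2], p = w$p)
    })
    tab <- do.call(rbind, rows)
  }
  hl <- hosmerLemeshow(stats::fitted(fit), dat$.y, groups = hlGroups)
  list(included = included, intercept = unname(stats::coef(fit)["(Intercept)"]),
       table = tab, fit = fit, hl = hl,
       fitted = unname(stats::fitted(fit)), logLikTrace = trace,
       separation = separationSuspected(fit))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping by predicted probability (ties kept in one
#' group), Pearson-type statistic `sum (O - E)^2 / (E (1 - E/n_g))` over
#' groups, upper-tail chi-square p-value on `groups - 2` degrees of
#' freedom. If there are fewer distinct probabilities than requested
#' groups, the group count is reduced with a warning.
#'
#' @param probabilities predicted probabilities in (0, 1).
#' @param outcomes binary outcomes.
#' @param groups number of risk groups (default 10, >= 2).
#' @return list with `statistic`, `df`, `p`, `groups`.
#' @export
hosmerLemeshow <- function(probabilities, outcomes, groups = 10) {
  p <- as.numeric(probabilities); y <- as.integer(outcomes)
  if (any(p <= 0 | p >= 1)) stop("probabilities must be strictly in (0, 1)")
  if (groups < 2) stop("need at least 2 groups")
  nd <- length(unique(p))
  if (nd < groups) {
    warning("fewer distinct probabilities (", nd, ") than groups; reducing")
    groups <- max(1L, nd)
  }
  br <- unique(stats::quantile(p, seq(0, 1, length.out = groups + 1)))
  g <- if (length(br) > 2) cut(p, br, include.lowest = TRUE)
       else factor(rep(1L, length(p)))
  O <- tapply(y, g, sum)
  E <- tapply(p, g, sum)
  n <- tapply(p, g, length)
  keep <- !is.na(O)
  O <- O[keep]; E <- E[keep]; n <- n[keep]
  denom <- E * (1 - E / n)
  term <- ifelse(abs(O - E) < 1e-12, 0, (O - E)^2 / denom)
  stat <- sum(term)
  df <- length(O) - 2L
  pval <- if (df < 1L) {
    if (stat < 1e-12) 1 else NA_real_
  } else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = unname(stat), df = df, p = unname(pval),
       groups = length(O))
}

publishedConstants <- list(
  Z1 = list(cohort = "all", intercept = -1.705, volumeTerm = "rtv_code",
            volumeCoef = -1.298, tcCoef = 1.2999),
  Z2 = list(cohort = "all", intercept = -1.620, volumeTerm = "atv_code",
            volumeCoef = -1.235, tcCoef = 1.293),
  Z3 = list(cohort = "non_mucinous", intercept = -1.429,
            volumeTerm = "rtv_code", volumeCoef = -1.227, tcCoef = 1.164),
  Z4 = list(cohort = "non_mucinous", intercept = -1.323,
            volumeTerm = "atv_code", volumeCoef = -1.19, tcCoef = 1.147))

#' A frozen published pCR prediction equation
#'
#' `Z1`/`Z2` were fitted on all patients and `Z3`/`Z4` on the
#' non-mucinous adenocarcinoma subgroup; `Z1`/`Z3` use the coded real
#' tumor volume and `Z2`/`Z4` the coded approximate tumor volume, each
#' with the coded tumor compactness.
#'
#' @param name "Z1", "Z2", "Z3" or "Z4".
#' @return a [PublishedModel-class].
#' @examples
#' evaluatePublishedModel(publishedModel("Z1"), volumeCode = 2, tcCode = 2)
#' @export
publishedModel <- function(name = c("Z1", "Z2", "Z3", "Z4")) {
  name <- match.arg(name)
  k <- publishedConstants[[name]]
  new("PublishedModel", name = name, cohort = k$cohort,
      intercept = k$intercept, volumeTerm = k$volumeTerm,
      volumeCoef = k$volumeCoef, tcCoef = k$tcCoef)
}

#' Predicted pCR probability from a published equation
#'
#' `plogis(intercept + volumeCoef * volumeCode + tcCoef * tcCode)`.
#' Codes must lie in their stratum ranges (volume codes 1..5, TC codes
#' 1..5).
#'
#' @param model a [PublishedModel-class].
#' @param volumeCode coded RTV (Z1/Z3) or ATV (Z2/Z4), in 1..5.
#' @param tcCode coded tumor compactness, in 1..5.
#' @return probability in (0, 1).
#' @export
evaluatePublishedModel <- function(model, volumeCode, tcCode) {
  if (any(!volumeCode %in% 1:5))
    stop(model@volumeTerm, " must be an integer code in 1..5")
  if (any(!tcCode %in% 1:5))
    stop("tc_code must be an integer code in 1..5")
  stats::plogis(model@intercept + model@volumeCoef * volumeCode +
                model@tcCoef * tcCode)
}

#' Odds ratios implied by a published equation
#'
#' Exponentials of the equation's coefficients (and intercept), for
#' comparison against the printed multivariate odds-ratio columns.
#'
#' @param model a [PublishedModel-class].
#' @return named numeric: the volume-term OR, the TC OR, and the
#'   intercept's odds.
#' @export
publishedOrConsistency <- function(model) {
  out <- c(exp(model@volumeCoef), exp(model@tcCoef), exp(model@intercept))
  names(out) <- c(model@volumeTerm, "tc_code", "constant")
  out
}
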