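test_that("Spearman correlations reproduce hand-computed values", {
  tab <- data.frame(x = 1:5, y = c(2, 1, 4, 3, 5))
  res <- spearmanMatrix(tab)
  expect_equal(res$rs, 0.8)                       # 1 - 6*4/(5*24)
  expect_equal(spearmanMatrix(data.frame(a = 1:6, b = (1:6)^3))$rs, 1)
  set.seed(8)
  z <- data.frame(u = rnorm(30), v = rnorm(30))
  expect_equal(spearmanMatrix(z, list(c("u", "v")))$rs,
               spearmanMatrix(z, list(c("v", "u")))$rs)
  # cross-check the p-value against the stats oracle
  ct <- suppressWarnings(cor.test(z$u, z$v, method = "spearman",
                                  exact = FALSE))
  expect_equal(spearmanMatrix(z, list(c("u", "v")))$p, ct$p.value)
  expect_error(spearmanMatrix(data.frame(a = rep(1, 5), b = 1:5)),
               "constant")
  expect_error(spearmanMatrix(data.frame(a = 1:2, b = 2:1)), ">= 3")
})

test_that("univariate logistic OR equals the 2x2 cross-product ratio", {
  x <- rep(c(1, 0), c(15, 15))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  u <- univariateLogistic(x, y)
  expect_equal(u$or, 4.0, tolerance = 1e-6)
  expect_true(u$ci95[1] <= u$or && u$or <= u$ci95[2])
  # translation of the predictor leaves the slope unchanged
  u2 <- univariateLogistic(x + 3, y)
  expect_equal(u2$or, u$or, tolerance = 1e-9)
  # outcome independent of predictor: OR exactly 1 for balanced rates
  x3 <- rep(1:3, each = 20)
  y3 <- rep(rep(c(1, 0), c(5, 15)), 3)
  expect_equal(univariateLogistic(x3, y3)$or, 1.0, tolerance = 1e-9)
  expect_error(univariateLogistic(x, rep(1, 30)), "both classes")
  expect_error(univariateLogistic(rep(2, 30), y), "constant")
})

test_that("complete separation is flagged rather than silently diverging", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- c(rep(0, 10), rep(1, 10))
  expect_warning(u <- univariateLogistic(x, y), "separation")
  expect_true(u$separation)
})

test_that("VIF is 1 for orthogonal columns and infinite for exact copies", {
  d <- data.frame(a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4),
                  c = rep(c(-1, 1), each = 8))
  v <- vifScreen(d)
  expect_equal(unname(v$vif), rep(1, 3), tolerance = 1e-9)
  expect_length(v$excluded, 0)
  set.seed(3)
  x <- rnorm(40)
  d2 <- data.frame(x1 = x, x2 = x + rnorm(40, 0, 1e-6 * sd(x)),
                   z = rnorm(40))
  v2 <- vifScreen(d2)
  expect_gt(max(v2$vif[c("x1", "x2")]), 10)
  expect_true(any(c("x1", "x2") %in% v2$excluded))
  expect_lt(max(v2$finalVif), 10)
  d3 <- data.frame(p = x, q = 2 * x, r = rnorm(40))
  expect_true(is.infinite(max(suppressWarnings(vifScreen(d3))$vif)))
  expect_error(vifScreen(d2[, 1, drop = FALSE]), "2 factors")
})

test_that("VIF agrees with the car oracle on a well-conditioned design", {
  set.seed(21)
  d <- data.frame(a = rnorm(60), b = rnorm(60))
  d$c <- 0.6 * d$a + rnorm(60, 0, 0.7)
  v <- vifScreen(d)
  y <- rnorm(60)
  ref <- car::vif(lm(y ~ a + b + c, data = d))
  expect_equal(unname(v$vif), unname(ref), tolerance = 1e-8)
})

test_that("forward stepwise recovers a single strong signal", {
  set.seed(501)
  clean <- 0L
  for (rep_ in 1:100) {
    n <- 500
    x1 <- sample(1:5, n, TRUE)
    noise1 <- sample(1:5, n, TRUE)
    noise2 <- sample(1:3, n, TRUE)
    y <- rbinom(n, 1, plogis(-1.5 + 1 * x1))
    fit <- forwardStepwiseLogistic(data.frame(x1 = x1, n1 = noise1,
                                              n2 = noise2), y)
    if (identical(fit$included, "x1")) clean <- clean + 1L
  }
  expect_gte(clean, 90L)
})

test_that("stepwise returns the intercept-only model under the global null", {
  set.seed(502)
  nullOnly <- 0L
  for (rep_ in 1:60) {
    n <- 300
    d <- data.frame(a = sample(1:5, n, TRUE), b = sample(1:4, n, TRUE),
                    c = sample(1:3, n, TRUE))
    y <- rbinom(n, 1, 0.3)
    fit <- suppressWarnings(suppressMessages(forwardStepwiseLogistic(d, y)))
    if (!length(fit$included)) nullOnly <- nullOnly + 1L
  }
  # three independent entry tests at 0.05 keep the null model ~0.95^3
  expect_gt(nullOnly / 60, 0.72)
  expect_lt(nullOnly / 60, 0.99)
})

test_that("each stepwise addition increases the log-likelihood", {
  co <- simulateCohort(cohortSpec(nPatients = 400L), seed = 14,
                       method = "analytic")
  codes <- codePredictors(clinicalTable(co), featureTable(co))
  fit <- suppressMessages(
    forwardStepwiseLogistic(codes[c("rtv_code", "tc_code", "age_code",
                                    "cea_code")],
                            clinicalTable(co)$pcr))
  expect_true(all(diff(fit$logLikTrace) > 0))
  expect_equal(unname(exp(fit$table$coef)), fit$table$or, tolerance = 1e-12)
})

test_that("stepwise on a cohort from the published generative model selects volume and compactness", {
  co <- simulateCohort(cohortSpec(nPatients = 2000L), seed = 90,
                       method = "analytic")
  codes <- codePredictors(clinicalTable(co), featureTable(co))
  design <- codes[setdiff(names(codes), "atv_code")]
  fit <- forwardStepwiseLogistic(design, clinicalTable(co)$pcr)
  expect_true(all(c("rtv_code", "tc_code") %in% fit$included))
  tab <- fit$table
  expect_lt(tab$coef[tab$factor == "rtv_code"], 0)
  expect_gt(tab$coef[tab$factor == "tc_code"], 0)
  # +/- 3 standard errors around the generative coefficients
  sm <- summary(fit$fit)$coefficients
  expect_lt(abs(sm["rtv_code", 1] - (-1.298)) / sm["rtv_code", 2], 3)
  expect_lt(abs(sm["tc_code", 1] - 1.2999) / sm["tc_code", 2], 3)
})

test_that("Hosmer-Lemeshow is exact under perfect calibration", {
  p <- rep(c(0.2, 0.4, 0.6, 0.8), each = 5)
  y <- c(rep(c(1, 0), c(1, 4)), rep(c(1, 0), c(2, 3)),
         rep(c(1, 0), c(3, 2)), rep(c(1, 0), c(4, 1)))
  expect_warning(hl <- hosmerLemeshow(p, y, groups = 10), "reducing")
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p, 1)
  # all probabilities identical and matching the event rate
  expect_warning(hl1 <- hosmerLemeshow(rep(0.25, 20), rep(c(1, 0), c(5, 15))),
                 "reducing")
  expect_equal(hl1$statistic, 0)
  expect_error(hosmerLemeshow(c(0, 0.5), c(0, 1)), "strictly")
})

test_that("Hosmer-Lemeshow holds its nominal level under a correct model", {
  set.seed(777)
  rejections <- 0L
  for (rep_ in 1:200) {
    n <- 500
    x <- runif(n, -2, 2)
    y <- rbinom(n, 1, plogis(-0.5 + x))
    fit <- glm(y ~ x, family = binomial())
    hl <- hosmerLemeshow(fitted(fit), y)
    if (hl$p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 200, 0.01)
  expect_lte(rejections / 200, 0.10)
})

test_that("published equations evaluate to their hand-computed probabilities", {
  expect_equal(evaluatePublishedModel(publishedModel("Z1"), 2, 2),
               0.154309, tolerance = 1e-5)
  expect_equal(evaluatePublishedModel(publishedModel("Z2"), 1, 5),
               0.973661, tolerance = 1e-5)
  z1 <- publishedModel("Z1")
  probsTc <- evaluatePublishedModel(z1, 2, 1:5)
  probsVol <- evaluatePublishedModel(z1, 1:5, 2)
  expect_true(all(diff(probsTc) > 0))
  expect_true(all(diff(probsVol) < 0))
  expect_error(evaluatePublishedModel(z1, 6, 2), "1..5")
  expect_error(evaluatePublishedModel(z1, 2, 0), "1..5")
})

test_that("exponentiated published coefficients match the printed odds ratios", {
  printed <- list(
    Z1 = c(0.273, 3.667, 0.182),
    Z2 = c(0.291, 3.643, 0.198),
    Z3 = c(0.293, 3.203, 0.240),
    Z4 = c(0.304, 3.148, 0.266))
  for (nm in names(printed)) {
    ors <- publishedOrConsistency(publishedModel(nm))
    expect_equal(unname(ors), printed[[nm]], tolerance = 0.002,
                 label = nm)
  }
})

test_that("multivariate Wald CIs cover the generative coefficients", {
  covered_rtv <- 0L; covered_tc <- 0L
  nrep <- 100L
  for (r in seq_len(nrep)) {
    co <- simulateCohort(cohortSpec(nPatients = 500L), seed = 9000 + r,
                         method = "analytic")
    codes <- codePredictors(clinicalTable(co), featureTable(co))
    fit <- glm(clinicalTable(co)$pcr ~ rtv_code + tc_code, data = codes,
               family = binomial())
    sm <- summary(fit)$coefficients
    ci <- function(term) sm[term, 1] + c(-1.96, 1.96) * sm[term, 2]
    if (-1.298 >= ci("rtv_code")[1] && -1.298 <= ci("rtv_code")[2])
      covered_rtv <- covered_rtv + 1L
    if (1.2999 >= ci("tc_code")[1] && 1.2999 <= ci("tc_code")[2])
      covered_tc <- covered_tc + 1L
  }
  expect_gte(covered_rtv / nrep, 0.90); expect_lte(covered_rtv / nrep, 0.99)
  expect_gte(covered_tc / nrep, 0.90); expect_lte(covered_tc / nrep, 0.99)
})
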