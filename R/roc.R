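## ROC analysis of a score against pCR: curve, AUC, Youden-optimal
## cutoff and the sensitivity/specificity/PPV/NPV panel.
##
## Positivity convention: under "positive" orientation a score >= cutoff
## is test-positive; negatively oriented features (larger volume
## predicts failure to achieve pCR) use score <= cutoff, so reported
## cutoffs stay on the feature's natural scale.

checkTwoClasses <- function(labels) {
  u <- unique(labels[!is.na(labels)])
  if (length(u) != 2L)
    stop("labels must contain both classes")
}

#' Area under the ROC curve (raw orientation)
#'
#' Trapezoidal area for the "higher score = positive" convention, equal
#' to the fraction of positive-negative pairs won by the positive
#' (ties counting 1/2, the Mann-Whitney statistic).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @examples
#' aucValue(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
aucValue <- function(scores, labels) {
  labels <- as.integer(labels)
  checkTwoClasses(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve over all distinct thresholds
#'
#' One operating point per distinct score value plus -Inf/+Inf
#' sentinels. With `orientation = "auto"` the orientation is chosen so
#' the AUC is >= 0.5 and reported; thresholds are always on the score's
#' natural scale.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), both classes present.
#' @param orientation "auto", "positive" (score >= t positive) or
#'   "negative" (score <= t positive).
#' @return a [ROCResult-class] with `points`, `auc` and `orientation`
#'   filled (cutoff/panel slots are NA until [rocPanel()]).
#' @export
rocCurve <- function(scores, labels, orientation = c("auto", "positive",
                                                     "negative")) {
  orientation <- match.arg(orientation)
  labels <- as.integer(labels)
  checkTwoClasses(labels)
  if (orientation == "auto") {
    orientation <- if (aucValue(scores, labels) >= 0.5) "positive"
                   else "negative"
  }
  s <- if (orientation == "negative") -scores else scores
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  pos <- s[labels == 1L]; neg <- s[labels == 0L]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  natThr <- if (orientation == "negative") -thr else thr
  pts <- data.frame(threshold = natThr, sensitivity = sens,
                    specificity = spec)
  ## trapezoid over (FPR, TPR); points are already ordered by increasing FPR
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  new("ROCResult", points = pts, auc = auc, orientation = orientation,
      cutoff = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
      ppv = NA_real_, npv = NA_real_,
      prevalence = mean(labels == 1L))
}

#' Optimal ROC cutoff
#'
#' Maximizes the Youden index J = sensitivity + specificity - 1 (the
#' default criterion) or minimizes the distance to the (0, 1) corner
#' (`criterion = "closest"`). Ties are broken toward the operating point
#' with higher sensitivity, then toward the lower threshold on the
#' score's natural scale. Sentinel thresholds are never selected for a
#' non-degenerate curve.
#'
#' @param roc a [ROCResult-class] from [rocCurve()].
#' @param criterion "youden" or "closest".
#' @return the optimal threshold (natural scale).
#' @export
optimalCutoff <- function(roc, criterion = c("youden", "closest")) {
  criterion <- match.arg(criterion)
  pts <- roc@points[is.finite(roc@points$threshold), , drop = FALSE]
  score <- switch(criterion,
    youden = pts$sensitivity + pts$specificity - 1,
    closest = -sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2))
  ## round away floating-point noise so exact ties break as documented
  ord <- order(-round(score, 10), -round(pts$sensitivity, 10),
               pts$threshold)
  pts$threshold[ord[1]]
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Bayes' formulas: `PPV = se p / (se p + (1 - sp)(1 - p))` and
#' `NPV = sp (1 - p) / (sp (1 - p) + (1 - se) p)`.
#'
#' @param sensitivity,specificity,prevalence values in (0, 1)
#'   (prevalence strictly interior; boundary sensitivity/specificity are
#'   allowed when the denominators stay positive).
#' @return named numeric `c(ppv, npv)`.
#' @examples
#' predictiveValues(0.85, 0.8983, 20 / 79)
#' @export
predictiveValues <- function(sensitivity, specificity, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be strictly inside (0, 1)")
  dPos <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  dNeg <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (dPos == 0) stop("no test-positives: PPV undefined")
  if (dNeg == 0) stop("no test-negatives: NPV undefined")
  c(ppv = sensitivity * prevalence / dPos,
    npv = specificity * (1 - prevalence) / dNeg)
}

#' Confusion matrix and metric panel at a cutoff
#'
#' Counts TP/FP/TN/FN at the cutoff (score >= cutoff test-positive under
#' positive orientation, score <= cutoff under negative orientation) and
#' the empirical sensitivity, specificity, PPV and NPV. The empirical
#' PPV/NPV coincide exactly with [predictiveValues()] applied to the
#' empirical sensitivity, specificity and prevalence.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), both classes present.
#' @param cutoff threshold on the natural scale.
#' @param orientation "positive" or "negative".
#' @return list with `table` (TP/FP/TN/FN), `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `prevalence`.
#' @export
confusionAtCutoff <- function(scores, labels, cutoff,
                              orientation = c("positive", "negative")) {
  orientation <- match.arg(orientation)
  labels <- as.integer(labels)
  checkTwoClasses(labels)
  testPos <- if (orientation == "positive") scores >= cutoff
             else scores <= cutoff
  tp <- sum(testPos & labels == 1L); fp <- sum(testPos & labels == 0L)
  fn <- sum(!testPos & labels == 1L); tn <- sum(!testPos & labels == 0L)
  list(table = c(TP = tp, FP = fp, TN = tn, FN = fn),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       prevalence = mean(labels == 1L))
}

#' Full ROC panel for one score
#'
#' ROC curve, AUC, optimal cutoff and the empirical
#' sensitivity/specificity/PPV/NPV panel at that cutoff.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1).
#' @param orientation passed to [rocCurve()].
#' @param criterion passed to [optimalCutoff()].
#' @return a completed [ROCResult-class].
#' @export
rocPanel <- function(scores, labels, orientation = "auto",
                     criterion = "youden") {
  roc <- rocCurve(scores, labels, orientation)
  cut <- optimalCutoff(roc, criterion)
  cm <- confusionAtCutoff(scores, labels, cut, roc@orientation)
  new("ROCResult", points = roc@points, auc = roc@auc,
      orientation = roc@orientation, cutoff = cut,
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      ppv = cm$ppv, npv = cm$npv, prevalence = cm$prevalence)
}
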