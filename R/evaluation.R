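# Prediction-accuracy quantification: AUC (Mann-Whitney), DeLong confidence
# intervals and test against chance, sensitivity/specificity at a frozen
# threshold, Youden threshold choice, and Nagelkerke pseudo-R2.

#' Area under the ROC curve (Mann-Whitney)
#'
#' The probability that a randomly chosen remitter receives a higher score
#' than a randomly chosen non-remitter, with ties contributing 1/2:
#' `(1/(n1 n0)) * sum over positive-negative pairs of [score+ > score-] +
#' 0.5 [tied]`, computed via average ranks.
#'
#' @param scores numeric scores (higher = more likely remitter).
#' @param labels binary labels with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary01(labels, "labels")
  check_both_classes(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval and test against chance for the AUC
#'
#' Placement-value (DeLong) variance of the Mann-Whitney AUC, a Wald
#' confidence interval truncated to `[0, 1]`, and a two-sided normal
#' p-value for the null hypothesis AUC = 0.5. With zero placement variance
#' (e.g. perfect separation or an all-tied constant score) the interval
#' degenerates to the point estimate and the result is flagged; the
#' p-value is then reported at the machine-precision floor (or 1 when the
#' point estimate is exactly 0.5).
#'
#' @param scores numeric scores.
#' @param labels binary labels with at least two members per class.
#' @param level confidence level.
#' @return List with `auc`, `ci_low`, `ci_high`, `p_value`, `se`,
#'   `degenerate`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  y <- as_binary01(labels, "labels")
  check_both_classes(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L) {
    stop("DeLong variance needs at least 2 members per class", call. = FALSE)
  }
  r_all <- rank(scores)
  r_pos <- rank(scores[y == 1L])
  r_neg <- rank(scores[y == 0L])
  # placement of each positive among negatives, and vice versa
  v10 <- (r_all[y == 1L] - r_pos) / n0
  v01 <- 1 - (r_all[y == 0L] - r_neg) / n1
  auc <- mean(v10)
  v <- var(v10) / n1 + var(v01) / n0
  if (v <= 0) {
    p <- if (isTRUE(all.equal(auc, 0.5))) 1 else .Machine$double.xmin
    return(list(auc = auc, ci_low = auc, ci_high = auc, p_value = p,
                se = 0, degenerate = TRUE))
  }
  se <- sqrt(v)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc,
       ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se),
       p_value = 2 * pnorm(-abs(auc - 0.5) / se),
       se = se, degenerate = FALSE)
}

#' Sensitivity and specificity at a threshold
#'
#' Classifies `p >= threshold` as a predicted remitter and returns
#' `sens = TP/(TP+FN)` and `spec = TN/(TN+FP)`.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary labels.
#' @param threshold classification threshold in `[0, 1]`.
#' @return Named list with `sensitivity` and `specificity`.
#' @export
sensitivity_specificity <- function(probabilities, labels, threshold) {
  y <- as_binary01(labels, "labels")
  pred <- probabilities >= threshold
  list(sensitivity = sum(pred & y == 1L) / sum(y == 1L),
       specificity = sum(!pred & y == 0L) / sum(y == 0L))
}

#' Choose a classification threshold by Youden's J
#'
#' Scans the midpoints between consecutive distinct predicted
#' probabilities and returns the threshold maximizing
#' `J = sensitivity + specificity - 1`, with ties broken toward the
#' candidate nearest 0.5. Meant to be applied to training predictions and
#' frozen in the model before validation.
#'
#' @param probabilities training predicted probabilities.
#' @param labels binary training labels with both classes present.
#' @return The chosen threshold.
#' @export
choose_threshold <- function(probabilities, labels) {
  y <- as_binary01(labels, "labels")
  check_both_classes(y)
  u <- sort(unique(probabilities))
  if (length(u) == 1L) return(0.5)
  cand <- (head(u, -1) + tail(u, -1)) / 2
  j <- vapply(cand, function(t) {
    ss <- sensitivity_specificity(probabilities, y, t)
    ss$sensitivity + ss$specificity - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cand[best][which.min(abs(cand[best] - 0.5))]
}

#' Nagelkerke pseudo-R-squared
#'
#' With `L1` the log-likelihood of the supplied probabilities and `L0` that
#' of an intercept-only null (by default refitted to the evaluated labels,
#' i.e. their prevalence; optionally a frozen training prevalence):
#' `R2_CS = 1 - exp(2 (L0 - L1) / n)` and
#' `R2_N = R2_CS / (1 - exp(2 L0 / n))`, clamped to `[0, 1]`.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary labels with both classes present.
#' @param null_probability optional fixed null-model probability (e.g. the
#'   training prevalence); defaults to the prevalence of `labels`.
#' @return Pseudo-R2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(probabilities, labels, null_probability = NULL) {
  y <- as_binary01(labels, "labels")
  check_both_classes(y)
  n <- length(y)
  p <- pmin(pmax(probabilities, 1e-12), 1 - 1e-12)
  p0 <- pmin(pmax(null_probability %||% mean(y), 1e-12), 1 - 1e-12)
  l1 <- sum(y * log(p) + (1 - y) * log(1 - p))
  l0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  cs <- 1 - exp(2 * (l0 - l1) / n)
  r2 <- cs / (1 - exp(2 * l0 / n))
  min(1, max(0, r2))
}

#' Empirical ROC points
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return Data frame of `threshold`, `fpr`, `tpr`, suitable for plotting
#'   or trapezoidal integration.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary01(labels, "labels")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & y == 0L) / sum(y == 0L),
      tpr = sum(pred & y == 1L) / sum(y == 1L))
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Full accuracy report for a set of predictions
#'
#' Bundles the AUC with its DeLong confidence interval and test against
#' chance, sensitivity and specificity at a frozen threshold, and the
#' Nagelkerke pseudo-R2, into one evaluation report.
#'
#' @param probabilities predicted remission probabilities.
#' @param labels binary outcomes with both classes present.
#' @param threshold classification threshold (typically chosen on training
#'   data and frozen).
#' @param context free-text label (e.g. `"validation_A"`,
#'   `"cross_A_on_B"`).
#' @param null_probability optional fixed null for the pseudo-R2.
#' @param level confidence level for the AUC interval.
#' @return An object of class `"remit_report"`.
#' @export
evaluate_predictions <- function(probabilities, labels, threshold = 0.5,
                                 context = "validation",
                                 null_probability = NULL, level = 0.95) {
  y <- as_binary01(labels, "labels")
  check_both_classes(y)
  dl <- delong_ci(probabilities, y, level = level)
  ss <- sensitivity_specificity(probabilities, y, threshold)
  structure(
    list(auc = dl$auc, ci_low = dl$ci_low, ci_high = dl$ci_high,
         p_value = dl$p_value, degenerate = dl$degenerate,
         sensitivity = ss$sensitivity, specificity = ss$specificity,
         pseudo_r2 = nagelkerke_r2(probabilities, y, null_probability),
         threshold = threshold, n = length(y), n_remitters = sum(y),
         context = context),
    class = "remit_report")
}

#' @export
print.remit_report <- function(x, ...) {
  cat(sprintf("[%s] AUC %.2f (95%%CI %.2f-%.2f; p = %.3g), sens %.2f, spec %.2f, pseudo-R2 %.2f (n = %d, remitters = %d)\n",
              x$context, x$auc, x$ci_low, x$ci_high, x$p_value,
              x$sensitivity, x$specificity, x$pseudo_r2, x$n, x$n_remitters))
  invisible(x)
}
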