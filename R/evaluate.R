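# Clinical evaluation of bag scores: confusion metrics, ROC/AUC with a
# DeLong 95% confidence interval, Youden and minimum-distance cut-offs,
# and decision-curve analysis. All functions are pure: the same cohort
# always yields the same report.
#
# Conventions (documented so cut-offs are reproducible): label 1 = response
# is the positive class; a bag is called positive when score >= cutoff
# (closed on the left).

check_cohort <- function(scores, labels, need_both = FALSE) {
  if (length(scores) != length(labels))
    stop_invalid("'scores' and 'labels' differ in length")
  if (length(scores) == 0L) stop_invalid("empty cohort")
  if (anyNA(scores) || anyNA(labels)) stop_invalid("missing scores or labels")
  if (!all(labels %in% c(0, 1))) stop_invalid("labels must be 0/1")
  if (need_both && length(unique(labels)) < 2L)
    stop_invalid("both classes must be present")
  invisible(NULL)
}

#' Confusion-matrix metrics at a cut-off
#'
#' Classifies `score >= cutoff` as positive, with label 1 (response) as the
#' positive class (set `positive = 0` to adopt the opposite convention),
#' and reports the confusion counts with accuracy `(TP+TN)/N`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision, and
#' `F1 = 2 * precision * recall / (precision + recall)`. Degenerate
#' denominators yield 0 with a warning.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param cutoff decision threshold.
#' @param positive which label is the positive class (1 = response).
#' @return Object of class `"dmil_confusion"` (a list of counts and rates).
#' @examples
#' # the study's test-cohort confusion: 26/30 response, 27/30 nonresponse
#' s <- c(rep(1, 26), rep(0, 4), rep(0, 27), rep(1, 3))
#' y <- c(rep(1, 30), rep(0, 30))
#' confusion_metrics(s, y, 0.5)$accuracy  # 53/60
#' @export
confusion_metrics <- function(scores, labels, cutoff = 0.5, positive = 1) {
  check_cohort(scores, labels)
  if (!positive %in% c(0, 1)) stop_invalid("'positive' must be 0 or 1")
  if (positive == 0) {
    labels <- 1 - labels
    scores <- 1 - scores
    cutoff <- 1 - cutoff   # score > 1-c  <=>  1-score < c; boundary shifts
  }
  pred <- as.numeric(scores >= cutoff)
  TP <- sum(pred == 1 & labels == 1)
  FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  N <- TP + FP + TN + FN
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("degenerate denominator for ", what, "; reporting 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  sens <- safe_div(TP, TP + FN, "sensitivity")
  spec <- safe_div(TN, TN + FP, "specificity")
  prec <- safe_div(TP, TP + FP, "precision")
  f1 <- if (prec + sens == 0) {
    warning("degenerate denominator for F1; reporting 0", call. = FALSE)
    0
  } else 2 * prec * sens / (prec + sens)
  structure(list(cutoff = cutoff, TP = TP, FP = FP, TN = TN, FN = FN, n = N,
                 accuracy = (TP + TN) / N, sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1,
                 positive = positive),
            class = "dmil_confusion")
}

#' @export
print.dmil_confusion <- function(x, ...) {
  cat("Confusion at cutoff ", fmt_num(x$cutoff), " (positive class = ",
      x$positive, ")\n", sep = "")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$n))
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f  F1 %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Builds the ROC over all unique score values plus sentinels (a threshold
#' above every score and one at the minimum), with positivity
#' `score >= threshold`. The AUC is the area under the resulting staircase
#' by trapezoid, which for tied scores equals the Mann-Whitney probability
#' with half-credit for ties:
#' `AUC = (#{pos > neg} + #{pos == neg}/2) / (n1 * n0)`.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return Object of class `"dmil_roc"`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  check_cohort(scores, labels, need_both = TRUE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = NA_real_, tpr = NA_real_)
  for (i in seq_len(nrow(pts))) {
    pred <- scores >= pts$threshold[i]
    pts$tpr[i] <- sum(pred & labels == 1) / n1
    pts$fpr[i] <- sum(pred & labels == 0) / n0
  }
  # rank-based Mann-Whitney AUC with average ranks (half-credit for ties)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(points = pts, auc = auc, n1 = n1, n0 = n0),
            class = "dmil_roc")
}

#' @export
print.dmil_roc <- function(x, ...) {
  cat("ROC:", nrow(x$points), "operating points, AUC =", fmt_num(x$auc), "\n")
  invisible(x)
}

#' @export
plot.dmil_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1),
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# DeLong placement values: for each positive score, the fraction of
# negatives it beats (ties half); and vice versa.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  V10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                numeric(1))
  V01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                numeric(1))
  list(auc = mean(V10), V10 = V10, V01 = V01, m = m, n = n)
}

#' Confidence interval for the AUC
#'
#' Default is the DeLong nonparametric variance estimate with a
#' normal-approximation interval, truncated to `[0, 1]`; the variance is
#' `var(V10)/m + var(V01)/n` where `V10`/`V01` are the placement values of
#' the positive/negative scores. A stratified percentile bootstrap is
#' available as an option.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, at least 2 per class.
#' @param level confidence level (default 0.95).
#' @param method `"delong"` (deterministic default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return List with `auc`, `low`, `high`, `level`, `method`, `se`
#'   (DeLong only).
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "bootstrap"), n_boot = 2000L,
                   seed = 1L) {
  check_cohort(scores, labels, need_both = TRUE)
  if (sum(labels == 1) < 2L || sum(labels == 0) < 2L)
    stop_invalid("need at least 2 bags per class for a CI")
  if (level <= 0 || level >= 1) stop_invalid("'level' must be in (0, 1)")
  method <- match.arg(method)
  dc <- delong_components(scores, labels)
  if (method == "delong") {
    v <- stats::var(dc$V10) / dc$m + stats::var(dc$V01) / dc$n
    se <- sqrt(v)
    z <- stats::qnorm(1 - (1 - level) / 2)
    list(auc = dc$auc, low = max(0, dc$auc - z * se),
         high = min(1, dc$auc + z * se), level = level, method = "delong",
         se = se)
  } else {
    set.seed(derive_seed(seed, "auc_boot"))
    ip <- which(labels == 1); im <- which(labels == 0)
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
      r <- rank(scores[idx]); l <- labels[idx]
      m <- length(ip); n <- length(im)
      (sum(r[l == 1]) - m * (m + 1) / 2) / (m * n)
    }, numeric(1))
    q <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    list(auc = dc$auc, low = max(0, q[1]), high = min(1, q[2]),
         level = level, method = "bootstrap", se = stats::sd(reps))
  }
}

#' Optimal ROC cut-offs
#'
#' Two standard operating points on the ROC: the Youden cut-off maximizes
#' `sensitivity + specificity - 1`, and the minimum-distance cut-off
#' minimizes the Euclidean distance `sqrt((1-sens)^2 + (1-spec)^2)` to the
#' ideal corner (0, 1). Ties are broken toward the lower threshold. Both
#' are invariant to monotone transformations of the scores (up to the
#' reported threshold value itself).
#'
#' @param roc a [roc_auc()] object.
#' @return List with `cutoff_youden`, `youden_j`, `cutoff_min_distance`,
#'   `min_distance`.
#' @export
optimal_cutoffs <- function(roc) {
  if (!inherits(roc, "dmil_roc")) stop_invalid("'roc' must come from roc_auc()")
  p <- roc$points
  finite <- is.finite(p$threshold)
  p <- p[finite, , drop = FALSE]
  j <- p$tpr - p$fpr
  d <- sqrt((1 - p$tpr)^2 + p$fpr^2)
  # thresholds are sorted decreasing; ties toward the lower threshold means
  # taking the LAST index attaining the optimum
  iy <- max(which(j == max(j)))
  id <- max(which(d == min(d)))
  list(cutoff_youden = p$threshold[iy], youden_j = j[iy],
       cutoff_min_distance = p$threshold[id], min_distance = d[id])
}

#' Decision-curve analysis
#'
#' Net benefit of using the model at threshold probability `p` (classify
#' positive when `score >= p`): `NB(p) = TP/N - (FP/N) * p/(1-p)`, compared
#' against treating everyone (`pi - (1-pi) * p/(1-p)`, `pi` the prevalence)
#' and treating no one (0). The treat-all curve equals the prevalence as
#' `p -> 0` and crosses zero at `p = pi`; a perfect classifier attains
#' `NB = pi` at every interior threshold.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param thresholds grid of threshold probabilities inside (0, 1);
#'   default 0.01 to 0.99 by 0.01.
#' @return Object of class `"dmil_dca"`: data.frame `thresholds`,
#'   `nb_model`, `nb_treat_all`, `nb_treat_none`, plus `prevalence`.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  check_cohort(scores, labels)
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop_invalid("'thresholds' must lie strictly inside (0, 1)")
  N <- length(scores)
  prev <- mean(labels == 1)
  odds <- thresholds / (1 - thresholds)
  nb_model <- vapply(thresholds, function(p) {
    pred <- scores >= p
    TP <- sum(pred & labels == 1)
    FP <- sum(pred & labels == 0)
    TP / N - (FP / N) * p / (1 - p)
  }, numeric(1))
  curve <- data.frame(threshold = thresholds, nb_model = nb_model,
                      nb_treat_all = prev - (1 - prev) * odds,
                      nb_treat_none = 0)
  structure(list(curve = curve, prevalence = prev, n = N),
            class = "dmil_dca")
}

#' @export
print.dmil_dca <- function(x, ...) {
  cat("Decision curve over", nrow(x$curve), "thresholds; prevalence",
      fmt_num(x$prevalence), "\n")
  invisible(x)
}

#' @export
plot.dmil_dca <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$threshold, cv$nb_model, type = "l", lwd = 2,
                 ylim = range(c(cv$nb_model, cv$nb_treat_all, 0, x$prevalence)),
                 xlab = "threshold probability", ylab = "net benefit",
                 main = "Decision curve analysis", ...)
  graphics::lines(cv$threshold, cv$nb_treat_all, lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}

#' Full evaluation report for a scored cohort
#'
#' Computes the complete panel reported for this model family: confusion
#' counts and rates at a cut-off (chosen by Youden's index by default, by
#' minimum distance, or given explicitly), the ROC and its AUC, the
#' DeLong 95% CI, both optimal cut-offs, and the decision curve.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 labels, both classes present.
#' @param cutoff `"youden"`, `"min_distance"`, or a number.
#' @param level confidence level for the AUC CI.
#' @param positive positive-class convention passed to
#'   [confusion_metrics()].
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @return Object of class `"dmil_eval"` bundling all of the above.
#' @export
evaluate_scores <- function(scores, labels, cutoff = "youden", level = 0.95,
                            positive = 1, ci_method = "delong") {
  check_cohort(scores, labels, need_both = TRUE)
  roc <- roc_auc(scores, labels)
  cuts <- optimal_cutoffs(roc)
  cut_val <- if (is.numeric(cutoff)) cutoff
    else switch(match.arg(cutoff, c("youden", "min_distance")),
                youden = cuts$cutoff_youden,
                min_distance = cuts$cutoff_min_distance)
  cm <- confusion_metrics(scores, labels, cut_val, positive = positive)
  ci <- auc_ci(scores, labels, level = level, method = ci_method)
  dca <- decision_curve(scores, labels)
  structure(list(cutoff = cut_val, confusion = cm, auc = roc$auc,
                 auc_ci = ci, roc = roc,
                 cutoff_youden = cuts$cutoff_youden,
                 cutoff_min_distance = cuts$cutoff_min_distance,
                 dca = dca, n = length(scores)),
            class = "dmil_eval")
}

#' @export
print.dmil_eval <- function(x, ...) {
  cat("Bag-level evaluation (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  AUC %.3f (%d%% CI %.3f-%.3f, %s)\n", x$auc,
              round(x$auc_ci$level * 100), x$auc_ci$low, x$auc_ci$high,
              x$auc_ci$method))
  cat(sprintf("  cut-offs: applied %.3f | Youden %.3f | min-distance %.3f\n",
              x$cutoff, x$cutoff_youden, x$cutoff_min_distance))
  print(x$confusion)
  invisible(x)
}

# flatten an evaluation report for JSON export
eval_report_list <- function(ev) {
  cm <- ev$confusion
  list(n = ev$n, cutoff = ev$cutoff,
       counts = list(TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN),
       accuracy = cm$accuracy, sensitivity = cm$sensitivity,
       specificity = cm$specificity, f1 = cm$f1, precision = cm$precision,
       auc = ev$auc,
       auc_ci = list(low = ev$auc_ci$low, high = ev$auc_ci$high,
                     level = ev$auc_ci$level, method = ev$auc_ci$method),
       cutoff_youden = ev$cutoff_youden,
       cutoff_min_distance = ev$cutoff_min_distance)
}
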