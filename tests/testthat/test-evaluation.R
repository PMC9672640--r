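# Evaluation panel: confusion metrics, ROC/AUC, DeLong CI, cut-offs, DCA.

test_that("confusion metrics recover the published cohort accuracies", {
  # test cohort: 26/30 response and 27/30 nonresponse correct
  co <- cohort_from_counts(TP = 26, FN = 4, TN = 27, FP = 3)
  cm <- confusion_metrics(co$scores, co$labels, 0.5)
  expect_equal(cm$TP, 26); expect_equal(cm$FN, 4)
  expect_equal(cm$TN, 27); expect_equal(cm$FP, 3)
  expect_equal(cm$accuracy, 53 / 60)
  expect_equal(round(cm$accuracy, 3), 0.883)
  expect_equal(cm$sensitivity, 26 / 30)
  expect_equal(cm$specificity, 27 / 30)

  # external cohort: 18/22 response and 17/20 nonresponse correct
  ex <- cohort_from_counts(TP = 18, FN = 4, TN = 17, FP = 3)
  cme <- confusion_metrics(ex$scores, ex$labels, 0.5)
  expect_equal(cme$accuracy, 35 / 42)
  expect_equal(round(cme$accuracy, 3), 0.833)
})

test_that("confusion metric identities and degenerate cases", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    s <- runif(n); y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    cm <- suppressWarnings(confusion_metrics(s, y, runif(1)))
    expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, n)
    expect_equal(cm$accuracy * n, cm$TP + cm$TN)
    expect_true(all(unlist(cm[c("accuracy", "sensitivity", "specificity",
                                "f1")]) >= 0))
    expect_true(all(unlist(cm[c("accuracy", "sensitivity", "specificity",
                                "f1")]) <= 1))
  }
  # perfect separation at an interior cutoff
  cm <- confusion_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(c(cm$accuracy, cm$sensitivity, cm$specificity, cm$f1),
               rep(1, 4))
  # all predicted negative -> degenerate precision and F1 warn, report 0
  cm0 <- NULL
  w <- capture_warnings(cm0 <- confusion_metrics(c(0.1, 0.2), c(1, 0), 0.9))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(cm0$f1, 0)
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
  # positive-class convention flips sensitivity and specificity
  s <- c(0.9, 0.8, 0.2, 0.3); y <- c(1, 0, 0, 1)
  a <- confusion_metrics(s, y, 0.5, positive = 1)
  b <- confusion_metrics(s, y, 0.5, positive = 0)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("ROC/AUC handles separation, ties and hand-checked cohorts", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # 8-item cohort with one tied pair, against exhaustive pair counting
  s <- c(0.9, 0.7, 0.7, 0.6, 0.5, 0.4, 0.3, 0.1)
  y <- c(1, 1, 0, 1, 0, 1, 0, 0)
  expect_equal(roc_auc(s, y)$auc, oracle_auc_pairs(s, y))
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC equals the Mann-Whitney statistic on random cohorts", {
  set.seed(62)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    s <- round(runif(n), sample(1:3, 1))   # rounding forces ties
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(s, y)$auc, oracle_auc_pairs(s, y))
  }
})

test_that("ROC points trace the trapezoid of the rank AUC", {
  set.seed(63)
  s <- round(runif(25), 2)
  y <- c(0, 1, rbinom(23, 1, 0.4))
  roc <- roc_auc(s, y)
  p <- roc$points
  expect_equal(p$fpr[1], 0); expect_equal(p$tpr[1], 0)
  expect_equal(tail(p$fpr, 1), 1); expect_equal(tail(p$tpr, 1), 1)
  trap <- sum(diff(p$fpr) * (head(p$tpr, -1) + tail(p$tpr, -1)) / 2)
  expect_equal(trap, roc$auc, tolerance = 1e-12)
})

test_that("DeLong interval behaves at the limits and reflects label reversal", {
  s <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  y <- rep(c(1, 0), each = 50)
  ci <- auc_ci(s, y)
  expect_equal(ci$auc, 1)
  expect_equal(ci$high, 1)
  expect_equal(ci$low, 1)         # zero-variance limit collapses
  set.seed(64)
  s2 <- c(rnorm(30, 1), rnorm(30))
  y2 <- rep(c(1, 0), each = 30)
  s2 <- plogis(s2)
  ci2 <- auc_ci(s2, y2)
  ci2r <- auc_ci(s2, 1 - y2)
  expect_equal(ci2r$auc, 1 - ci2$auc)
  expect_equal(ci2r$low, 1 - ci2$high, tolerance = 1e-12)
  expect_equal(ci2r$high, 1 - ci2$low, tolerance = 1e-12)
  expect_true(ci2$low <= ci2$auc && ci2$auc <= ci2$high)
  # bootstrap option returns a sane interval too
  cib <- auc_ci(s2, y2, method = "bootstrap", n_boot = 200)
  expect_true(cib$low <= cib$auc && cib$auc <= cib$high)
  expect_error(auc_ci(c(0.2, 0.8, 0.5), c(1, 0, 1)), "at least 2")
})

test_that("optimal cut-offs match exhaustive search and are rank-invariant", {
  # 6-point hand cohort
  s <- c(0.95, 0.8, 0.7, 0.45, 0.3, 0.1)
  y <- c(1, 1, 0, 1, 0, 0)
  roc <- roc_auc(s, y)
  cuts <- optimal_cutoffs(roc)
  thr <- sort(unique(s))
  best_j <- -Inf; best_d <- Inf; cy <- cd <- NA
  for (t in thr) {
    sens <- sum(s >= t & y == 1) / sum(y == 1)
    spec <- sum(s < t & y == 0) / sum(y == 0)
    j <- sens + spec - 1
    dd <- sqrt((1 - sens)^2 + (1 - spec)^2)
    if (j > best_j) { best_j <- j; cy <- t }   # ascending + strict > keeps
    if (dd < best_d) { best_d <- dd; cd <- t } # the lowest tied threshold
  }
  expect_equal(cuts$cutoff_youden, cy)
  expect_equal(cuts$cutoff_min_distance, cd)
  expect_equal(cuts$youden_j, best_j)
  # perfect classifier: Youden J = 1, both cut-offs separate the classes
  rp <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  cp <- optimal_cutoffs(rp)
  expect_equal(cp$youden_j, 1)
  expect_true(cp$cutoff_youden > 0.2 && cp$cutoff_youden <= 0.8)
  # monotone transform preserves the selected partition
  s3 <- s^3
  c3 <- optimal_cutoffs(roc_auc(s3, y))
  expect_equal(s >= cuts$cutoff_youden, s3 >= c3$cutoff_youden)
  expect_equal(s >= cuts$cutoff_min_distance, s3 >= c3$cutoff_min_distance)
})

test_that("iterating thresholds from low upward visits these partitions", {
  # exhaustive-search property on random cohorts
  set.seed(65)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    s <- round(runif(n), 2)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    cuts <- optimal_cutoffs(roc_auc(s, y))
    js <- vapply(sort(unique(s)), function(t) {
      sum(s >= t & y == 1) / sum(y == 1) + sum(s < t & y == 0) / sum(y == 0) - 1
    }, numeric(1))
    expect_equal(cuts$youden_j, max(js), tolerance = 1e-12)
  }
})

test_that("decision curve matches the recount oracle and its closed forms", {
  set.seed(66)
  s <- runif(50); y <- rbinom(50, 1, 0.45)
  grid <- seq(0.01, 0.99, by = 0.01)
  dca <- decision_curve(s, y, grid)
  for (i in seq_along(grid)) {
    expect_equal(dca$curve$nb_model[i], oracle_net_benefit(s, y, grid[i]),
                 tolerance = 1e-10)
  }
  prev <- mean(y)
  expect_equal(dca$curve$nb_treat_all,
               prev - (1 - prev) * grid / (1 - grid), tolerance = 1e-12)
  expect_true(all(dca$curve$nb_treat_none == 0))
  expect_true(all(dca$curve$nb_model <= prev + 1e-12))
  # treat-all crosses zero at p = prevalence
  below <- grid[grid < prev - 0.011]; above <- grid[grid > prev + 0.011]
  expect_true(all(prev - (1 - prev) * below / (1 - below) > 0))
  expect_true(all(prev - (1 - prev) * above / (1 - above) < 0))
  # perfect classifier attains the prevalence at every interior threshold
  sp <- c(rep(1, 9), rep(0, 11)); yp <- c(rep(1, 9), rep(0, 11))
  dcp <- decision_curve(sp, yp, grid)
  expect_true(all(abs(dcp$curve$nb_model - mean(yp)) < 1e-12))
  # when a threshold classifies everyone positive, model equals treat-all
  s_all <- runif(20, 0.5, 1); y_all <- rbinom(20, 1, 0.5)
  nb <- decision_curve(s_all, y_all, 0.3)
  expect_equal(nb$curve$nb_model, nb$curve$nb_treat_all, tolerance = 1e-12)
  expect_error(decision_curve(s, y, c(0, 0.5)), "inside")
})

test_that("evaluate_scores bundles a coherent report", {
  set.seed(67)
  s <- plogis(c(rnorm(25, 1.5), rnorm(25, -1.5)))
  y <- rep(c(1, 0), each = 25)
  ev <- evaluate_scores(s, y)
  expect_s3_class(ev, "dmil_eval")
  expect_equal(ev$cutoff, ev$cutoff_youden)
  expect_true(ev$auc_ci$low <= ev$auc && ev$auc <= ev$auc_ci$high)
  expect_equal(ev$confusion$TP + ev$confusion$FP + ev$confusion$TN +
                 ev$confusion$FN, 50)
  # pure function: identical cohort -> identical report
  ev2 <- evaluate_scores(s, y)
  expect_identical(eval_list <- dmilct:::eval_report_list(ev),
                   dmilct:::eval_report_list(ev2))
  ev3 <- evaluate_scores(s, y, cutoff = "min_distance")
  expect_equal(ev3$cutoff, ev$cutoff_min_distance)
  expect_output(print(ev), "AUC")
})
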