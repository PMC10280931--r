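# exhaustive pairwise Mann-Whitney AUC: P(s_pos > s_neg) + 0.5 P(tie)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# ECDF difference evaluated at every pooled jump point
ks_bruteforce <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

test_that("confusion counts are exact and ties go to positive", {
  cm <- confusion_from_scores(c(0.9, 0.1), c("jia", "control"))
  expect_identical(unlist(cm[c("TP", "FP", "TN", "FN")]),
                   c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  tie <- confusion_from_scores(0.5, "control", threshold = 0.5)
  expect_identical(tie$FP, 1L)      # score == threshold predicts positive
  allpos <- confusion_from_scores(c(0.2, 0.8), c("jia", "jia"))
  expect_identical(allpos$FP + allpos$TN, 0L)
  expect_error(confusion_from_scores(numeric(0), character(0)), "empty")

  # counts conserve n under any threshold
  set.seed(1)
  s <- runif(50); l <- sample(c("jia", "control"), 50, TRUE)
  for (thr in c(0.1, 0.5, 0.9)) {
    cm <- confusion_from_scores(s, l, thr)
    expect_identical(cm$TP + cm$FP + cm$TN + cm$FN, 50L)
  }
})

test_that("summary metrics are the standard ratios with undefined flags", {
  m <- summary_metrics(structure(list(TP = 8L, FN = 2L, TN = 9L, FP = 1L),
                                 class = "jae_confusion"))
  expect_equal(m$sensitivity, 0.80)
  expect_equal(m$specificity, 0.90)
  expect_equal(m$accuracy, 0.85)
  expect_length(m$undefined, 0L)

  perfect <- summary_metrics(structure(list(TP = 5L, FN = 0L, TN = 5L, FP = 0L),
                                       class = "jae_confusion"))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))

  nopos <- summary_metrics(structure(list(TP = 0L, FN = 0L, TN = 5L, FP = 1L),
                                     class = "jae_confusion"))
  expect_true(is.na(nopos$sensitivity))
  expect_identical(nopos$undefined, "sensitivity")
})

test_that("trapezoidal AUC equals the pairwise probability", {
  roc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("jia", "jia", "control", "control"))
  expect_equal(roc$auc, 1.0)
  expect_error(roc_curve(c(0.1, 0.9), c("jia", "jia")), "both classes")

  set.seed(17)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    scores <- round(runif(n), 2)      # rounding forces ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC matches an independent implementation and is rank-invariant", {
  set.seed(19)
  scores <- runif(80)
  labels <- sample(c("jia", "control"), 80, TRUE)
  r <- roc_curve(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("control", "jia"),
                                              direction = "<")))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  expect_equal(roc_curve(exp(scores), labels)$auc, r$auc, tolerance = 1e-12)
  expect_equal(roc_curve(rank(scores), labels)$auc, r$auc, tolerance = 1e-12)
})

test_that("null AUC concentrates near one half", {
  set.seed(23)
  s <- runif(400)
  l <- rep(c("jia", "control"), each = 200)
  a <- roc_curve(s, l)$auc
  expect_gt(a, 0.42); expect_lt(a, 0.58)
})

test_that("the KS statistic is the exhaustive ECDF supremum", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")

  a <- c(0.1, 0.4, 0.7); b <- c(0.2, 0.5, 0.6, 0.9)
  expect_equal(ks_two_sample(a, b)$D, ks_bruteforce(a, b), tolerance = 1e-15)

  set.seed(29)
  for (i in 1:50) {
    a <- round(runif(sample(5:30, 1)), 2)
    b <- round(runif(sample(5:30, 1)), 2)
    res <- ks_two_sample(a, b)
    expect_equal(res$D, ks_bruteforce(a, b), tolerance = 1e-15)
    ref <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(res$D, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("the asymptotic KS p-value tracks the reference distribution", {
  set.seed(31)
  a <- rnorm(60); b <- rnorm(60, 0.5)
  res <- ks_two_sample(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("reports are internally consistent across their components", {
  set.seed(37)
  n <- 40
  cvs <- data.frame(
    knee_id = sprintf("k%02d", 1:n),
    group = rep(c("jia", "control"), each = n / 2),
    activity = rep(c("active", "none"), each = n / 2),
    label = rep(c("jia", "control"), each = n / 2),
    score = c(runif(n / 2, 0.3, 1), runif(n / 2, 0, 0.7)),
    stringsAsFactors = FALSE)
  tss <- data.frame(
    knee_id = sprintf("t%02d", 1:20),
    group = rep(c("jia", "control"), each = 10),
    activity = rep(c("inactive", "none"), each = 10),
    label = rep(c("jia", "control"), each = 10),
    score = c(runif(10, 0.2, 1), runif(10, 0, 0.5)),
    stringsAsFactors = FALSE)
  rep_ <- build_report(cvs, tss)
  cm <- rep_$cv$confusion
  expect_equal(rep_$cv$metrics$accuracy,
               (cm$TP + cm$TN) / (cm$TP + cm$TN + cm$FP + cm$FN))
  expect_setequal(names(rep_$distributions), c("healthy", "inactive", "active"))
  expect_false(is.null(rep_$ks))
  expect_error(build_report(cvs[1, , drop = FALSE]), "at least 2")
})
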