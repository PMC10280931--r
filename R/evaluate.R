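#' Confusion matrix from joint scores
#'
#' A score at or above the threshold predicts the positive (JIA) class —
#' ties go to positive by convention.
#'
#' @param scores numeric joint scores.
#' @param labels logical or character labels; \code{positive} names the
#'   positive class when labels are character.
#' @param threshold decision threshold (default 0.5).
#' @param positive positive class value.
#' @return object of class \code{jae_confusion}: list with TP, FP, TN, FN.
#' @export
confusion_from_scores <- function(scores, labels, threshold = 0.5,
                                  positive = "jia") {
  if (length(scores) == 0L) stop("confusion_from_scores: empty input")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  truth <- if (is.logical(labels)) labels else labels == positive
  pred <- scores >= threshold
  structure(list(TP = sum(pred & truth), FP = sum(pred & !truth),
                 TN = sum(!pred & !truth), FN = sum(!pred & truth),
                 threshold = threshold),
            class = "jae_confusion")
}

#' @export
print.jae_confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, 2L,
              dimnames = list(truth = c("jia", "healthy"),
                              predicted = c("jia", "healthy")))
  cat(sprintf("Confusion matrix (threshold %.2f):\n", x$threshold))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' A ratio with a zero denominator is reported as \code{NA} and flagged in
#' the \code{undefined} field rather than silently coerced to 0.
#'
#' @param cm a \code{jae_confusion}.
#' @return list: accuracy, sensitivity, specificity, undefined (character
#'   vector naming any undefined metric).
#' @export
summary_metrics <- function(cm) {
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  undef <- character(0)
  acc <- if (total > 0) (cm$TP + cm$TN) / total else {
    undef <- c(undef, "accuracy"); NA_real_ }
  sens <- if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else {
    undef <- c(undef, "sensitivity"); NA_real_ }
  spec <- if (cm$TN + cm$FP > 0) cm$TN / (cm$TN + cm$FP) else {
    undef <- c(undef, "specificity"); NA_real_ }
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       undefined = undef)
}

#' ROC curve and AUC
#'
#' Thresholds sweep the unique score values (ties grouped); the area under
#' the curve is computed by the trapezoidal rule, which equals the
#' normalized Mann-Whitney U statistic
#' \eqn{P(s_{pos} > s_{neg}) + \tfrac{1}{2} P(s_{pos} = s_{neg})}.
#'
#' @inheritParams confusion_from_scores
#' @return object of class \code{jae_roc}: data.frame \code{points}
#'   (threshold, fpr, tpr) and scalar \code{auc}.
#' @export
roc_curve <- function(scores, labels, positive = "jia") {
  truth <- if (is.logical(labels)) labels else labels == positive
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0L || nn == 0L) stop("roc_curve: need both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !truth) / nn, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "jae_roc")
}

#' @export
print.jae_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.jae_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "s",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum of the absolute difference of the two
#' empirical cumulative distribution functions, evaluated at every jump
#' point of either sample. The p-value uses the asymptotic Kolmogorov
#' distribution with effective sample size \eqn{n_a n_b / (n_a + n_b)};
#' \code{method = "permutation"} replaces it with a label-permutation
#' p-value.
#'
#' @param a,b numeric samples.
#' @param method \code{"asymptotic"} (default) or \code{"permutation"}.
#' @param n_perm permutations when \code{method = "permutation"}.
#' @param seed seed for the permutation method.
#' @return list: \code{D}, \code{p_value}, \code{method}.
#' @export
ks_two_sample <- function(a, b, method = c("asymptotic", "permutation"),
                          n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) stop("ks_two_sample: empty sample")
  D <- ks_statistic(a, b)
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  if (method == "asymptotic") {
    p <- kolmogorov_sf(sqrt(n_eff) * D)
  } else {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
    pool <- c(a, b)
    na <- length(a)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      if (ks_statistic(pool[idx], pool[-idx]) >= D - 1e-12)
        exceed <- exceed + 1L
    }
    p <- (exceed + 1L) / (n_perm + 1L)
  }
  list(D = D, p_value = min(1, p), method = method)
}

# sup |ECDF_a - ECDF_b| over the pooled jump points
ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# survival function of the Kolmogorov distribution, Q(x) = 2 sum (-1)^{k-1} exp(-2 k^2 x^2)
kolmogorov_sf <- function(x) {
  if (x <= 0) return(1)
  k <- 1:100
  s <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(1, max(0, s))
}

#' Full evaluation report
#'
#' Combines the cross-validated training scores and the test-set scores
#' into the reported quantities: confusion matrices, accuracy, sensitivity
#' and specificity for both sets, the training-CV ROC/AUC, the per-group
#' score distributions (healthy / inactive / active), and the two-sample
#' Kolmogorov-Smirnov comparison of active versus inactive joint scores.
#'
#' @param cv_scores data.frame from [lolo_cv()] merged with metadata
#'   columns \code{group}, \code{activity} (see [jae_run()]), or any
#'   data.frame with knee_id, label, score, group, activity.
#' @param test_scores data.frame of the same shape for the test set, or
#'   \code{NULL}.
#' @param threshold decision threshold (default 0.5).
#' @return object of class \code{jae_eval_report}.
#' @export
build_report <- function(cv_scores, test_scores = NULL, threshold = 0.5) {
  if (nrow(cv_scores) < 2L) stop("build_report: need at least 2 scored knees")
  mk <- function(df) {
    cm <- confusion_from_scores(df$score, df$label, threshold)
    list(confusion = cm, metrics = summary_metrics(cm))
  }
  cv <- mk(cv_scores)
  cv$roc <- roc_curve(cv_scores$score, cv_scores$label)
  test <- if (!is.null(test_scores) && nrow(test_scores) > 0L) mk(test_scores)

  all_scores <- rbind(cv_scores[, c("knee_id", "group", "activity", "score")],
                      if (!is.null(test_scores))
                        test_scores[, c("knee_id", "group", "activity", "score")])
  grp <- ifelse(all_scores$group == "control", "healthy", all_scores$activity)
  dists <- split(all_scores$score, grp)

  ks <- if (all(c("active", "inactive") %in% names(dists)))
    ks_two_sample(dists$active, dists$inactive)

  structure(list(cv = cv, test = test, distributions = dists, ks = ks,
                 threshold = threshold),
            class = "jae_eval_report")
}

#' @export
print.jae_eval_report <- function(x, ...) {
  cat("JAE classification report\n")
  m <- x$cv$metrics
  cat(sprintf("  training (LOLO-CV): accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              m$accuracy, m$sensitivity, m$specificity, x$cv$roc$auc))
  if (!is.null(x$test)) {
    mt <- x$test$metrics
    cat(sprintf("  test set: accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
                mt$accuracy, mt$sensitivity, mt$specificity))
  }
  for (g in names(x$distributions))
    cat(sprintf("  %s scores: n = %d, median %.3f\n", g,
                length(x$distributions[[g]]),
                stats::median(x$distributions[[g]])))
  if (!is.null(x$ks))
    cat(sprintf("  KS active vs inactive: D = %.3f, p = %.3g\n",
                x$ks$D, x$ks$p_value))
  invisible(x)
}

# plain-list view used for serialization
report_as_list <- function(r) {
  cm2l <- function(cm) cm[c("TP", "FP", "TN", "FN")]
  out <- list(
    threshold = r$threshold,
    cv = list(confusion = cm2l(r$cv$confusion),
              accuracy = r$cv$metrics$accuracy,
              sensitivity = r$cv$metrics$sensitivity,
              specificity = r$cv$metrics$specificity,
              auc = r$cv$roc$auc))
  if (!is.null(r$test))
    out$test <- list(confusion = cm2l(r$test$confusion),
                     accuracy = r$test$metrics$accuracy,
                     sensitivity = r$test$metrics$sensitivity,
                     specificity = r$test$metrics$specificity)
  if (!is.null(r$ks))
    out$ks_active_vs_inactive <- list(D = r$ks$D, p_value = r$ks$p_value)
  out$score_distributions <- lapply(r$distributions, function(v)
    list(n = length(v), median = stats::median(v),
         q1 = as.numeric(stats::quantile(v, 0.25)),
         q3 = as.numeric(stats::quantile(v, 0.75))))
  out
}
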