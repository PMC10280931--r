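#' Build the train/test split plan
#'
#' Training set: all clinically active JIA knees plus both knees of a
#' random fraction (default 80\%) of control subjects. Test set: all
#' inactive JIA knees plus the knees of the remaining control subjects.
#' Controls are partitioned at the subject level so that the two knees of a
#' subject never straddle the split.
#'
#' @param metadata cohort metadata (knee_id, subject_id, group, activity).
#' @param control_train_fraction fraction of control subjects assigned to
#'   training (default 0.8).
#' @param seed integer seed for the control partition.
#' @return object of class \code{jae_split} with \code{train_ids},
#'   \code{test_ids}, \code{seed}.
#' @export
make_split <- function(metadata, control_train_fraction = 0.8, seed = 1L) {
  if (control_train_fraction < 0 || control_train_fraction > 1)
    stop("control_train_fraction must lie in [0, 1]")
  active <- metadata$knee_id[metadata$activity == "active"]
  inactive <- metadata$knee_id[metadata$activity == "inactive"]
  ctl_subjects <- unique(metadata$subject_id[metadata$group == "control"])
  if (length(active) == 0L) stop("no active knees in metadata")
  if (length(ctl_subjects) == 0L) stop("no control subjects in metadata")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  n_train <- round(control_train_fraction * length(ctl_subjects))
  train_subj <- if (n_train > 0L) sample(ctl_subjects, n_train) else character(0)
  test_subj <- setdiff(ctl_subjects, train_subj)
  if (length(test_subj) == 0L)
    warning("control test set is empty (control_train_fraction = 1)")
  ctl_train <- metadata$knee_id[metadata$subject_id %in% train_subj]
  ctl_test <- metadata$knee_id[metadata$subject_id %in% test_subj]
  structure(list(train_ids = c(active, ctl_train),
                 test_ids = c(inactive, ctl_test),
                 seed = as.integer(seed)),
            class = "jae_split")
}

#' @export
print.jae_split <- function(x, ...) {
  cat(sprintf("Split plan: %d training knees, %d test knees (seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

default_hyperparams <- function() {
  list(nrounds = 200L, max_depth = 3L, eta = 0.1, subsample = 0.8)
}

# Gradient-boosted trees via the low-level xgboost interface. The intercept
# (base_score) is pinned at 0.5 rather than estimated from the training
# labels: leave-one-leg-out folds are one label short of balance, and a
# data-estimated intercept tracks that imbalance, anti-correlating held-out
# scores with the held-out label on null data.
fit_booster <- function(x, y01, hp, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y01, nthread = 1L)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = as.integer(hp$max_depth), eta = hp$eta,
                  subsample = hp$subsample, base_score = 0.5,
                  tree_method = "exact",
                  nthread = 1L, seed = as.integer(seed)),
    data = dtrain, nrounds = as.integer(hp$nrounds), verbose = 0)
}

booster_scores <- function(booster, x) {
  stats::predict(booster, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1L))
}

#' Fit the classification pipeline
#'
#' The full decision chain, fitted as one unit on the training rows only:
#' per-feature standardization (mean / standard deviation; constant
#' features get unit scale), principal component analysis retaining the
#' smallest number of components whose cumulative explained variance
#' reaches \code{variance_target} (capped at \code{max_components} and at
#' the matrix rank, never below 1), and a gradient-boosted tree classifier
#' (XGBoost, logistic objective) on the retained projections, emitting a
#' joint score in [0, 1] interpreted as the probability of JIA involvement.
#'
#' @param x numeric training matrix (knees x summary features).
#' @param y labels; coerced to factor. \code{positive} names the JIA class.
#' @param variance_target cumulative explained-variance target (default 0.95).
#' @param max_components component cap (default 60).
#' @param hyperparams list with \code{nrounds}, \code{max_depth},
#'   \code{eta}, \code{subsample}.
#' @param positive label value treated as the positive (JIA) class.
#' @param threshold decision threshold on the joint score (default 0.5;
#'   scores at the threshold are called positive).
#' @param seed integer seed passed to the booster.
#' @return object of class \code{jae_pipeline}.
#' @export
fit_pipeline <- function(x, y, variance_target = 0.95, max_components = 60L,
                         hyperparams = default_hyperparams(),
                         positive = "jia", threshold = 0.5, seed = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("fit_pipeline: training labels contain a single class")
  if (!positive %in% levels(y))
    stop("positive class '", positive, "' not present in labels")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  y01 <- as.integer(y == positive)

  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")

  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  evr <- ev[seq_len(rank)] / sum(ev[seq_len(rank)])
  k <- which(cumsum(evr) >= variance_target)[1L]
  if (is.na(k)) k <- rank
  k <- max(1L, min(k, max_components, rank))

  proj <- xs %*% pc$rotation[, seq_len(k), drop = FALSE]
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  booster <- fit_booster(proj, y01, hp, seed)

  structure(list(center = center, scale = scale,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_variance_ratio = evr, n_components = k,
                 booster = booster, hyperparams = hp,
                 positive = positive, threshold = threshold,
                 feature_names = colnames(x), seed = as.integer(seed)),
            class = "jae_pipeline")
}

#' @export
print.jae_pipeline <- function(x, ...) {
  cat("Joint-score classification pipeline\n")
  cat(sprintf("  features: %d; retained components: %d (%.1f%% variance)\n",
              length(x$center), x$n_components,
              100 * sum(x$explained_variance_ratio[seq_len(x$n_components)])))
  cat(sprintf("  booster: %d trees, depth %d, eta %g; threshold %.2f\n",
              x$hyperparams$nrounds, x$hyperparams$max_depth,
              x$hyperparams$eta, x$threshold))
  invisible(x)
}

#' @export
summary.jae_pipeline <- function(object, ...) {
  cat("Joint-score classification pipeline\n")
  k <- object$n_components
  evr <- object$explained_variance_ratio
  cat(sprintf("  %d summary features -> %d principal components\n",
              length(object$center), k))
  cat(sprintf("  cumulative explained variance: %.4f (target components)\n",
              sum(evr[seq_len(k)])))
  cat(sprintf("  leading component variance ratios: %s\n",
              paste(sprintf("%.3f", utils::head(evr, 5L)), collapse = " ")))
  cat(sprintf("  positive class: %s; decision threshold: %.2f\n",
              object$positive, object$threshold))
  invisible(object)
}

#' Joint scores for new knees
#'
#' Standardizes with the training statistics, projects onto the retained
#' components and returns the booster probability — the joint score in
#' [0, 1].
#'
#' @param object a fitted \code{jae_pipeline}.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return named numeric vector of scores in [0, 1].
#' @export
predict.jae_pipeline <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center) ||
      (!is.null(colnames(newdata)) && !is.null(object$feature_names) &&
       !identical(colnames(newdata), object$feature_names)))
    stop("predict: feature columns do not match the training schema")
  xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  proj <- xs %*% object$rotation
  p <- booster_scores(object$booster, proj)
  names(p) <- rownames(newdata)
  pmin(pmax(p, 0), 1)
}

#' Score a feature matrix, keeping labels
#'
#' @param model a \code{jae_pipeline}.
#' @param fm a \code{jae_feature_matrix} (or list with \code{x},
#'   \code{meta}).
#' @param fold fold tag for the output (default \code{"test"}).
#' @return data.frame: knee_id, fold, group, activity, label, score.
#' @export
predict_scores <- function(model, fm, fold = "test") {
  s <- predict(model, fm$x)
  data.frame(knee_id = fm$meta$knee_id, fold = fold,
             group = fm$meta$group, activity = fm$meta$activity,
             label = ifelse(fm$meta$group == "jia", "jia", "control"),
             score = as.numeric(s), stringsAsFactors = FALSE)
}

#' Leave-one-leg-out cross-validation
#'
#' For every training knee the full pipeline — standardization, PCA and
#' booster — is refitted on all remaining knees and the held-out knee is
#' scored, so no fold statistic ever sees the held-out row. The other knee
#' of the same subject stays in the training fold (leg-wise design);
#' \code{grouping = "subject"} switches to leave-one-subject-out. The
#' alternative \code{pca_scope = "prefit"} fits standardization and PCA
#' once on the full training set before cross-validating the booster only
#' (the leaky ordering, kept for comparison).
#'
#' @param x training matrix (knees x features).
#' @param y labels (see [fit_pipeline()]).
#' @param grouping \code{"leg"} (default) or \code{"subject"}; subject ids
#'   are taken from \code{subject} when grouping by subject.
#' @param subject optional subject id per row (required for
#'   \code{grouping = "subject"}).
#' @param pca_scope \code{"fold"} (refit inside every fold, default) or
#'   \code{"prefit"}.
#' @param seed master seed; per-fold booster seeds are derived from it.
#' @inheritParams fit_pipeline
#' @return data.frame with one row per knee: knee_id, fold, label, score.
#' @export
lolo_cv <- function(x, y, variance_target = 0.95, max_components = 60L,
                    hyperparams = default_hyperparams(), positive = "jia",
                    grouping = c("leg", "subject"), subject = NULL,
                    pca_scope = c("fold", "prefit"), seed = 1L) {
  grouping <- match.arg(grouping)
  pca_scope <- match.arg(pca_scope)
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  if (n < 3L) stop("lolo_cv: need at least 3 training knees")
  if (grouping == "subject" && is.null(subject))
    stop("grouping = 'subject' requires subject ids")
  folds <- if (grouping == "leg") as.list(seq_len(n))
           else split(seq_len(n), subject)

  prefit <- NULL
  if (pca_scope == "prefit") {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
    xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
    pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2
    rank <- sum(ev > max(ev) * 1e-12)
    evr <- ev[seq_len(rank)] / sum(ev[seq_len(rank)])
    k <- which(cumsum(evr) >= variance_target)[1L]
    if (is.na(k)) k <- rank
    k <- max(1L, min(k, max_components, rank))
    prefit <- xs %*% pc$rotation[, seq_len(k), drop = FALSE]
  }

  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("knee%03d", seq_len(n))
  out <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    hold <- folds[[fi]]
    keep <- setdiff(seq_len(n), hold)
    if (nlevels(droplevels(y[keep])) < 2L)
      stop(sprintf("lolo_cv: fold %d has a single training class", fi))
    fold_seed <- (as.integer(seed) + 7919L * fi) %% .Machine$integer.max
    if (pca_scope == "fold") {
      fit <- fit_pipeline(x[keep, , drop = FALSE], y[keep],
                          variance_target = variance_target,
                          max_components = max_components,
                          hyperparams = hyperparams, positive = positive,
                          seed = fold_seed)
      sc <- predict(fit, x[hold, , drop = FALSE])
    } else {
      hp <- utils::modifyList(default_hyperparams(), hyperparams)
      booster <- fit_booster(prefit[keep, , drop = FALSE],
                             as.integer(y[keep] == positive), hp, fold_seed)
      sc <- booster_scores(booster, prefit[hold, , drop = FALSE])
    }
    out[[fi]] <- data.frame(knee_id = ids[hold], fold = fi,
                            label = as.character(y[hold]),
                            score = as.numeric(sc),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
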