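make_meta <- function(n_jia = 5L, n_ctl = 30L, active = NULL) {
  subj <- c(sprintf("JIA%03d", seq_len(n_jia)), sprintf("CTL%03d", seq_len(n_ctl)))
  grp <- rep(c("jia", "control"), c(n_jia, n_ctl))
  meta <- data.frame(subject_id = rep(subj, each = 2L),
                     knee_side = rep(c("left", "right"), n_jia + n_ctl),
                     group = rep(grp, each = 2L), stringsAsFactors = FALSE)
  meta$knee_id <- paste(meta$subject_id, meta$knee_side, sep = "_")
  meta$activity <- ifelse(meta$group == "control", "none", "inactive")
  if (is.null(active)) active <- which(meta$group == "jia")[c(TRUE, FALSE)]
  meta$activity[active] <- "active"
  meta
}

test_that("the split plan reproduces the 80/20 control partition", {
  meta <- make_meta()
  sp <- make_split(meta, 0.8, seed = 5L)
  ctl_train <- grepl("^CTL", sp$train_ids)
  expect_identical(sum(ctl_train), 48L)                 # 24 subjects x 2 knees
  expect_identical(sum(grepl("^CTL", sp$test_ids)), 12L)
  expect_identical(make_split(meta, 0.8, seed = 5L)$train_ids, sp$train_ids)
  expect_false(identical(make_split(meta, 0.8, seed = 6L)$train_ids,
                         sp$train_ids))
  expect_warning(make_split(meta, 1.0, seed = 1L), "empty")
})

test_that("split invariants hold on every generated plan", {
  meta <- make_meta()
  for (seed in 1:20) {
    sp <- make_split(meta, 0.8, seed = seed)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
    expect_true(all(meta$knee_id[meta$activity == "active"] %in% sp$train_ids))
    expect_true(all(meta$knee_id[meta$activity == "inactive"] %in% sp$test_ids))
    # both knees of each control subject co-assigned
    for (ids in list(sp$train_ids, sp$test_ids)) {
      subj <- sub("_(left|right)$", "", ids[grepl("^CTL", ids)])
      expect_true(all(table(subj) == 2L))
    }
  }
  expect_error(make_split(meta[meta$group == "jia", ], 0.8, 1L), "control")
  expect_error(make_split(meta[meta$activity != "active", ], 0.8, 1L), "active")
})

test_that("PCA retention follows the smallest-k rule with the cap", {
  # rank-1 matrix: one component explaining everything
  x1 <- outer(1:10, seq(0.1, 1, length.out = 20))
  colnames(x1) <- paste0("f", 1:20)
  f1 <- fit_pipeline(x1 + 0, rep(c("jia", "control"), 5),
                     hyperparams = list(nrounds = 5L))
  expect_identical(f1$n_components, 1L)
  expect_equal(f1$explained_variance_ratio[1], 1.0, tolerance = 1e-9)

  # isotropic Gaussian: the 60-component cap binds before 95% variance
  set.seed(12)
  x2 <- matrix(rnorm(200 * 100), 200, 100)
  colnames(x2) <- paste0("f", 1:100)
  f2 <- fit_pipeline(x2, rep(c("jia", "control"), 100),
                     hyperparams = list(nrounds = 5L))
  expect_identical(f2$n_components, 60L)

  # brute-force eigendecomposition agrees with the retained count rule
  xs <- scale(x2)
  ev <- sort(eigen(stats::cov(xs), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  evr <- ev / sum(ev)
  k_bf <- min(which(cumsum(evr) >= 0.95)[1], 60L)
  expect_identical(f2$n_components, as.integer(k_bf))

  # variance_target 0 keeps a single component
  f3 <- fit_pipeline(x2, rep(c("jia", "control"), 100), variance_target = 0,
                     hyperparams = list(nrounds = 5L))
  expect_identical(f3$n_components, 1L)

  expect_error(fit_pipeline(x2, rep("jia", 200)), "single class")
})

test_that("joint scores live in [0, 1] and separate a separable toy set", {
  toy <- toy_separable()
  fit <- fit_pipeline(toy$x, toy$y, hyperparams = list(nrounds = 50L))
  s <- predict(fit, toy$x)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all((s >= 0.5) == (toy$y == "jia")))
  # determinism for a duplicated row
  expect_identical(unname(predict(fit, toy$x[c(1, 1), ])[1]),
                   unname(predict(fit, toy$x[c(1, 1), ])[2]))
  bad <- toy$x[, 1:3]
  expect_error(predict(fit, bad), "schema")
})

test_that("LOLO-CV scores every knee once and nails separable data", {
  toy <- toy_separable(n_per_class = 8L)
  cv <- lolo_cv(toy$x, toy$y, hyperparams = list(nrounds = 50L), seed = 2L)
  expect_identical(nrow(cv), 16L)
  expect_identical(sort(cv$knee_id), sort(rownames(toy$x)))
  expect_identical(anyDuplicated(cv$knee_id), 0L)
  expect_true(all((cv$score >= 0.5) == (cv$label == "jia")))
  expect_error(lolo_cv(toy$x[1:2, ], toy$y[1:2]), "at least 3")
})

test_that("subject grouping holds both knees of a subject out together", {
  toy <- toy_separable(n_per_class = 6L)
  subject <- rep(sprintf("S%02d", 1:6), each = 2L)
  cv <- lolo_cv(toy$x, toy$y, grouping = "subject", subject = subject,
                hyperparams = list(nrounds = 20L), seed = 3L)
  expect_identical(nrow(cv), 12L)
  folds <- tapply(cv$fold, subject[match(cv$knee_id, rownames(toy$x))],
                  function(v) length(unique(v)))
  expect_true(all(folds == 1L))
})

test_that("fold statistics never include the held-out knee", {
  toy <- toy_separable(n_per_class = 6L)
  full <- fit_pipeline(toy$x, toy$y, hyperparams = list(nrounds = 5L))
  fold <- fit_pipeline(toy$x[-1, ], toy$y[-1],
                       hyperparams = list(nrounds = 5L))
  # on non-degenerate data the fold standardization must differ
  expect_false(isTRUE(all.equal(full$center, fold$center)))
  expect_false(isTRUE(all.equal(full$scale, fold$scale)))
})

test_that("prefit PCA scope reuses one global projection", {
  toy <- toy_separable(n_per_class = 6L)
  cv <- lolo_cv(toy$x, toy$y, pca_scope = "prefit",
                hyperparams = list(nrounds = 20L), seed = 4L)
  expect_identical(nrow(cv), 12L)
  expect_true(all(cv$score >= 0 & cv$score <= 1))
})
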