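test_that("metrics match a brute-force confusion recount", {
  # perfect predictions
  y <- rep(c("active", "inactive"), c(4, 6))
  m <- compute_metrics(y, y)
  expect_equal(unlist(m[c("precision", "recall", "f1", "accuracy", "mcc")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1, mcc = 1))

  # frozen worked example: TP=3, FP=1, TN=4, FN=2 -> MCC = 10/sqrt(600)
  truth <- rep(c("active", "inactive"), c(5, 5))
  pred <- c("active", "active", "active", "inactive", "inactive",
            "active", "inactive", "inactive", "inactive", "inactive")
  cc <- count_confusion(pred, truth)
  expect_equal(cc, c(TP = 3L, TN = 4L, FP = 1L, FN = 2L))
  m <- compute_metrics(pred, truth)
  expect_equal(m$TP, 3L); expect_equal(m$FP, 1L)
  expect_equal(m$mcc, 10 / sqrt(600))
  expect_equal(round(m$mcc, 3), 0.408)

  # property over random label vectors: identities and oracle agreement
  set.seed(99)
  for (i in 1:60) {
    n <- sample(3:40, 1)
    truth <- sample(c("active", "inactive"), n, replace = TRUE)
    pred <- sample(c("active", "inactive"), n, replace = TRUE)
    m <- suppressWarnings(compute_metrics(pred, truth))
    cc <- count_confusion(pred, truth)
    expect_identical(c(TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN), cc)
    expect_equal(m$accuracy, (cc["TP"] + cc["TN"]) / n, ignore_attr = TRUE)
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  }
})

test_that("degenerate metric denominators warn and report 0", {
  allneg <- rep("inactive", 5)
  w <- capture_warnings(m <- compute_metrics(allneg, allneg))
  expect_true(any(grepl("MCC", w)))
  expect_true(any(grepl("precision", w)))
  expect_equal(m$accuracy, 1)
  expect_equal(m$mcc, 0)
  expect_error(compute_metrics("active", c("active", "inactive")),
               class = "gpcrstates_validation_error")
  expect_error(compute_metrics("maybe", "active"),
               class = "gpcrstates_validation_error")
})

test_that("training rejects degenerate inputs and unknown hyperparameters", {
  ds <- fixture_model_env$ds %||% { fixture_model(); fixture_model_env$ds }
  folds <- fixture_model_env$folds
  one_class <- ds
  one_class$labels <- rep("active", length(ds$labels))
  expect_error(train_state_model(one_class, folds, cv_k = 0),
               class = "gpcrstates_validation_error")
  expect_error(train_state_model(ds, folds, hyperparameters = list(bogus = 1)),
               "bogus", class = "gpcrstates_validation_error")
})

test_that("models beat the nearest-centroid oracle on separable data", {
  ds <- fixture_model_env$ds %||% { fixture_model(); fixture_model_env$ds }
  folds <- fixture_model_env$folds
  tr <- ds$traj_id %in% folds$traj_id[folds$partition == "train"]
  oracle_pred <- centroid_oracle(ds$matrix[tr, ], ds$labels[tr],
                                 ds$matrix[!tr, ])
  oracle_acc <- mean(oracle_pred == ds$labels[!tr])
  expect_gte(oracle_acc, 0.95)
  for (fam in c("random_forest", "svm", "gbt")) {
    acc <- evaluate_state_model(fixture_model(fam), ds, folds)$accuracy
    expect_gte(acc, 0.95)
    expect_gte(acc, oracle_acc - 0.02)
  }
})

test_that("scores stay in [0,1] and centroid descriptors score correctly", {
  ds <- fixture_model_env$ds %||% { fixture_model(); fixture_model_env$ds }
  m <- fixture_model()
  sc <- score_state_model(m, ds$matrix)
  expect_true(all(sc >= 0 & sc <= 1))
  centroid_act <- colMeans(ds$matrix[ds$labels == "active", , drop = FALSE])
  centroid_ina <- colMeans(ds$matrix[ds$labels == "inactive", , drop = FALSE])
  names(centroid_act) <- names(centroid_ina) <- colnames(ds$matrix)
  expect_gt(score_state_model(m, centroid_act), 0.5)
  expect_lt(score_state_model(m, centroid_ina), 0.5)
})

test_that("pair misalignment is refused, never silently reordered", {
  m <- fixture_model()
  d <- fixture_model_env$ds$matrix[1, ]
  names(d) <- rev(names(d))
  expect_error(score_state_model(m, d), class = "gpcrstates_pair_mismatch")
  expect_error(score_state_model(m, unname(d)),
               class = "gpcrstates_pair_mismatch")
})

test_that("identical seeds give identical predictions, bundles round-trip bitwise", {
  ds <- fixture_model_env$ds %||% { fixture_model(); fixture_model_env$ds }
  folds <- fixture_model_env$folds
  probe <- ds$matrix[seq(1, nrow(ds$matrix), by = 7), , drop = FALSE]
  for (fam in c("random_forest", "svm", "gbt")) {
    m1 <- train_state_model(ds, folds, family = fam, seed = 17, cv_k = 0)
    m2 <- train_state_model(ds, folds, family = fam, seed = 17, cv_k = 0)
    expect_identical(score_state_model(m1, probe), score_state_model(m2, probe))
    f <- withr::local_tempfile(fileext = ".json")
    save_state_model(m1, f)
    m3 <- load_state_model(f)
    expect_identical(score_state_model(m1, probe), score_state_model(m3, probe))
    expect_identical(m3$family, fam)
    expect_identical(m3$pairs, m1$pairs)
  }
  # different forest seeds grow different trees (scores may still agree on
  # perfectly separable data, so compare the fitted ensembles themselves)
  m4 <- train_state_model(ds, folds, seed = 18, cv_k = 0)
  m1 <- train_state_model(ds, folds, seed = 17, cv_k = 0)
  expect_false(identical(m1$fit$trees, m4$fit$trees))
})

test_that("decision paths report the traversed splits faithfully", {
  # craft a 2-feature dataset where 5x62:6x37 separates at ~10 A
  pairs <- tiny_pairs()
  n <- 40
  X <- cbind("5x62:6x37" = c(rep(6, n / 2), rep(15, n / 2)) + seq(-.5, .5, length.out = n),
             "7x45:7x49" = rep(3, n))
  ds <- structure(list(matrix = X,
                       labels = rep(c("active", "inactive"), each = n / 2),
                       traj_id = rep(sprintf("t%d", 1:8), each = n / 8),
                       frame_index = seq_len(n), pairs = pairs),
                  class = "gpcr_dataset")
  folds <- assign_folds(ds, 6, 2, seed = 1)
  m <- train_state_model(ds, folds, hyperparameters = list(n_trees = 5L,
                                                           mtry = 2L),
                         seed = 1, cv_k = 0)
  d <- c("5x62:6x37" = 6.07, "7x45:7x49" = 3)
  path <- explain_state_model(m, d, estimator = 1L)
  expect_s3_class(path, "gpcr_decision_path")
  expect_equal(path$pair[1], "5x62:6x37")
  expect_equal(path$branch[1], "<=")
  expect_equal(path$observed[1], 6.07)
  expect_gt(attr(path, "leaf_value"), 0.5)
  # branch consistency along every step
  for (i in seq_len(nrow(path)))
    expect_identical(path$branch[i],
                     if (path$observed[i] <= path$threshold[i]) "<=" else ">")

  # depth-0 tree (min_split too large to split): empty path + leaf vote
  m0 <- train_state_model(ds, folds, hyperparameters = list(min_split = 10000L),
                          seed = 1, cv_k = 0)
  p0 <- explain_state_model(m0, d, 1L)
  expect_equal(nrow(p0), 0L)
  expect_true(is.finite(attr(p0, "leaf_value")))

  expect_error(explain_state_model(m, d, estimator = 9999L),
               class = "gpcrstates_validation_error")
  expect_error(explain_state_model(fixture_model("svm"),
                                   fixture_model_env$ds$matrix[1, ], 1L),
               class = "gpcrstates_not_explainable")
})

test_that("feature report ranks the informative feature first", {
  # only feature 1 carries signal by construction
  set.seed(5)
  n <- 120
  X <- cbind("5x62:6x37" = c(rnorm(n / 2, 6, .3), rnorm(n / 2, 15, .3)),
             "7x45:7x49" = rnorm(n, 8, .5))
  labs <- rep(c("active", "inactive"), each = n / 2)
  ds <- structure(list(matrix = X, labels = labs,
                       traj_id = rep(sprintf("t%d", 1:8), each = n / 8),
                       frame_index = seq_len(n), pairs = tiny_pairs()),
                  class = "gpcr_dataset")
  folds <- assign_folds(ds, 6, 2, seed = 1)
  m <- train_state_model(ds, folds, seed = 1, cv_k = 0)
  rep_ <- feature_report(m, ds)
  expect_equal(rep_$importance$pair[1], "5x62:6x37")
  expect_equal(sum(rep_$importance$importance), 1, tolerance = 1e-9)

  # oracle: single-feature threshold classifiers agree on which feature wins
  single_feature_acc <- function(j) {
    thr <- mean(tapply(X[, j], labs, mean))
    max(mean((X[, j] <= thr) == (labs == "active")),
        mean((X[, j] > thr) == (labs == "active")))
  }
  expect_gt(single_feature_acc(1), single_feature_acc(2))

  # duplicated column -> |r| = 1 flagged; constant column -> undefined
  X2 <- cbind(X, X[, 1], rep(4, n))
  colnames(X2) <- c(colnames(X), "3x50:7x53", "2x50:3x39")
  ds2 <- ds
  ds2$matrix <- X2
  ds2$pairs <- as_pairlist(data.frame(
    a = c("5x62", "7x45", "3x50", "2x50"),
    b = c("6x37", "7x49", "7x53", "3x39")))
  m2 <- train_state_model(ds2, folds, seed = 1, cv_k = 0)
  rep2 <- feature_report(m2, ds2)
  dup <- rep2$correlated[rep2$correlated$pair_a == "5x62:6x37" &
                           rep2$correlated$pair_b == "3x50:7x53", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(abs(dup$r), 1, tolerance = 1e-12)
  expect_true("2x50:3x39" %in% rep2$undefined)
})

test_that("grouped CV metrics are recorded without trajectory leakage", {
  ds <- fixture_model_env$ds %||% { fixture_model(); fixture_model_env$ds }
  folds <- fixture_model_env$folds
  m <- train_state_model(ds, folds, seed = 3, cv_k = 3)
  cv <- m$metadata$cv_metrics
  expect_s3_class(cv, "data.frame")
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  expect_true(all(cv$mcc >= -1 & cv$mcc <= 1))
})
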