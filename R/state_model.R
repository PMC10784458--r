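MODEL_FAMILIES <- c("random_forest", "svm", "gbt")

default_hyperparameters <- function(family, p) {
  switch(family,
    random_forest = list(n_trees = 100L, mtry = max(1L, floor(sqrt(p))),
                         max_depth = 0L, min_split = 2L, min_leaf = 1L),
    gbt = list(n_rounds = 100L, learning_rate = 0.1, max_depth = 3L,
               min_leaf = 1L),
    svm = list(lambda = 1e-3, maxit = 500L))
}

#' Train the conformational-state classifier
#'
#' Fits a classifier on the TRAIN partition of a trajectory-stratified fold
#' assignment and reports grouped cross-validation metrics: every CV
#' iteration holds out whole trajectories, never individual frames, so
#' near-duplicate frames of one simulation cannot leak between fit and
#' validation subsets.
#'
#' The positive class is `"active"`: scores are the probability of the
#' active state.
#'
#' @param dataset A `gpcr_dataset`.
#' @param folds A `gpcr_folds` from [assign_folds()].
#' @param family `"random_forest"` (default, 100 trees), `"svm"` (linear,
#'   Platt-calibrated scores) or `"gbt"` (gradient-boosted trees).
#' @param hyperparameters Named list overriding family defaults; unknown
#'   keys are an error.
#' @param seed Integer seed; fixed seed gives bitwise-identical models.
#' @param cv_k Number of grouped CV iterations over the train folds (5 by
#'   default); `cv_k = 0` skips cross-validation.
#' @return A `gpcr_state_model` with fields `family`, `fit`, `pairs`
#'   (descriptor component order, validated at scoring time), `metadata`
#'   (seed, fold scheme, class prior, hyperparameters, CV metrics).
#' @export
train_state_model <- function(dataset, folds, family = "random_forest",
                              hyperparameters = list(), seed = 1L, cv_k = 5L) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (!all(unique(dataset$traj_id) %in% folds$traj_id))
    gpcr_abort("fold assignment does not cover every dataset trajectory",
               "gpcrstates_validation_error")
  check_no_leakage(folds)
  hp <- default_hyperparameters(family, ncol(dataset$matrix))
  unknown <- setdiff(names(hyperparameters), names(hp))
  if (length(unknown))
    gpcr_abort(sprintf("unknown hyperparameter(s) for %s: %s", family,
                       paste(unknown, collapse = ", ")),
               "gpcrstates_validation_error")
  hp[names(hyperparameters)] <- hyperparameters
  train_ids <- folds$traj_id[folds$partition == "train"]
  in_train <- dataset$traj_id %in% train_ids
  if (!any(in_train))
    gpcr_abort("empty train partition", "gpcrstates_validation_error")
  y <- dataset$labels[in_train]
  if (length(unique(y)) < 2L)
    gpcr_abort("training data contains a single class; need both states",
               "gpcrstates_validation_error")
  X <- dataset$matrix[in_train, , drop = FALSE]
  tid <- dataset$traj_id[in_train]

  cv_metrics <- NULL
  if (cv_k > 0L) {
    groups <- assign_cv_groups(folds, k = cv_k, seed = seed)
    rows <- lapply(seq_len(cv_k), function(g) {
      hold <- groups$traj_id[groups$cv_group == g]
      vi <- tid %in% hold
      if (!any(vi) || length(unique(y[!vi])) < 2L) return(NULL)
      fit <- fit_family(X[!vi, , drop = FALSE], y[!vi], family, hp,
                        seed + g)
      sc <- predict_family(fit, family, X[vi, , drop = FALSE])
      m <- suppressWarnings(
        compute_metrics(ifelse(sc > 0.5, "active", "inactive"), y[vi]))
      data.frame(iteration = g, n_holdout_traj = length(hold),
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 accuracy = m$accuracy, mcc = m$mcc)
    })
    cv_metrics <- do.call(rbind, rows)
  }
  fit <- fit_family(X, y, family, hp, seed)
  base::structure(list(
    family = family,
    fit = fit,
    pairs = colnames(dataset$matrix),
    pairlist = dataset$pairs,
    metadata = list(
      seed = as.integer(seed),
      fold_scheme = list(n_train = sum(folds$partition == "train"),
                         n_test = sum(folds$partition == "test"),
                         cv_k = as.integer(cv_k)),
      class_prior = mean(y == "active"),
      hyperparameters = hp,
      cv_metrics = cv_metrics)),
    class = "gpcr_state_model")
}

fit_family <- function(X, y, family, hp, seed) {
  y01 <- as.integer(y == "active")
  if (family == "random_forest") {
    cpp_grow_forest(X, y01, hp$n_trees, hp$mtry, hp$max_depth, hp$min_split,
                    hp$min_leaf, as.integer(seed))
  } else if (family == "gbt") {
    cpp_gbt_fit(X, y01, hp$n_rounds, hp$learning_rate, hp$max_depth,
                hp$min_leaf)
  } else {
    fit_linear_svm(X, y01, hp$lambda, hp$maxit)
  }
}

# linear squared-hinge SVM (BFGS) on standardized features, with Platt
# sigmoid calibration of the decision values fitted by Newton iterations
fit_linear_svm <- function(X, y01, lambda, maxit) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yy <- ifelse(y01 == 1L, 1, -1)
  p <- ncol(Xs)
  obj <- function(th) {
    f <- drop(Xs %*% th[1:p]) + th[p + 1]
    m <- pmax(0, 1 - yy * f)
    mean(m^2) + lambda * sum(th[1:p]^2)
  }
  grad <- function(th) {
    f <- drop(Xs %*% th[1:p]) + th[p + 1]
    m <- pmax(0, 1 - yy * f)
    gf <- -2 * yy * m / length(yy)
    c(drop(crossprod(Xs, gf)) + 2 * lambda * th[1:p], sum(gf))
  }
  fit <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  w <- fit$par[1:p]; b <- fit$par[p + 1]
  dec <- drop(Xs %*% w) + b
  platt <- platt_fit(dec, y01)
  list(w = w, b = b, center = ctr, scale = scl, platt = platt)
}

# logistic fit p(active) = 1/(1+exp(A*f+B)) via Newton-Raphson (Platt 1999)
platt_fit <- function(dec, y01, iters = 50L) {
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  t <- ifelse(y01 == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  ab <- c(0, log((n0 + 1) / (n1 + 1)))
  for (i in seq_len(iters)) {
    f <- ab[1] * dec + ab[2]
    p <- 1 / (1 + exp(f))
    g <- c(sum(dec * (p - t)), sum(p - t)) * -1
    W <- p * (1 - p)
    H <- matrix(c(sum(dec^2 * W), sum(dec * W), sum(dec * W), sum(W) + 1e-12),
                2, 2)
    step <- tryCatch(solve(H, g), error = function(e) c(0, 0))
    ab <- ab - step
    if (sum(abs(step)) < 1e-10) break
  }
  c(A = ab[1], B = ab[2])
}

predict_family <- function(fit, family, X) {
  if (family == "random_forest") {
    cpp_forest_score(fit$trees, X)
  } else if (family == "gbt") {
    cpp_gbt_score(fit, X)
  } else {
    Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
    dec <- drop(Xs %*% fit$w) + fit$b
    1 / (1 + exp(fit$platt["A"] * dec + fit$platt["B"]))
  }
}

#' @export
print.gpcr_state_model <- function(x, ...) {
  cat(sprintf("<state model> family: %s, %d descriptor pairs, seed %d\n",
              x$family, length(x$pairs), x$metadata$seed))
  if (!is.null(x$metadata$cv_metrics)) {
    m <- x$metadata$cv_metrics
    cat(sprintf("  grouped %d-fold CV: accuracy %.3f, MCC %.3f\n",
                nrow(m), mean(m$accuracy), mean(m$mcc)))
  }
  invisible(x)
}

# validates descriptor/pair alignment and returns a 1 x p or n x p matrix
descriptor_to_matrix <- function(model, descriptor) {
  if (is.matrix(descriptor)) {
    nm <- colnames(descriptor)
  } else {
    nm <- names(descriptor)
    descriptor <- matrix(descriptor, 1, dimnames = list(NULL, nm))
  }
  if (is.null(nm) || !identical(nm, model$pairs))
    gpcr_abort(paste0("descriptor pair order does not match the model's ",
                      "pair list; refusing to reorder silently"),
               "gpcrstates_pair_mismatch")
  descriptor
}

#' Score a conformation with the state model
#'
#' @param model A `gpcr_state_model`.
#' @param descriptor A `gpcr_descriptor` (or a named matrix of them). The
#'   pair names and order must match the model's stored pair list exactly.
#' @return Active-state score(s) in `[0, 1]`.
#' @export
score_state_model <- function(model, descriptor) {
  X <- descriptor_to_matrix(model, descriptor)
  predict_family(model$fit, model$family, X)
}

#' Binary classification metrics
#'
#' Precision, recall, F1, accuracy and Matthews correlation coefficient
#' from the confusion counts, with `"active"` as the positive class.
#' Degenerate denominators yield a flagged 0 sentinel with a warning
#' rather than NaN.
#'
#' @param predicted,truth Equal-length character vectors over
#'   `{"active", "inactive"}`.
#' @return A `gpcr_metrics` list: `TP`, `TN`, `FP`, `FN`, `precision`,
#'   `recall`, `f1`, `accuracy`, `mcc`.
#' @examples
#' compute_metrics(c("active", "inactive"), c("active", "inactive"))
#' @export
compute_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    gpcr_abort("predicted and truth differ in length",
               "gpcrstates_validation_error")
  ok <- c("active", "inactive")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    gpcr_abort("labels must be 'active' or 'inactive'",
               "gpcrstates_validation_error")
  TP <- sum(predicted == "active" & truth == "active")
  TN <- sum(predicted == "inactive" & truth == "inactive")
  FP <- sum(predicted == "active" & truth == "inactive")
  FN <- sum(predicted == "inactive" & truth == "active")
  safe <- function(num, den, what) {
    if (den == 0) {
      gpcr_warn(sprintf("%s undefined (zero denominator); reporting 0", what),
                "gpcrstates_degenerate_metric")
      return(0)
    }
    num / den
  }
  precision <- safe(TP, TP + FP, "precision")
  recall <- safe(TP, TP + FN, "recall")
  f1 <- safe(2 * precision * recall, precision + recall, "F1")
  accuracy <- (TP + TN) / length(truth)
  mcc_den <- sqrt(as.numeric(TP + FP) * as.numeric(TP + FN) *
                    as.numeric(TN + FP) * as.numeric(TN + FN))
  mcc <- if (mcc_den == 0) {
    gpcr_warn("MCC undefined (zero denominator); reporting 0",
              "gpcrstates_degenerate_metric")
    0
  } else (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  base::structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                       precision = precision, recall = recall, f1 = f1,
                       accuracy = accuracy, mcc = mcc),
                  class = "gpcr_metrics")
}

#' @export
print.gpcr_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f  MCC %.4f\n",
              x$precision, x$recall, x$f1, x$accuracy, x$mcc))
  invisible(x)
}

#' Evaluate a model on one partition of a dataset
#'
#' @param model A `gpcr_state_model`.
#' @param dataset A `gpcr_dataset` whose columns match the model's pairs.
#' @param folds A `gpcr_folds`.
#' @param partition `"test"` (default) or `"train"`.
#' @param theta Score threshold for calling a frame active.
#' @return A `gpcr_metrics`.
#' @export
evaluate_state_model <- function(model, dataset, folds, partition = "test",
                                 theta = 0.5) {
  ids <- folds$traj_id[folds$partition == partition]
  sel <- dataset$traj_id %in% ids
  if (!any(sel))
    gpcr_abort(sprintf("no frames in partition '%s'", partition),
               "gpcrstates_validation_error")
  sc <- score_state_model(model, dataset$matrix[sel, , drop = FALSE])
  compute_metrics(ifelse(sc > theta, "active", "inactive"),
                  dataset$labels[sel])
}

#' Trace the decision path of one tree for one conformation
#'
#' Walks the chosen estimator from root to leaf with the descriptor's
#' observed distances and reports every split: which residue pair was
#' interrogated, the learned threshold, the observed distance, and the
#' branch taken.
#'
#' @param model A tree-based `gpcr_state_model` (`random_forest` or
#'   `gbt`).
#' @param descriptor A `gpcr_descriptor` matching the model's pairs.
#' @param estimator 1-based tree index.
#' @return A `gpcr_decision_path` data frame with columns `pair`,
#'   `threshold`, `observed`, `branch`, plus attributes `leaf_value`
#'   (active-class fraction at the leaf for forests; additive logit
#'   contribution for boosted trees) and `estimator`.
#' @export
explain_state_model <- function(model, descriptor, estimator = 1L) {
  if (!model$family %in% c("random_forest", "gbt"))
    gpcr_abort(sprintf("family '%s' is not explainable (tree families only)",
                       model$family), "gpcrstates_not_explainable")
  trees <- model$fit$trees
  if (estimator < 1L || estimator > length(trees))
    gpcr_abort(sprintf("estimator index %d out of range 1..%d", estimator,
                       length(trees)), "gpcrstates_validation_error")
  x <- drop(descriptor_to_matrix(model, descriptor))
  tree <- trees[[estimator]]
  node <- 1L
  steps <- list()
  while (tree$feature[node] >= 0L) {
    f <- tree$feature[node] + 1L
    thr <- tree$threshold[node]
    obs <- x[f]
    left <- obs <= thr
    steps[[length(steps) + 1L]] <- data.frame(
      pair = model$pairs[f], threshold = thr, observed = unname(obs),
      branch = if (left) "<=" else ">", stringsAsFactors = FALSE)
    node <- (if (left) tree$left[node] else tree$right[node]) + 1L
  }
  path <- if (length(steps)) do.call(rbind, steps) else
    data.frame(pair = character(), threshold = numeric(),
               observed = numeric(), branch = character(),
               stringsAsFactors = FALSE)
  base::structure(path, leaf_value = tree$value[node],
                  estimator = as.integer(estimator),
                  class = c("gpcr_decision_path", "data.frame"))
}

#' @export
print.gpcr_decision_path <- function(x, ...) {
  cat(sprintf("<decision path> estimator %d, %d splits, leaf value %.3f\n",
              attr(x, "estimator"), nrow(x), attr(x, "leaf_value")))
  if (nrow(x))
    print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Feature importances and cross-correlation report
#'
#' Ranks the model's impurity-decrease feature importances (they sum to 1)
#' and computes the pairwise Pearson correlation matrix of the dataset's
#' descriptor columns, flagging any feature pair with `|r| >= 0.9`.
#' Constant columns yield undefined correlations; these are flagged, not
#' fatal.
#'
#' @param model A tree-based `gpcr_state_model`.
#' @param dataset A `gpcr_dataset` with at least 2 frames.
#' @return A `gpcr_feature_report` list: `importance` (ranked data
#'   frame), `correlation` (symmetric matrix, unit diagonal),
#'   `correlated` (data frame of flagged pairs), `undefined` (labels of
#'   constant columns).
#' @export
feature_report <- function(model, dataset) {
  if (!model$family %in% c("random_forest", "gbt"))
    gpcr_abort("feature importances require a tree-based family",
               "gpcrstates_not_explainable")
  if (nrow(dataset$matrix) < 2L)
    gpcr_abort("need at least 2 frames for a correlation report",
               "gpcrstates_validation_error")
  imp <- data.frame(pair = model$pairs,
                    importance = as.numeric(model$fit$importance),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$importance), , drop = FALSE]
  rownames(imp) <- NULL
  sds <- apply(dataset$matrix, 2, stats::sd)
  undefined <- colnames(dataset$matrix)[sds == 0]
  cm <- suppressWarnings(stats::cor(dataset$matrix))
  diag(cm) <- 1
  ij <- which(upper.tri(cm) & !is.na(cm) & abs(cm) >= 0.9, arr.ind = TRUE)
  correlated <- data.frame(
    pair_a = colnames(cm)[ij[, 1]], pair_b = colnames(cm)[ij[, 2]],
    r = cm[ij], stringsAsFactors = FALSE)
  base::structure(list(importance = imp, correlation = cm,
                       correlated = correlated, undefined = undefined),
                  class = "gpcr_feature_report")
}

#' @export
print.gpcr_feature_report <- function(x, ...) {
  cat("<feature report> top pairs by importance:\n")
  print(utils::head(x$importance, 5), row.names = FALSE)
  cat(sprintf("%d feature pair(s) with |r| >= 0.9; %d undefined column(s)\n",
              nrow(x$correlated), length(x$undefined)))
  invisible(x)
}

MODEL_BUNDLE_VERSION <- 1L

#' Save a state model bundle
#'
#' Single-file JSON archive: format version, family, pair list, metadata,
#' and the estimator state serialized and base64-encoded so predictions
#' round-trip bitwise.
#'
#' @param model A `gpcr_state_model`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_state_model <- function(model, path) {
  bundle <- list(
    format = "gpcrstates-model",
    version = MODEL_BUNDLE_VERSION,
    family = model$family,
    pairs = model$pairs,
    pairlist = list(a = model$pairlist$a, b = model$pairlist$b,
                    name = attr(model$pairlist, "name")),
    metadata = model$metadata,
    fit = jsonlite::base64_enc(serialize(model$fit, NULL, version = 3L)))
  writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Load a state model bundle
#' @param path Path written by [save_state_model()].
#' @return A `gpcr_state_model`.
#' @export
load_state_model <- function(path) {
  bundle <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                               simplifyVector = TRUE)
  if (!identical(bundle$format, "gpcrstates-model"))
    gpcr_abort(sprintf("not a model bundle: %s", path), "gpcrstates_io_error")
  if (bundle$version > MODEL_BUNDLE_VERSION)
    gpcr_abort(sprintf("bundle version %d newer than supported %d",
                       bundle$version, MODEL_BUNDLE_VERSION),
               "gpcrstates_io_error")
  fit <- unserialize(jsonlite::base64_dec(bundle$fit))
  pl <- as_pairlist(data.frame(a = bundle$pairlist$a, b = bundle$pairlist$b,
                               stringsAsFactors = FALSE),
                    name = bundle$pairlist$name %||% "loaded")
  md <- bundle$metadata
  if (!is.null(md$cv_metrics)) md$cv_metrics <- as.data.frame(md$cv_metrics)
  base::structure(list(family = bundle$family, fit = fit,
                       pairs = bundle$pairs, pairlist = pl, metadata = md),
                  class = "gpcr_state_model")
}
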