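# Supervised classification and ranking of hotspots. Five model families
# (RBF-SVM, random forest, two gradient-boosted tree variants, AdaBoost),
# leave-one-out and repeated stratified k-fold evaluation, consensus models,
# probability-based per-protein ranking and top-N reports.
#
# Feature standardization is always fitted on training rows only and re-fitted
# inside every cross-validation fold, so no test information leaks into the
# scaling.

#' Specify a classification model
#'
#' @param algorithm one of `"adaboost"`, `"svm_rbf"`, `"random_forest"`,
#'   `"gradient_boosting_xgb_style"`, `"gradient_boosting_lgb_style"`.
#' @param hyperparams named list overriding algorithm defaults. AdaBoost
#'   defaults are the tuned operating point: max_depth 4, min_samples_leaf 2,
#'   min_samples_split 15, learning_rate 0.0112, n_estimators 190.
#' @param classification_threshold probability cutoff for the confusion
#'   metrics (default 0.5).
#' @param seed integer seed fixed into every stochastic fit.
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm = c("adaboost", "svm_rbf", "random_forest",
                                     "gradient_boosting_xgb_style",
                                     "gradient_boosting_lgb_style"),
                       hyperparams = list(), classification_threshold = 0.5,
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, hyperparams = hyperparams,
                 classification_threshold = classification_threshold,
                 seed = as.integer(seed)),
            class = "model_spec")
}

feature_columns <- function(ds) {
  setdiff(names(ds)[vapply(ds, is.numeric, TRUE)],
          c("label", "rank", "probability"))
}

label_vector <- function(ds) {
  lb <- ds$label
  if (is.numeric(lb)) return(as.integer(lb > 0))
  as.integer(as.character(lb) %in% c("1", "positive", "cryptic", "TRUE", "pos"))
}

#' Fit a feature standardizer on training rows
#'
#' Columns are centred and scaled to zero mean and unit (population) variance.
#' Zero-variance columns get scale 1 with a warning.
#'
#' @param X training feature matrix.
#' @return a `standardizer` with `center` and `scale`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  zero <- sc <= .Machine$double.eps
  if (any(zero)) {
    warning(sprintf("zero-variance column(s): %s; scale set to 1",
                    paste(colnames(X)[zero], collapse = ",")))
    sc[zero] <- 1
  }
  structure(list(center = ctr, scale = sc), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std a `standardizer` from [fit_standardizer()].
#' @param X matrix of rows to transform with the training statistics.
#' @return transformed matrix.
#' @export
apply_standardizer <- function(std, X) {
  X <- rbind(as.matrix(X))
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

default_hyperparams <- function(algorithm) {
  switch(algorithm,
    adaboost = list(n_estimators = 190L, learning_rate = 0.0112,
                    max_depth = 4L, min_samples_split = 15L,
                    min_samples_leaf = 2L),
    svm_rbf = list(cost = 1, gamma = NULL),
    random_forest = list(ntree = 500L, mtry = NULL),
    gradient_boosting_xgb_style = list(nrounds = 200L, eta = 0.1, max_depth = 4L,
                                       subsample = 1, colsample_bytree = 1),
    gradient_boosting_lgb_style = list(nrounds = 200L, eta = 0.1,
                                       max_leaves = 31L, min_child_weight = 1))
}

#' Train a classifier on a labelled feature table
#'
#' Standardization is fitted on the training rows and stored with the model.
#' All stochastic fits are seeded from the spec, so identical data and seed
#' give identical probabilities.
#'
#' @param ds data.frame with a `label` column (positive = cryptic) and
#'   numeric feature columns; `protein_id`/`hotspot_id` are carried along.
#' @param spec a [model_spec()].
#' @return A `cryptohot_model` with a [predict_prob()] method.
#' @export
train_model <- function(ds, spec = model_spec()) {
  fc <- feature_columns(ds)
  y <- label_vector(ds)
  if (length(unique(y)) < 2L)
    stop_cryptohot("training data must contain both classes",
                   "cryptohot_training_error")
  std <- withCallingHandlers(fit_standardizer(as.matrix(ds[, fc, drop = FALSE])),
                             warning = function(w) invokeRestart("muffleWarning"))
  X <- apply_standardizer(std, ds[, fc, drop = FALSE])
  hp <- utils::modifyList(default_hyperparams(spec$algorithm), spec$hyperparams)
  set.seed(spec$seed)
  fit <- switch(spec$algorithm,
    adaboost = adaboost_fit(X, y, n_estimators = hp$n_estimators,
                            learning_rate = hp$learning_rate,
                            max_depth = hp$max_depth,
                            min_samples_split = hp$min_samples_split,
                            min_samples_leaf = hp$min_samples_leaf),
    svm_rbf = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                         cost = hp$cost,
                         gamma = hp$gamma %||% (1 / ncol(X)),
                         probability = TRUE, scale = FALSE),
    random_forest = randomForest::randomForest(
      X, factor(y, levels = c(0, 1)), ntree = hp$ntree,
      mtry = hp$mtry %||% max(1L, floor(sqrt(ncol(X))))),
    gradient_boosting_xgb_style = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    max_depth = hp$max_depth, subsample = hp$subsample,
                    colsample_bytree = hp$colsample_bytree,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = hp$nrounds,
      verbose = 0),
    gradient_boosting_lgb_style = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    tree_method = "hist", grow_policy = "lossguide",
                    max_leaves = hp$max_leaves, max_depth = 0,
                    min_child_weight = hp$min_child_weight, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = hp$nrounds,
      verbose = 0))
  structure(list(spec = spec, fit = fit, standardizer = std,
                 feature_names = fc,
                 feature_hash = fnv1a_hash(paste(fc, collapse = ","))),
            class = "cryptohot_model")
}

#' Predict cryptic probabilities from a trained model
#'
#' @param model a `cryptohot_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_prob <- function(model, newdata) {
  X <- apply_standardizer(model$standardizer,
                          as.matrix(newdata[, model$feature_names, drop = FALSE]))
  alg <- model$spec$algorithm
  if (alg == "adaboost") return(predict(model$fit, X))
  if (alg == "svm_rbf") {
    pr <- attr(predict(model$fit, X, probability = TRUE), "probabilities")
    return(unname(pr[, "1"]))
  }
  if (alg == "random_forest")
    return(unname(predict(model$fit, X, type = "prob")[, "1"]))
  unname(predict(model$fit, xgboost::xgb.DMatrix(X)))
}

#' ROC AUC (trapezoidal / Mann-Whitney with tie correction)
#'
#' @param labels binary labels (1 = positive).
#' @param scores classifier scores; higher means more positive.
#' @return area under the ROC curve.
#' @export
roc_auc <- function(labels, scores) {
  y <- as.integer(labels > 0)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_cryptohot("ROC AUC undefined for single-class labels",
                   "cryptohot_metric_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC (step integration)
#'
#' Step-wise integration of precision over recall across all score
#' thresholds (equivalent to average precision), without interpolation.
#'
#' @inheritParams roc_auc
#' @return area under the precision-recall curve.
#' @export
pr_auc <- function(labels, scores) {
  y <- as.integer(labels > 0)
  if (!any(y == 1L) || !any(y == 0L))
    stop_cryptohot("PR AUC undefined for single-class labels",
                   "cryptohot_metric_error")
  ord <- order(-scores)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate only at the last index of each tied score block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / sum(y)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Confusion and ranking metrics at a probability threshold
#'
#' @param labels binary labels (1 = positive/cryptic).
#' @param probabilities classifier probabilities.
#' @param threshold classification cutoff (predicted positive iff
#'   probability >= threshold).
#' @return A `metrics_report` list: accuracy, precision, recall, f1,
#'   specificity, roc_auc, pr_auc, and the confusion counts.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  y <- as.integer(labels > 0)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(
    accuracy = (tp + tn) / length(y),
    precision = precision, recall = recall,
    f1 = if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    roc_auc = roc_auc(y, probabilities),
    pr_auc = pr_auc(y, probabilities),
    tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f\n",
                     "specificity %.3f  ROC AUC %.3f  PR AUC %.3f\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$specificity,
              x$roc_auc, x$pr_auc))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' n folds of size 1; standardization and the model are re-fitted on the
#' n-1 training rows of every fold, and metrics are computed on the pooled
#' out-of-fold probabilities.
#'
#' @param ds labelled feature table (see [train_model()]).
#' @param spec a [model_spec()].
#' @return list with `metrics` ([compute_metrics()] output) and
#'   `probabilities` (out-of-fold, in row order).
#' @export
loocv <- function(ds, spec = model_spec()) {
  n <- nrow(ds)
  if (n < 3L) stop_cryptohot("LOOCV needs n >= 3", "cryptohot_argument_error")
  probs <- numeric(n)
  for (i in seq_len(n)) {
    model <- train_model(ds[-i, , drop = FALSE], spec)
    probs[i] <- predict_prob(model, ds[i, , drop = FALSE])
  }
  list(metrics = compute_metrics(label_vector(ds), probs,
                                 spec$classification_threshold),
       probabilities = probs)
}

#' Repeated stratified k-fold cross-validation
#'
#' Random stratified splits repeated `reps` times; the ROC AUC of each
#' repetition is computed on that repetition's pooled out-of-fold
#' probabilities.
#'
#' @param ds labelled feature table.
#' @param spec a [model_spec()].
#' @param k folds (default 10).
#' @param reps repetitions.
#' @param seed split-generation seed.
#' @return list with `mean`, `sd` and the per-rep `aucs`.
#' @export
repeated_kfold <- function(ds, spec = model_spec(), k = 10L, reps = 10L,
                           seed = 1L) {
  n <- nrow(ds)
  if (k > n) stop_cryptohot("k exceeds number of rows", "cryptohot_argument_error")
  y <- label_vector(ds)
  set.seed(seed)
  aucs <- vapply(seq_len(reps), function(r) {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    probs <- numeric(n)
    for (f in seq_len(k)) {
      test <- fold == f
      model <- train_model(ds[!test, , drop = FALSE], spec)
      probs[test] <- predict_prob(model, ds[test, , drop = FALSE])
    }
    roc_auc(y, probs)
  }, 1)
  list(mean = mean(aucs), sd = stats::sd(aucs), aucs = aucs)
}

#' Hyperparameter search maximizing cross-validated ROC AUC
#'
#' Grid (exhaustive) or random search over a declared space; deterministic
#' under a fixed seed. The cross-validation scheme is LOOCV by default or
#' k-fold by argument.
#'
#' @param ds labelled feature table.
#' @param spec base [model_spec()].
#' @param space named list; each element a vector of candidate values.
#' @param budget maximum configurations to evaluate (random search).
#' @param method `"grid"` or `"random"`.
#' @param cv `"loocv"` or `"kfold"`.
#' @param k folds for `cv = "kfold"`.
#' @param seed search seed.
#' @return list with `best_hyperparams`, `best_auc`, and the search `trace`.
#' @export
tune_model <- function(ds, spec = model_spec(), space, budget = 20L,
                       method = c("grid", "random"), cv = c("loocv", "kfold"),
                       k = 5L, seed = 1L) {
  method <- match.arg(method); cv <- match.arg(cv)
  if (!length(space)) stop_cryptohot("empty search space", "cryptohot_argument_error")
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  if (method == "random") {
    set.seed(seed)
    grid <- grid[sample(nrow(grid), min(budget, nrow(grid))), , drop = FALSE]
  } else if (nrow(grid) > budget && method == "random") {
    grid <- grid[seq_len(budget), , drop = FALSE]
  }
  eval_one <- function(hp) {
    sp <- spec
    sp$hyperparams <- utils::modifyList(spec$hyperparams, as.list(hp))
    if (cv == "loocv") loocv(ds, sp)$metrics$roc_auc
    else {
      rk <- repeated_kfold(ds, sp, k = k, reps = 1L, seed = seed)
      rk$mean
    }
  }
  aucs <- vapply(seq_len(nrow(grid)), function(i) eval_one(grid[i, , drop = FALSE]), 1)
  best <- which.max(aucs)
  list(best_hyperparams = as.list(grid[best, , drop = FALSE]),
       best_auc = aucs[best],
       trace = cbind(grid, roc_auc = aucs))
}

#' Consensus of the five base models
#'
#' Out-of-fold (LOOCV) probabilities of each base model feed either a
#' logistic-regression stacking meta-learner or a simple average.
#'
#' @param ds labelled feature table.
#' @param specs list of [model_spec()]s (typically the five families).
#' @param mode `"stack_logistic"` or `"average"`.
#' @return list with pooled consensus `probabilities`, `metrics`, the base
#'   out-of-fold probability matrix, and (for stacking) the meta-model.
#' @export
consensus <- function(ds, specs, mode = c("stack_logistic", "average")) {
  mode <- match.arg(mode)
  base_probs <- vapply(specs, function(sp) loocv(ds, sp)$probabilities,
                       numeric(nrow(ds)))
  y <- label_vector(ds)
  if (mode == "average") {
    probs <- rowMeans(base_probs)
    meta <- NULL
  } else {
    dfm <- data.frame(y = y, base_probs)
    meta <- stats::glm(y ~ ., data = dfm, family = stats::binomial())
    probs <- unname(predict(meta, dfm, type = "response"))
  }
  list(probabilities = probs,
       metrics = compute_metrics(y, probs),
       base_probabilities = base_probs, meta_model = meta, mode = mode)
}

#' Rank hotspots per protein by predicted probability
#'
#' Descending probability; tied probabilities share the minimum rank; within
#' ties the row order is stabilized by hotspot id.
#'
#' @param df data.frame with `protein_id`, `hotspot_id`, `probability`.
#' @return the data.frame with a `rank` column, ordered per protein.
#' @export
rank_hotspots <- function(df) {
  stopifnot(all(c("protein_id", "hotspot_id", "probability") %in% names(df)))
  out <- do.call(rbind, lapply(split(df, df$protein_id), function(g) {
    g <- g[order(-g$probability, g$hotspot_id), , drop = FALSE]
    g$rank <- rank(-g$probability, ties.method = "min")
    g
  }))
  rownames(out) <- NULL
  out
}

#' Top-N ranking report
#'
#' For each protein, the best (minimum) rank over its cryptic hotspots is
#' compared with N; the report counts proteins whose best cryptic rank is
#' <= N and converts counts to percentages of `n_proteins`, rounded to
#' integer percent.
#'
#' @param rankings output of [rank_hotspots()].
#' @param labels binary cryptic labels aligned with `rankings` rows (or a
#'   `label` column already present in `rankings`).
#' @param Ns thresholds to report (default 1, 3, 5).
#' @param n_proteins denominator; defaults to the number of distinct
#'   proteins in `rankings`.
#' @return A `topn_report` data.frame with N, hits, percent.
#' @export
topn_report <- function(rankings, labels = NULL, Ns = c(1L, 3L, 5L),
                        n_proteins = NULL) {
  if (is.null(labels)) {
    stopifnot("label" %in% names(rankings))
    labels <- rankings$label
  }
  lab <- as.integer(if (is.numeric(labels)) labels > 0
                    else as.character(labels) %in% c("1", "positive", "cryptic", "TRUE"))
  rankings$.lab <- lab
  n_proteins <- n_proteins %||% length(unique(rankings$protein_id))
  empty <- tapply(rankings$.lab, rankings$protein_id, length) == 0
  best <- tapply(ifelse(rankings$.lab == 1L, rankings$rank, NA_integer_),
                 rankings$protein_id, function(r) {
                   if (all(is.na(r))) Inf else min(r, na.rm = TRUE)
                 })
  hits <- vapply(Ns, function(N) sum(best <= N), 1L)
  structure(data.frame(N = Ns, hits = hits, n_proteins = n_proteins,
                       percent = round(hits / n_proteins * 100)),
            class = c("topn_report", "data.frame"))
}

#' Save / load a trained model with a metadata sidecar
#'
#' The sidecar (JSON) records algorithm, hyperparameters, seed, and a hash of
#' the feature column names so prediction-time tables can be validated.
#'
#' @param model a `cryptohot_model`.
#' @param path file path stem; sidecar written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model_sidecar <- function(model, path) {
  sidecar <- list(algorithm = model$spec$algorithm,
                  hyperparams = model$spec$hyperparams,
                  seed = model$spec$seed,
                  feature_names = model$feature_names,
                  feature_hash = model$feature_hash)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Check a feature table against a model's sidecar hash
#'
#' @param model a `cryptohot_model`.
#' @param ds feature table intended for prediction.
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
check_feature_hash <- function(model, ds) {
  h <- fnv1a_hash(paste(intersect(model$feature_names, names(ds)), collapse = ","))
  if (!identical(h, model$feature_hash) ||
      !all(model$feature_names %in% names(ds)))
    stop_cryptohot("feature columns do not match the model sidecar",
                   "cryptohot_feature_hash_error")
  invisible(TRUE)
}
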