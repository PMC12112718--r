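# AdaBoost over rpart decision trees. The default algorithm is SAMME.R
# (real-valued stages built from leaf class probabilities); discrete SAMME
# (0/1 stage votes with stage weights) is available as an option.
#
# Base trees use the classical CART controls so the tuned operating point
# (max_depth = 4, min_samples_leaf = 2, min_samples_split = 15,
# learning_rate = 0.0112, n_estimators = 190) maps one-to-one onto
# rpart.control(maxdepth, minbucket, minsplit) with pruning disabled.

#' Fit an AdaBoost classifier with tree base learners
#'
#' SAMME.R (default): each stage contributes half the log-odds of its leaf
#' class probabilities, case weights are updated from the log-probability of
#' the true class, and `learning_rate` shrinks both the contribution and the
#' weight update. SAMME: stages vote 0/1 and carry weight
#' `learning_rate * log((1-err)/err)`.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y binary labels (0/1 or logical), 1 = positive class.
#' @param n_estimators boosting rounds (default 190).
#' @param learning_rate shrinkage (default 0.0112).
#' @param max_depth,min_samples_split,min_samples_leaf CART controls
#'   (defaults 4, 15, 2).
#' @param algorithm `"samme_r"` (default) or `"samme"`.
#' @param sample_weight optional initial case weights.
#' @return An `adaboost` model with per-stage compiled trees.
#' @export
adaboost_fit <- function(X, y, n_estimators = 190L, learning_rate = 0.0112,
                         max_depth = 4L, min_samples_split = 15L,
                         min_samples_leaf = 2L,
                         algorithm = c("samme_r", "samme"),
                         sample_weight = NULL) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop_cryptohot("AdaBoost needs both classes present", "cryptohot_training_error")
  n <- nrow(X)
  w <- sample_weight %||% rep(1 / n, n)
  w <- w / sum(w)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, minsplit = min_samples_split,
                               minbucket = min_samples_leaf, cp = 0, xval = 0,
                               maxsurrogate = 0, usesurrogate = 0, maxcompete = 0)
  df <- data.frame(y = factor(y, levels = c(0L, 1L)), X)
  compiled <- list(); alphas <- numeric(0)
  eps <- 1e-10
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w * n, method = "class",
                        control = ctrl)
    ct <- compile_rpart_tree(fit)
    # in-sample stage outputs straight from the fitted leaves
    leaf_row <- ct$lookup[as.integer(rownames(fit$frame))[fit$where]]
    pred <- ct$tab$yval[leaf_row]
    miss <- pred != y
    err <- sum(w[miss])
    if (algorithm == "samme") {
      if (err <= 0) {      # perfect stage: keep with a large finite weight
        compiled[[length(compiled) + 1L]] <- ct
        alphas <- c(alphas, learning_rate * log((1 - eps) / eps))
        break
      }
      if (err >= 0.5) {
        if (!length(compiled)) { compiled[[1L]] <- ct; alphas <- 1e-8 }
        break
      }
      alpha <- learning_rate * log((1 - err) / err)
      compiled[[length(compiled) + 1L]] <- ct
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * miss)
    } else {
      # SAMME.R: stage weight update from clipped leaf log-probabilities
      p1 <- pmin(pmax(ct$tab$prob1[leaf_row], eps), 1 - eps)
      half_logit <- 0.5 * (log(p1) - log1p(-p1))
      compiled[[length(compiled) + 1L]] <- ct
      alphas <- c(alphas, 1)
      if (err <= 0) break  # degenerate pure fit: further stages identical
      w <- w * exp(-learning_rate * ifelse(y == 1L, 1, -1) * half_logit)
    }
    w <- w / sum(w)
  }
  structure(list(compiled = compiled, alphas = alphas,
                 algorithm = algorithm,
                 feature_names = colnames(X),
                 params = list(n_estimators = n_estimators,
                               learning_rate = learning_rate,
                               max_depth = max_depth,
                               min_samples_split = min_samples_split,
                               min_samples_leaf = min_samples_leaf)),
            class = "adaboost")
}

# Flatten an rpart classification tree (no surrogates/competitors) into a
# node table indexed by binary-heap node number, for fast batch traversal.
compile_rpart_tree <- function(fit) {
  fr <- fit$frame
  node_id <- as.integer(rownames(fr))
  is_leaf <- fr$var == "<leaf>"
  # yval2 columns for 2-class "class" fits: yval, n1, n2, prob1, prob2, nodeprob
  prob1 <- fr$yval2[, 5]
  tab <- data.frame(node = node_id, leaf = is_leaf,
                    var = NA_integer_, thresh = NA_real_, dir = NA_real_,
                    yval = as.integer(fr$yval) - 1L, prob1 = prob1)
  if (any(!is_leaf)) {
    sp <- fit$splits
    # one primary split per internal node, in frame order
    internal <- which(!is_leaf)
    var_names <- attr(fit$terms, "term.labels")
    tab$var[internal] <- match(rownames(sp)[seq_along(internal)], var_names)
    tab$thresh[internal] <- sp[seq_along(internal), "index"]
    tab$dir[internal] <- sign(sp[seq_along(internal), "ncat"])
  }
  lookup <- integer(max(node_id))
  lookup[node_id] <- seq_along(node_id)
  list(tab = tab, lookup = lookup)
}

# Batch traversal: returns the leaf row index per row of X.
tree_leaf_rows <- function(ct, X) {
  tab <- ct$tab; lookup <- ct$lookup
  n <- nrow(X)
  node <- rep(1L, n)
  active <- !tab$leaf[lookup[node]]
  while (any(active)) {
    idx <- which(active)
    row <- lookup[node[idx]]
    v <- tab$var[row]; th <- tab$thresh[row]; dir <- tab$dir[row]
    xv <- X[cbind(idx, v)]
    # ncat < 0: go left when x < threshold; ncat > 0: left when x >= threshold
    go_left <- ifelse(dir < 0, xv < th, xv >= th)
    node[idx] <- 2L * node[idx] + ifelse(go_left, 0L, 1L)
    active[idx] <- !tab$leaf[lookup[node[idx]]]
  }
  lookup[node]
}

# Batch 0/1 class prediction for one compiled tree.
predict_compiled_tree <- function(ct, X) {
  ct$tab$yval[tree_leaf_rows(ct, X)]
}

#' Predict cryptic-class probabilities from an AdaBoost model
#'
#' The accumulated stage scores (log-odds contributions for SAMME.R, the
#' normalized weighted vote margin for SAMME) are mapped to (0, 1) through a
#' logistic link, preserving the ensemble's ranking.
#'
#' @param object an `adaboost` model.
#' @param X feature matrix.
#' @param ... unused.
#' @return probability of the positive class per row.
#' @export
predict.adaboost <- function(object, X, ...) {
  X <- as.matrix(X)
  colnames(X) <- object$feature_names
  eps <- 1e-10
  lr <- object$params$learning_rate
  score <- numeric(nrow(X))
  for (m in seq_along(object$compiled)) {
    ct <- object$compiled[[m]]
    rows <- tree_leaf_rows(ct, X)
    if (object$algorithm == "samme") {
      score <- score + object$alphas[m] *
        ifelse(ct$tab$yval[rows] == 1L, 1, -1)
    } else {
      p1 <- pmin(pmax(ct$tab$prob1[rows], eps), 1 - eps)
      score <- score + lr * 0.5 * (log(p1) - log1p(-p1))
    }
  }
  if (object$algorithm == "samme") {
    total <- sum(abs(object$alphas))
    if (total > 0) score <- score / total
  } else {
    score <- score / max(1, length(object$compiled) * lr)
  }
  1 / (1 + exp(-2 * score))
}
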