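#' Train a random forest on pair feature vectors
#'
#' Fits an ensemble of `n_trees` unpruned classification trees, each grown on
#' a bootstrap resample of the training pairs (sampling with replacement,
#' same size as the training set), choosing at every node the best Gini split
#' among a random subset of `mtry` features. Out-of-bag votes give an
#' internal accuracy estimate without a held-out set. Training is
#' deterministic given `seed`.
#'
#' @param data A tibble with an integer `label` column (0/1) and numeric
#'   feature columns (id columns `id_a`/`id_b`/`id` are ignored), as produced
#'   by [pair_features()].
#' @param n_trees Ensemble size N (default 60).
#' @param mtry Features considered per split, M (default 10).
#' @param seed Integer seed controlling bootstrap draws and feature sampling.
#' @return An object of class `mld_forest` wrapping the fitted ensemble, the
#'   configuration, the feature layout, and the out-of-bag accuracy.
#' @examples
#' \donttest{
#' sim <- simulate_ppi_data(n_positive = 20, n_negative = 20, seed = 1)
#' feats <- pair_features(sim$pairs, mld_featurize(sim$proteins))
#' fit <- mld_train(feats, n_trees = 10, seed = 1)
#' glance(fit)
#' }
#' @export
mld_train <- function(data, n_trees = 60L, mtry = 10L, seed = 1L) {
  stopifnot("label" %in% names(data))
  fcols <- feature_columns(data)
  x <- as.matrix(data[, fcols, drop = FALSE])
  y <- factor(as.integer(data$label), levels = c(0L, 1L))
  if (nrow(x) != length(y)) {
    abort("feature rows and labels differ in length", class = "mldppi_error_config")
  }
  if (length(unique(y[!is.na(y)])) < 2L) {
    abort("training data must contain both classes", class = "mldppi_error_validation")
  }
  if (mtry > ncol(x)) {
    abort(sprintf("mtry (%d) exceeds the feature dimension (%d)", mtry, ncol(x)),
          class = "mldppi_error_config")
  }
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(
    x = x, y = y,
    ntree = as.integer(n_trees),
    mtry = as.integer(mtry),
    nodesize = 1L  # grow unpruned trees to purity
  )
  structure(
    list(
      forest = forest,
      config = list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                    seed = as.integer(seed)),
      feature_names = fcols,
      layout_version = (attr(data, "mld_config") %||% list(layout_version = MLD_LAYOUT_VERSION))$layout_version,
      oob_accuracy = 1 - unname(forest$err.rate[n_trees, "OOB"])
    ),
    class = "mld_forest"
  )
}

#' @export
print.mld_forest <- function(x, ...) {
  cat(sprintf(
    "<mld_forest> N = %d trees, M = %d features/split, %d features, OOB accuracy %.3f\n",
    x$config$n_trees, x$config$mtry, length(x$feature_names), x$oob_accuracy
  ))
  invisible(x)
}

#' Predict interaction labels for new pairs
#'
#' The forest votes: the score is the fraction of trees predicting
#' "interacting", and the label is 1 when the score is at least 0.5 (an
#' exact tie is called positive — fixed, documented convention).
#'
#' @param object An `mld_forest`.
#' @param newdata A tibble (or matrix) containing the model's feature
#'   columns.
#' @param ... Unused.
#' @return A tibble with `.pred_score` (vote fraction in \[0, 1\]) and
#'   `.pred_label` (integer 0/1).
#' @export
predict.mld_forest <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$feature_names, names(newdata))
    if (length(missing) > 0L) {
      abort(sprintf("newdata lacks %d model feature(s), e.g. %s",
                    length(missing), missing[1]),
            class = "mldppi_error_config")
    }
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  if (ncol(newdata) != length(object$feature_names)) {
    abort("newdata feature dimension does not match the model",
          class = "mldppi_error_config")
  }
  votes <- predict(object$forest, newdata, type = "vote")[, "1"]
  tibble(
    .pred_score = unname(votes),
    .pred_label = as.integer(votes >= 0.5)
  )
}

#' @rdname mld_train
#' @param x An `mld_forest`.
#' @param ... Unused.
#' @export
glance.mld_forest <- function(x, ...) {
  tibble(
    n_trees = x$config$n_trees,
    mtry = x$config$mtry,
    seed = x$config$seed,
    n_features = length(x$feature_names),
    oob_accuracy = x$oob_accuracy
  )
}

#' @rdname mld_train
#' @export
tidy.mld_forest <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(
    feature = rownames(imp),
    gini_decrease = unname(imp[, "MeanDecreaseGini"])
  ) |>
    dplyr::arrange(dplyr::desc(.data$gini_decrease))
}

# One bootstrap resample: n draws with replacement from 1..n. Exposed
# internally so the in-bag fraction contract (about 63.2% unique) is testable
# against the exact sampler the reference tree uses.
bootstrap_indices <- function(n) {
  sample.int(n, n, replace = TRUE)
}

# ---- from-scratch Gini reference tree ------------------------------------
# A minimal unpruned CART used to pin down the tree-growing contract
# (binary Gini splits, grow to purity, majority leaves). It is the
# cross-check for the delegated ensemble, not the production path.

gini_impurity <- function(n1, n) {
  p <- n1 / n
  2 * p * (1 - p)
}

# Best threshold for one feature: O(n log n) scan over sorted values.
best_split_feature <- function(xj, y) {
  ord <- order(xj)
  xs <- xj[ord]
  ys <- y[ord]
  n <- length(ys)
  cum1 <- cumsum(ys)
  total1 <- cum1[n]
  cut_ok <- which(diff(xs) > 0)
  if (length(cut_ok) == 0L) {
    return(NULL)
  }
  nl <- cut_ok
  nr <- n - nl
  imp <- nl / n * gini_impurity(cum1[cut_ok], nl) +
    nr / n * gini_impurity(total1 - cum1[cut_ok], nr)
  best <- which.min(imp)
  list(
    threshold = (xs[cut_ok[best]] + xs[cut_ok[best] + 1L]) / 2,
    impurity = imp[best]
  )
}

grow_gini_tree <- function(x, y, mtry) {
  n <- length(y)
  n1 <- sum(y)
  node_imp <- gini_impurity(n1, n)
  majority <- as.integer(n1 * 2 >= n)
  if (n < 2L || n1 == 0L || n1 == n) {
    return(list(leaf = TRUE, pred = majority))
  }
  cand <- if (is.null(mtry) || mtry >= ncol(x)) {
    seq_len(ncol(x))
  } else {
    sample.int(ncol(x), mtry)
  }
  best <- NULL
  for (j in cand) {
    s <- best_split_feature(x[, j], y)
    if (!is.null(s) && (is.null(best) || s$impurity < best$impurity)) {
      best <- c(s, feature = j)
    }
  }
  if (is.null(best) || best$impurity >= node_imp - 1e-12) {
    return(list(leaf = TRUE, pred = majority))
  }
  left <- x[, best$feature] <= best$threshold
  list(
    leaf = FALSE, feature = best$feature, threshold = best$threshold,
    left = grow_gini_tree(x[left, , drop = FALSE], y[left], mtry),
    right = grow_gini_tree(x[!left, , drop = FALSE], y[!left], mtry)
  )
}

#' Reference unpruned Gini decision tree
#'
#' A compact from-scratch CART: binary splits chosen by maximum Gini-impurity
#' decrease (over all features, or a random subset of `mtry` per node), grown
#' until nodes are pure or indivisible, majority-class leaves. It documents
#' and tests the tree-growing contract the forest relies on; the forest
#' itself uses the compiled ensemble implementation.
#'
#' @param data A tibble with a `label` column and numeric feature columns, or
#'   a numeric matrix `x` with `labels` given separately.
#' @param labels Optional binary label vector when `data` is a matrix.
#' @param mtry Features sampled per node; `NULL` (default) scans all.
#' @return An object of class `mld_gini_tree`.
#' @export
gini_tree <- function(data, labels = NULL, mtry = NULL) {
  if (is.data.frame(data)) {
    labels <- as.integer(data$label)
    data <- as.matrix(data[, feature_columns(data), drop = FALSE])
  }
  structure(
    list(root = grow_gini_tree(data, as.integer(labels), mtry),
         n_features = ncol(data), feature_names = colnames(data)),
    class = "mld_gini_tree"
  )
}

#' @export
predict.mld_gini_tree <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  descend <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[node$feature] <= node$threshold) node$left else node$right
    }
    node$pred
  }
  as.integer(apply(newdata, 1L, function(r) descend(object$root, r)))
}

# Single unpruned CART via rpart (cp = 0, split to purity): the fast
# single-classifier baseline used by cross-validation and the ensemble
# comparisons.
fit_single_tree <- function(data) {
  fcols <- feature_columns(data)
  df <- data.frame(label = factor(as.integer(data$label), levels = c(0L, 1L)),
                   as.data.frame(data[, fcols, drop = FALSE]))
  rpart::rpart(
    label ~ ., data = df, method = "class",
    control = rpart::rpart.control(cp = 0, minsplit = 2L, minbucket = 1L, xval = 0L)
  )
}

predict_single_tree <- function(tree, data) {
  fcols <- setdiff(names(data), c("id_a", "id_b", "id", "label"))
  p <- predict(tree, as.data.frame(data[, fcols, drop = FALSE]), type = "prob")[, "1"]
  tibble(.pred_score = unname(p), .pred_label = as.integer(p >= 0.5))
}
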