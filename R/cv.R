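# Stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin into k folds, so every fold carries both classes and
# class proportions as evenly as the counts allow.
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  if (k < 2L) {
    abort("k must be at least 2", class = "mldppi_error_config")
  }
  if (min(table(factor(labels, levels = c(0L, 1L)))) < k) {
    abort(sprintf("k = %d exceeds the size of the smaller class", k),
          class = "mldppi_error_config")
  }
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the pair classifier
#'
#' Splits the labelled pairs into `k` stratified folds (seeded, so the
#' partition is reproducible), trains on k-1 folds and evaluates on the held
#' out fold, and reports the confusion counts plus the seven standard
#' metrics per fold and their mean and standard deviation across folds.
#' Metrics are computed per fold and then averaged (matching the usual
#' mean +/- sd presentation), not pooled.
#'
#' @param data Pair feature tibble with a `label` column (see
#'   [pair_features()]).
#' @param k Number of folds (default 5).
#' @param n_trees,mtry Forest hyperparameters (defaults N = 60, M = 10).
#' @param seed Seed controlling the fold partition and each fold's forest.
#' @param classifier `"forest"` (default) or `"tree"` for a single unpruned
#'   decision tree, the component-classifier baseline.
#' @return An object of class `mld_cv`: a list with `folds` (per-fold tibble:
#'   fold, confusion counts, the seven metrics), `summary` (mean and sd per
#'   metric), and the run configuration.
#' @examples
#' \donttest{
#' sim <- simulate_ppi_data(n_positive = 30, n_negative = 30, seed = 1)
#' feats <- pair_features(sim$pairs, mld_featurize(sim$proteins))
#' cv <- mld_cross_validate(feats, k = 3, n_trees = 20, seed = 1)
#' glance(cv)
#' }
#' @export
mld_cross_validate <- function(data, k = 5L, n_trees = 60L, mtry = 10L,
                               seed = 1L, classifier = c("forest", "tree")) {
  classifier <- match.arg(classifier)
  fold <- stratified_folds(data$label, k, seed)
  fold_rows <- purrr::map(seq_len(k), function(i) {
    train <- data[fold != i, , drop = FALSE]
    test <- data[fold == i, , drop = FALSE]
    pred <- if (classifier == "forest") {
      fit <- mld_train(train, n_trees = n_trees, mtry = mtry, seed = seed + i)
      predict(fit, test)
    } else {
      set.seed(as.integer(seed) + i)
      predict_single_tree(fit_single_tree(train), test)
    }
    cc <- confusion_counts(test$label, pred$.pred_label)
    dplyr::bind_cols(tibble(fold = i), cc, metrics_wide(classification_metrics(cc)))
  })
  folds <- dplyr::bind_rows(fold_rows)
  metric_names <- c("acc", "sn", "spec", "ppv", "npv", "f_score", "mcc")
  summary <- folds |>
    tidyr::pivot_longer(dplyr::all_of(metric_names),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(metric = factor(.data$metric, levels = metric_names)) |>
    dplyr::arrange(.data$metric) |>
    dplyr::mutate(metric = as.character(.data$metric))
  structure(
    list(
      folds = folds,
      summary = summary,
      config = list(k = as.integer(k), n_trees = as.integer(n_trees),
                    mtry = as.integer(mtry), seed = as.integer(seed),
                    classifier = classifier, n_pairs = nrow(data))
    ),
    class = "mld_cv"
  )
}

#' @export
print.mld_cv <- function(x, ...) {
  cat(sprintf("<mld_cv> %d-fold CV, %s (N = %d, M = %d), %d pairs\n",
              x$config$k, x$config$classifier, x$config$n_trees,
              x$config$mtry, x$config$n_pairs))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-7s %6.2f%% +/- %.2f\n", s$metric[i], 100 * s$mean[i], 100 * s$sd[i]))
  }
  invisible(x)
}

#' @rdname mld_cross_validate
#' @param x An `mld_cv` object.
#' @param ... Unused.
#' @export
tidy.mld_cv <- function(x, ...) {
  x$folds
}

#' @rdname mld_cross_validate
#' @export
glance.mld_cv <- function(x, ...) {
  wide <- setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(
    tibble(k = x$config$k, n_trees = x$config$n_trees, mtry = x$config$mtry,
           classifier = x$config$classifier),
    as_tibble(wide)
  )
}

#' Cross-validated report table formatted as percentages
#'
#' Per-fold confusion counts followed by the seven metrics as percentages
#' rounded to 2 decimals — the conventional presentation of PPI benchmark
#' tables.
#'
#' @param cv An `mld_cv` object.
#' @return A tibble with character metric columns like `"94.72"`.
#' @export
cv_report <- function(cv) {
  metric_names <- c("acc", "sn", "spec", "ppv", "npv", "f_score", "mcc")
  cv$folds |>
    dplyr::mutate(dplyr::across(dplyr::all_of(metric_names),
                                ~ sprintf("%.2f", 100 * .x)))
}

#' Hyperparameter sweep over feature-subset size and ensemble size
#'
#' Runs [mld_cross_validate()] for every combination of `m_values` (features
#' per split) and `n_values` (trees) and collects the aggregate metrics, the
#' standard sensitivity analysis for the two forest hyperparameters.
#'
#' @param data Pair feature tibble with a `label` column.
#' @param m_values Integer vector of feature-subset sizes M.
#' @param n_values Integer vector of ensemble sizes N.
#' @param k Folds per run (default 5).
#' @param seed Seed shared across runs so every (M, N) sees the same folds.
#' @param n_repeats Independent seeded cross-validation repetitions averaged
#'   per (M, N) (default 1). Use more than one when the effect under study
#'   (e.g. the M-sensitivity band) is smaller than single-run fold noise;
#'   repetition r uses seed `seed + r - 1`, identical across the grid.
#' @return A tibble of class `mld_sweep`: one row per (M, N) with the mean of
#'   each metric over all `k * n_repeats` folds and the between-fold sd.
#' @export
mld_sweep <- function(data, m_values = c(5L, 10L, 15L, 20L, 25L, 30L),
                      n_values = 60L, k = 5L, seed = 1L, n_repeats = 1L) {
  grid <- tidyr::expand_grid(mtry = as.integer(m_values),
                             n_trees = as.integer(n_values))
  rows <- purrr::pmap(grid, function(mtry, n_trees) {
    folds <- dplyr::bind_rows(purrr::map(seq_len(n_repeats), function(r) {
      mld_cross_validate(data, k = k, n_trees = n_trees, mtry = mtry,
                         seed = seed + r - 1L)$folds
    }))
    metric_names <- c("acc", "sn", "spec", "ppv", "npv", "f_score", "mcc")
    wide_mean <- setNames(as.list(colMeans(folds[metric_names])), metric_names)
    wide_sd <- setNames(purrr::map(folds[metric_names], sd),
                        paste0(metric_names, "_sd"))
    dplyr::bind_cols(tibble(mtry = mtry, n_trees = n_trees),
                     as_tibble(wide_mean), as_tibble(wide_sd))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mld_sweep", class(out))
  out
}
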