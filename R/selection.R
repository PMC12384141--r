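#' Rank features by cross-validated mean decrease in impurity
#'
#' Stage one of the two-stage selector: a random forest is fitted on the
#' training portion of each of `n_folds` stratified folds, its impurity
#' importances are normalized to sum to 1 (per forest), and the per-fold
#' scores are averaged and sorted in decreasing order.
#'
#' @param feature_table Data frame of numeric features (one row per lesion).
#' @param labels 0/1 outcome vector.
#' @param n_folds Number of stratified CV folds.
#' @param seed Integer seed (forest fits and fold assignment).
#' @param num_trees Trees per forest.
#' @return A tibble of class `mdi_ranking` with columns `feature`, `mdi`,
#'   sorted non-increasing; attribute `n_folds`.
#' @export
rank_by_mdi <- function(feature_table, labels, n_folds = 5, seed = 1L,
                        num_trees = 500) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) abort("labels contain a single class")
  if (anyNA(feature_table)) abort("feature table contains missing values")
  feature_table <- as.data.frame(feature_table)
  n_folds <- cap_cv_folds(labels, n_folds)
  set.seed(as.integer(seed))
  fold <- stratified_folds(labels, n_folds)
  imp <- matrix(0, nrow = ncol(feature_table), ncol = n_folds,
                dimnames = list(colnames(feature_table), NULL))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- ranger::ranger(
      x = feature_table[tr, , drop = FALSE],
      y = factor(labels[tr], levels = c(0, 1)),
      num.trees = num_trees, importance = "impurity",
      seed = child_seed(seed, paste0("mdi", f)), num.threads = 1
    )
    v <- fit$variable.importance
    tot <- sum(v)
    imp[names(v), f] <- if (tot > 0) v / tot else v
  }
  score <- rowMeans(imp)
  ord <- order(-score, names(score))
  out <- tibble::tibble(feature = names(score)[ord], mdi = unname(score[ord]))
  attr(out, "n_folds") <- n_folds
  class(out) <- c("mdi_ranking", class(out))
  out
}

# out-of-fold random-forest probabilities under stratified CV
oof_rf_probs <- function(x, y, n_folds, seed, num_trees = 500) {
  n_folds <- cap_cv_folds(y, n_folds)
  set.seed(as.integer(seed))
  fold <- stratified_folds(y, n_folds)
  prob <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- ranger::ranger(
      x = x[tr, , drop = FALSE], y = factor(y[tr], levels = c(0, 1)),
      num.trees = num_trees, probability = TRUE,
      seed = child_seed(seed, paste0("oof", f)), num.threads = 1
    )
    prob[!tr] <- predict(fit, x[!tr, , drop = FALSE])$predictions[, "1"]
  }
  prob
}

#' Stage-two incremental AUC feature selection
#'
#' Features are added in ranking order; for each prefix size a random
#' forest is evaluated by stratified cross-validation (AUC computed on
#' out-of-fold predictions only) and the prefix with the highest mean AUC
#' is selected, smallest size winning ties.
#'
#' @param ranking An `mdi_ranking` from [rank_by_mdi()].
#' @param feature_table The same feature table the ranking was computed on.
#' @param labels 0/1 outcome vector.
#' @param n_folds CV folds.
#' @param seed Integer seed.
#' @param scan_range Optional `c(min, max)` prefix sizes to scan; defaults
#'   to 1 through the number of features.
#' @param num_trees Trees per forest.
#' @return A list of class `selected_features`: `names` (the chosen
#'   prefix), `chosen_size`, `auc_curve` tibble (`subset_size`, `mean_auc`).
#' @export
incremental_auc_selection <- function(ranking, feature_table, labels,
                                      n_folds = 5, seed = 1L,
                                      scan_range = NULL, num_trees = 500) {
  if (nrow(ranking) == 0) abort("empty ranking")
  labels <- as.integer(labels)
  feature_table <- as.data.frame(feature_table)
  sizes <- if (is.null(scan_range)) seq_len(nrow(ranking)) else {
    seq(max(1, scan_range[1]), min(nrow(ranking), scan_range[2]))
  }
  aucs <- purrr::map_dbl(sizes, function(k) {
    feats <- ranking$feature[seq_len(k)]
    prob <- oof_rf_probs(feature_table[, feats, drop = FALSE], labels,
                         n_folds, child_seed(seed, paste0("sel", k)),
                         num_trees = num_trees)
    auc_score(prob, labels)
  })
  best <- sizes[which.max(aucs)]  # which.max returns the first (smallest) tie
  structure(list(
    names = ranking$feature[seq_len(best)],
    chosen_size = best,
    auc_curve = tibble::tibble(subset_size = sizes, mean_auc = aucs)
  ), class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("<selected_features> %d features (best mean AUC %.3f)\n",
              x$chosen_size, max(x$auc_curve$mean_auc)))
  cat(" ", paste(head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Two-stage selection for one region
#'
#' Convenience wrapper running [rank_by_mdi()] then
#' [incremental_auc_selection()] on the columns of one region prefix.
#'
#' @param features Wide feature tibble from [extract_cohort_features()].
#' @param labels 0/1 outcome vector aligned to rows.
#' @param region `"tumoral"` or `"peritumoral"`.
#' @param ... Passed to the two stages (`n_folds`, `seed`, `scan_range`).
#' @return A `selected_features` object.
#' @export
select_region_features <- function(features, labels,
                                   region = c("tumoral", "peritumoral"), ...) {
  region <- match.arg(region)
  prefix <- if (region == "tumoral") "tum_" else "peri_"
  cols <- grep(paste0("^", prefix), colnames(features), value = TRUE)
  tab <- features[, cols, drop = FALSE]
  args <- list(...)
  rk <- rank_by_mdi(tab, labels,
                    n_folds = args$n_folds %||% 5, seed = args$seed %||% 1L,
                    num_trees = args$num_trees %||% 500)
  incremental_auc_selection(rk, tab, labels,
                            n_folds = args$n_folds %||% 5,
                            seed = args$seed %||% 1L,
                            scan_range = args$scan_range,
                            num_trees = args$num_trees %||% 500)
}
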