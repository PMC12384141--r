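#' Patient-level stratified k-fold split
#'
#' Patients (not lesions) are assigned to folds so that every lesion of a
#' patient shares a fold -- the strict choice that prevents leakage between
#' lesions of one patient. Within each class, patients are shuffled and
#' distributed as evenly as possible (fold sizes differ by at most one per
#' class, larger folds first).
#'
#' @param patients Tibble with columns `patient_id` and `outcome` (0/1),
#'   one row per patient.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return A tibble (`patient_id`, `outcome`, `fold`) of class `split_plan`.
#' @export
stratified_kfold_split <- function(patients, n_folds = 4, seed = 1L) {
  stopifnot(all(c("patient_id", "outcome") %in% colnames(patients)))
  if (anyDuplicated(patients$patient_id)) abort("patients must be unique")
  set.seed(as.integer(seed))
  fold <- stratified_folds(patients$outcome, n_folds)
  out <- tibble::tibble(patient_id = patients$patient_id,
                        outcome = as.integer(patients$outcome),
                        fold = fold)
  class(out) <- c("split_plan", class(out))
  out
}

# probability random forest wrapper
rf_prob_fit <- function(x, y, seed, num_trees = 500) {
  fit <- ranger::ranger(
    x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
    num.trees = num_trees, probability = TRUE,
    seed = as.integer(seed), num.threads = 1
  )
  structure(list(fit = fit, features = colnames(x)), class = "radstack_rf")
}

#' @export
predict.radstack_rf <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$features, drop = FALSE]
  predict(object$fit, newdata)$predictions[, "1"]
}

#' Region-feature classifier with strictly out-of-fold training probabilities
#'
#' Fits a probability random forest on the selected region features.
#' Training-cohort probabilities are produced by `cv_folds`-fold stratified
#' cross-validation, so no lesion is ever scored by a model that saw it;
#' test-cohort probabilities come from a refit on the full training cohort.
#'
#' @param train_features,test_features Data frames restricted to the
#'   selected feature set (test may be `NULL`).
#' @param train_labels 0/1 outcome per training lesion.
#' @param cv_folds CV folds for the out-of-fold probabilities.
#' @param seed Integer seed.
#' @param num_trees Trees per forest.
#' @return A list of class `region_classifier`: `train_prob` (out-of-fold),
#'   `test_prob` (or `NULL`), and `model`.
#' @export
fit_region_classifier <- function(train_features, train_labels,
                                  test_features = NULL, cv_folds = 3,
                                  seed = 1L, num_trees = 500) {
  train_labels <- as.integer(train_labels)
  train_features <- as.data.frame(train_features)
  train_prob <- oof_rf_probs(train_features, train_labels, cv_folds,
                             child_seed(seed, "regioncv"), num_trees = num_trees)
  model <- rf_prob_fit(train_features, train_labels,
                       child_seed(seed, "regionfit"), num_trees = num_trees)
  test_prob <- if (!is.null(test_features)) predict(model, test_features) else NULL
  structure(list(train_prob = train_prob, test_prob = test_prob, model = model),
            class = "region_classifier")
}

#' Encode clinical records as a numeric model matrix
#'
#' Smoking is encoded ordinally (never = 0, former = 1, current = 2),
#' monotone with exposure.
#'
#' @param clinical Data frame with `pdl1_score`, `tmb`, `smoking`, `age`.
#' @return Numeric data frame with columns `pdl1_score`, `tmb`,
#'   `smoking_ord`, `age`.
#' @export
encode_clinical <- function(clinical) {
  need <- c("pdl1_score", "tmb", "smoking", "age")
  miss <- setdiff(need, colnames(clinical))
  if (length(miss)) abort(paste("missing clinical fields:", paste(miss, collapse = ", ")))
  smoking_ord <- c(never = 0, former = 1, current = 2)[as.character(clinical$smoking)]
  if (anyNA(smoking_ord)) abort("smoking must be one of never/former/current")
  data.frame(pdl1_score = clinical$pdl1_score, tmb = clinical$tmb,
             smoking_ord = unname(smoking_ord), age = clinical$age)
}

#' Decoupled probability-stacking classifier
#'
#' Stacks the out-of-fold region probabilities (pT, ppT -- or a single
#' pT_all) with the clinical variables PD-L1 score, TMB, smoking status and
#' age into one random forest. The probability features must be strictly
#' out-of-fold on the training cohort to avoid leakage.
#'
#' @param clinical Training clinical data frame.
#' @param probs Data frame of probability features (e.g. columns `pT`,
#'   `ppT`, or `pT_all`).
#' @param labels 0/1 outcome per training lesion.
#' @param seed Integer seed.
#' @param num_trees Trees per forest.
#' @return A `stacked_classifier` object with a `predict(clinical, probs)`
#'   interface via [predict.stacked_classifier()].
#' @export
fit_stacked_classifier <- function(clinical, probs, labels, seed = 1L,
                                   num_trees = 500) {
  x <- cbind(encode_clinical(clinical), as.data.frame(probs))
  model <- rf_prob_fit(x, as.integer(labels), child_seed(seed, "stack"),
                       num_trees = num_trees)
  structure(list(model = model, prob_cols = colnames(as.data.frame(probs))),
            class = "stacked_classifier")
}

#' @export
predict.stacked_classifier <- function(object, clinical, probs, ...) {
  x <- cbind(encode_clinical(clinical), as.data.frame(probs))
  predict(object$model, x)
}

#' Direct clinical + raw-feature classifier
#'
#' Comparison arm combining the clinical variables with the selected raw
#' tumoral and peritumoral feature columns (no probability stacking).
#'
#' @param clinical Training clinical data frame.
#' @param region_features Data frame of the selected raw feature columns.
#' @param labels 0/1 outcome.
#' @param seed Integer seed.
#' @param num_trees Trees per forest.
#' @return A `stacked_classifier`-shaped object (same predict interface).
#' @export
fit_direct_feature_classifier <- function(clinical, region_features, labels,
                                          seed = 1L, num_trees = 500) {
  x <- cbind(encode_clinical(clinical), as.data.frame(region_features))
  model <- rf_prob_fit(x, as.integer(labels), child_seed(seed, "direct"),
                       num_trees = num_trees)
  structure(list(model = model,
                 prob_cols = colnames(as.data.frame(region_features))),
            class = "stacked_classifier")
}

#' Aggregate instance probabilities to subject level
#'
#' @param probs Tibble with columns `patient_id` and `prob`.
#' @param rule `"mean"` (default) or `"max"`.
#' @return Tibble (`patient_id`, `prob`), one row per patient.
#' @export
aggregate_subjectwise <- function(probs, rule = c("mean", "max")) {
  rule <- match.arg(rule)
  f <- if (rule == "mean") mean else max
  probs |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(prob = f(.data$prob), .groups = "drop")
}

#' Classification metrics: AUC, accuracy, recall
#'
#' AUC is the rank statistic (Mann-Whitney, ties counted 1/2); accuracy and
#' recall are computed at the probability threshold.
#'
#' @param prob Predicted probabilities in [0, 1].
#' @param labels 0/1 outcomes (both classes must be present).
#' @param threshold Classification threshold for accuracy/recall.
#' @param method,level Optional labels recorded in the output.
#' @return A one-row tibble: `method`, `level`, `auc`, `accuracy`, `recall`,
#'   `n`.
#' @export
evaluate <- function(prob, labels, threshold = 0.5,
                     method = "model", level = "instance") {
  labels <- as.integer(labels)
  auc <- auc_score(prob, labels)
  pred <- as.integer(prob >= threshold)
  tibble::tibble(
    method = method, level = level, auc = auc,
    accuracy = mean(pred == labels),
    recall = mean(pred[labels == 1L] == 1L),
    n = length(labels)
  )
}

#' Train and evaluate the full response-model matrix
#'
#' Runs the model matrix on a feature table split into training and test
#' cohorts by a patient-level plan: region forests on the selected tumoral
#' (fT) and peritumoral (fpT) features producing pT / ppT / pT_all
#' (out-of-fold on training, refit for test), the clinical-only forest,
#' the stacked forests (Clin-pT-ppT and Clin-pT_all), the direct
#' Clin-fT-fpT forest, and subject-wise aggregation of the stacked model.
#'
#' @param features Wide feature tibble from [extract_cohort_features()]
#'   joined with clinical columns (`pdl1_score`, `tmb`, `smoking`, `age`).
#' @param test_patients Character vector of patient ids forming the test
#'   cohort; the remainder trains.
#' @param tumoral_features,peritumoral_features Character vectors of
#'   selected feature column names.
#' @param cv_folds Folds for out-of-fold training probabilities.
#' @param seed Integer seed.
#' @param threshold Classification threshold.
#' @param aggregation Subject-wise rule, `"mean"` or `"max"`.
#' @param num_trees Trees per forest.
#' @return A list of class `response_matrix`: `metrics` (Table-style
#'   tibble), `predictions` (per lesion and method), and the fitted models.
#' @export
run_response_matrix <- function(features, test_patients,
                                tumoral_features, peritumoral_features,
                                cv_folds = 3, seed = 1L, threshold = 0.5,
                                aggregation = "mean", num_trees = 500) {
  is_test <- features$patient_id %in% test_patients
  tr <- features[!is_test, , drop = FALSE]
  te <- features[is_test, , drop = FALSE]
  y_tr <- as.integer(tr$outcome)
  y_te <- as.integer(te$outcome)
  clin_tr <- tr[, c("pdl1_score", "tmb", "smoking", "age")]
  clin_te <- te[, c("pdl1_score", "tmb", "smoking", "age")]

  arms <- list(
    fT = tumoral_features,
    fpT = peritumoral_features,
    fT_fpT = c(tumoral_features, peritumoral_features)
  )
  region_fits <- purrr::imap(arms, function(cols, nm) {
    fit_region_classifier(tr[, cols, drop = FALSE], y_tr,
                          te[, cols, drop = FALSE], cv_folds = cv_folds,
                          seed = child_seed(seed, nm), num_trees = num_trees)
  })
  pT_tr <- region_fits$fT$train_prob;     pT_te <- region_fits$fT$test_prob
  ppT_tr <- region_fits$fpT$train_prob;   ppT_te <- region_fits$fpT$test_prob
  pTall_tr <- region_fits$fT_fpT$train_prob
  pTall_te <- region_fits$fT_fpT$test_prob

  clin_only <- rf_prob_fit(encode_clinical(clin_tr), y_tr,
                           child_seed(seed, "clin"), num_trees = num_trees)
  stacked <- fit_stacked_classifier(clin_tr, data.frame(pT = pT_tr, ppT = ppT_tr),
                                    y_tr, seed = seed, num_trees = num_trees)
  stacked_all <- fit_stacked_classifier(clin_tr, data.frame(pT_all = pTall_tr),
                                        y_tr, seed = child_seed(seed, "all"),
                                        num_trees = num_trees)
  direct <- fit_direct_feature_classifier(
    clin_tr, tr[, c(tumoral_features, peritumoral_features), drop = FALSE],
    y_tr, seed = seed, num_trees = num_trees)

  preds <- list(
    `RF-fT` = pT_te,
    `RF-fpT` = ppT_te,
    `RF-fT-fpT` = pTall_te,
    `RF-Clin` = predict(clin_only, encode_clinical(clin_te)),
    `RF-Clin-pT_all` = predict(stacked_all, clin_te,
                               data.frame(pT_all = pTall_te)),
    `RF-Clin-pT-ppT` = predict(stacked, clin_te,
                               data.frame(pT = pT_te, ppT = ppT_te)),
    `RF-Clin-fT-fpT` = predict(
      direct, clin_te,
      te[, c(tumoral_features, peritumoral_features), drop = FALSE])
  )

  metrics <- dplyr::bind_rows(
    evaluate(pT_tr, y_tr, threshold, "RF-train-val-fT", "instance"),
    evaluate(ppT_tr, y_tr, threshold, "RF-train-val-fpT", "instance"),
    evaluate(pTall_tr, y_tr, threshold, "RF-train-val-fT-fpT", "instance"),
    purrr::imap(preds, function(p, nm) evaluate(p, y_te, threshold, nm, "instance")) |>
      dplyr::bind_rows()
  )

  sub <- aggregate_subjectwise(
    tibble::tibble(patient_id = te$patient_id, prob = preds$`RF-Clin-pT-ppT`),
    rule = aggregation)
  sub_labels <- te |>
    dplyr::distinct(.data$patient_id, .data$outcome) |>
    dplyr::arrange(.data$patient_id)
  sub <- dplyr::left_join(sub, sub_labels, by = "patient_id")
  metrics <- dplyr::bind_rows(
    metrics,
    evaluate(sub$prob, sub$outcome, threshold, "RF-Clin-pT-ppT-Sub", "subject"))

  predictions <- dplyr::bind_rows(purrr::imap(preds, function(p, nm) {
    tibble::tibble(lesion_id = te$lesion_id, patient_id = te$patient_id,
                   method = nm, probability = p, label = y_te)
  }))

  structure(list(
    metrics = metrics, predictions = predictions,
    train_probs = tibble::tibble(lesion_id = tr$lesion_id,
                                 patient_id = tr$patient_id,
                                 pT = pT_tr, ppT = ppT_tr, pT_all = pTall_tr,
                                 outcome = y_tr),
    test_probs = tibble::tibble(lesion_id = te$lesion_id,
                                patient_id = te$patient_id,
                                pT = pT_te, ppT = ppT_te, pT_all = pTall_te,
                                outcome = y_te),
    subject_probs = sub,
    models = list(stacked = stacked, stacked_all = stacked_all,
                  clinical = clin_only, direct = direct)
  ), class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix>\n")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.response_matrix <- function(x, ...) x$metrics

#' @export
glance.response_matrix <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$auc), ]
  tibble::tibble(n_methods = nrow(x$metrics),
                 best_method = best$method, best_auc = best$auc)
}

#' Broom-style tidiers
#'
#' @param x Object to tidy.
#' @param ... Unused.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
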