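test_that("stratified 4-fold split reproduces the cohort arithmetic", {
  patients <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:187),
    outcome = rep(c(1L, 0L), times = c(51, 136)))
  plan <- stratified_kfold_split(patients, n_folds = 4, seed = 42)
  tab <- table(plan$fold, plan$outcome)
  # responders 51 -> 13/13/13/12; non-responders 136 -> 34 each
  expect_equal(sort(as.numeric(tab[, "1"]), decreasing = TRUE), c(13, 13, 13, 12))
  expect_true(all(tab[, "0"] == 34))
  # the first fold is a 47-patient test cohort with 13 responders,
  # leaving a 140-patient training remainder
  expect_equal(sum(plan$fold == 1), 47)
  expect_equal(sum(plan$fold == 1 & plan$outcome == 1), 13)
  expect_equal(sum(plan$fold != 1), 140)
})

test_that("split is a partition with exact divisibility handled exactly", {
  patients <- tibble::tibble(patient_id = letters[1:8],
                             outcome = rep(c(0L, 1L), 4))
  plan <- stratified_kfold_split(patients, n_folds = 4, seed = 1)
  expect_equal(as.numeric(table(plan$fold)), rep(2, 4))
  expect_true(all(table(plan$fold, plan$outcome) == 1))
  expect_setequal(plan$patient_id, patients$patient_id)
  expect_error(
    stratified_kfold_split(tibble::tibble(patient_id = letters[1:5],
                                          outcome = c(1, 0, 0, 0, 0)), 4),
    "fewer members")
})

test_that("evaluate matches hand AUC and the Mann-Whitney oracle", {
  r <- evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$recall, 1)

  # all-tied scores: AUC 0.5 by the half-credit convention
  expect_equal(evaluate(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  # mixed 6-sample case against the exhaustive pair count
  prob <- c(0.9, 0.4, 0.65, 0.4, 0.2, 0.75)
  lab <- c(1, 0, 1, 1, 0, 0)
  expect_equal(evaluate(prob, lab)$auc, oracle_auc(prob, lab))
  expect_error(evaluate(c(0.2, 0.4), c(1, 1)), "single class")
})

test_that("subject-wise aggregation applies the chosen rule", {
  p <- tibble::tibble(patient_id = c("a", "b", "b"), prob = c(0.4, 0.2, 0.8))
  m <- aggregate_subjectwise(p, "mean")
  expect_equal(m$prob[m$patient_id == "b"], 0.5)
  expect_equal(m$prob[m$patient_id == "a"], 0.4)  # single lesion = identity
  expect_equal(aggregate_subjectwise(p, "max")$prob[2], 0.8)
})

test_that("region classifier recovers separable data and stays honest on nulls", {
  set.seed(5)
  n <- 120
  y <- rep(c(0L, 1L), each = n / 2)
  x <- data.frame(f1 = rnorm(n) + 8 * y, f2 = rnorm(n))
  fit <- fit_region_classifier(x, y, cv_folds = 3, seed = 5, num_trees = 200)
  expect_gt(auc_score <- evaluate(fit$train_prob, y)$auc, 0.95)
  expect_length(fit$train_prob, n)

  # permuted labels: out-of-fold AUC near chance
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    yp <- sample(y)
    f <- fit_region_classifier(x, yp, cv_folds = 3, seed = s, num_trees = 100)
    evaluate(f$train_prob, yp)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("stacking with constant probabilities reduces to clinical information", {
  set.seed(6)
  n <- 160
  y <- rep(c(0L, 1L), each = n / 2)
  clin <- data.frame(pdl1_score = runif(n, 0, 100) + 25 * y,
                     tmb = rexp(n, 1 / 10), smoking = sample(
                       c("never", "former", "current"), n, TRUE),
                     age = sample(40:85, n, TRUE))
  const <- data.frame(pT = rep(0.5, n), ppT = rep(0.5, n))
  m_const <- fit_stacked_classifier(clin, const, y, seed = 6, num_trees = 200)
  # held-out-ish check on fresh draws from the same generator
  set.seed(60)
  clin2 <- data.frame(pdl1_score = runif(n, 0, 100) + 25 * y,
                      tmb = rexp(n, 1 / 10), smoking = sample(
                        c("never", "former", "current"), n, TRUE),
                      age = sample(40:85, n, TRUE))
  const2 <- data.frame(pT = rep(0.5, n), ppT = rep(0.5, n))
  p_const <- predict(m_const, clin2, const2)
  expect_gt(evaluate(p_const, y)$auc, 0.6)  # clinical signal still there

  # informative probabilities materially improve the same model family
  probs <- data.frame(pT = pmin(pmax(0.5 + 0.4 * (y - 0.5) + rnorm(n, 0, 0.1), 0), 1),
                      ppT = rep(0.5, n))
  m_inf <- fit_stacked_classifier(clin, probs, y, seed = 6, num_trees = 200)
  probs2 <- data.frame(pT = pmin(pmax(0.5 + 0.4 * (y - 0.5) + rnorm(n, 0, 0.1), 0), 1),
                       ppT = rep(0.5, n))
  p_inf <- predict(m_inf, clin2, probs2)
  expect_gt(evaluate(p_inf, y)$auc, evaluate(p_const, y)$auc)

  expect_error(fit_stacked_classifier(clin[, -1], const, y), "missing clinical")
})

test_that("smoking is encoded ordinally and unknown levels are rejected", {
  enc <- encode_clinical(data.frame(pdl1_score = 1, tmb = 1,
                                    smoking = c("never", "former", "current"),
                                    age = 60))
  expect_equal(enc$smoking_ord, c(0, 1, 2))
  expect_error(encode_clinical(data.frame(pdl1_score = 1, tmb = 1,
                                          smoking = "pipe", age = 60)),
               "smoking")
})

test_that("the full model matrix is deterministic and leakage-guarded", {
  co <- generate_cohort(cohort_config(n_patients = 16, seed = 31,
                                      texture_effect_size = 1.5))
  feats <- extract_cohort_features(co)
  feats <- dplyr::left_join(
    feats, dplyr::select(co, lesion_id, pdl1_score, tmb, smoking, age),
    by = "lesion_id")
  tum <- grep("^tum_", colnames(feats), value = TRUE)[1:8]
  peri <- grep("^peri_", colnames(feats), value = TRUE)[1:8]
  test_pat <- unique(co$patient_id)[1:4]
  m1 <- run_response_matrix(feats, test_pat, tum, peri, seed = 9, num_trees = 150)
  m2 <- run_response_matrix(feats, test_pat, tum, peri, seed = 9, num_trees = 150)
  expect_identical(m1$metrics, m2$metrics)
  # every training lesion has exactly one pT and one ppT, all in [0, 1]
  expect_equal(nrow(m1$train_probs), sum(!feats$patient_id %in% test_pat))
  expect_true(all(m1$train_probs$pT >= 0 & m1$train_probs$pT <= 1))
  expect_true(all(m1$train_probs$ppT >= 0 & m1$train_probs$ppT <= 1))
  # test lesions never appear among training probabilities
  expect_length(intersect(m1$train_probs$patient_id, test_pat), 0)
  expect_true(all(m1$test_probs$patient_id %in% test_pat))
})
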