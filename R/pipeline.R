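#' Pipeline run configuration
#'
#' @param cohort A [cohort_config()].
#' @param radiomics A [radiomics_config()].
#' @param selection_folds,cv_folds,split_folds Folds for the two-stage
#'   selector, the out-of-fold probability models, and the patient split.
#' @param scan_range Optional prefix-size scan range for selection.
#' @param ess Equivalent sample size for the BN stages.
#' @param threshold Classification threshold.
#' @param t_max RMST horizon (months).
#' @param tau Relevancy margin for report filtering.
#' @param aggregation Subject-wise aggregation rule.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), radiomics = radiomics_config(),
                       selection_folds = 5, cv_folds = 3, split_folds = 4,
                       scan_range = c(1, 20), ess = 1.0, threshold = 0.5,
                       t_max = 32, tau = 0.05, aggregation = "mean",
                       seed = 1L) {
  structure(list(cohort = cohort, radiomics = radiomics,
                 selection_folds = selection_folds, cv_folds = cv_folds,
                 split_folds = split_folds, scan_range = scan_range,
                 ess = ess, threshold = threshold, t_max = t_max, tau = tau,
                 aggregation = aggregation, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates synthesize, extract, select, model, Bayesian structure
#' learning (both the out-of-structure and in-structure modes), survival
#' contrast of the predicted groups, and report generation. Identical
#' config and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, stage outputs
#'   (`features.csv`, `metrics.csv`, `predictions.csv`, `dag_edges.csv`,
#'   `survival.csv`, `reports.md`, `manifest.yaml`) are written there.
#' @return A list of class `pipeline_run` with elements `cohort_features`,
#'   `selection`, `models` (a `response_matrix`), `bnsl` (both modes),
#'   `survival`, `reports`, and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  t_start <- Sys.time()
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  cohort <- tick("synth", generate_cohort(config$cohort))
  feats <- tick("extract", extract_cohort_features(cohort, config$radiomics))
  clin_cols <- c("pdl1_score", "tmb", "smoking", "age", "pfs_months", "pfs_event")
  feats <- dplyr::left_join(
    feats,
    dplyr::select(cohort, dplyr::all_of(c("lesion_id", clin_cols))),
    by = "lesion_id")

  patients <- dplyr::distinct(cohort, .data$patient_id, .data$outcome)
  plan <- stratified_kfold_split(patients, n_folds = config$split_folds,
                                 seed = child_seed(config$seed, "split"))
  test_patients <- plan$patient_id[plan$fold == 1L]
  tr_mask <- !(feats$patient_id %in% test_patients)

  sel <- tick("select", list(
    tumoral = select_region_features(
      feats[tr_mask, ], feats$outcome[tr_mask], "tumoral",
      n_folds = config$selection_folds, seed = child_seed(config$seed, "selT"),
      scan_range = config$scan_range),
    peritumoral = select_region_features(
      feats[tr_mask, ], feats$outcome[tr_mask], "peritumoral",
      n_folds = config$selection_folds, seed = child_seed(config$seed, "selP"),
      scan_range = config$scan_range)
  ))

  models <- tick("train", run_response_matrix(
    feats, test_patients,
    tumoral_features = sel$tumoral$names,
    peritumoral_features = sel$peritumoral$names,
    cv_folds = config$cv_folds, seed = child_seed(config$seed, "models"),
    threshold = config$threshold, aggregation = config$aggregation))

  # BN stages operate on the training cohort, one row per lesion
  tr <- feats[tr_mask, ]
  disc_tr <- discretize_clinical(
    tr, probs = data.frame(pT = models$train_probs$pT,
                           ppT = models$train_probs$ppT))
  bn <- tick("bnsl", {
    clin_only <- disc_tr[, c("pdl1_bin", "tmb_bin", "smoking", "age_bin", "outcome")]
    bnsl1 <- hill_climb_search(clin_only, ess = config$ess)
    bnsl1 <- attach_probability_nodes(bnsl1)
    bnsl2 <- hill_climb_search(disc_tr, ess = config$ess)
    list(bnsl1 = bnsl1, bnsl2 = bnsl2,
         classifier = fit_bayes_classifier(bnsl1, disc_tr, ess = config$ess))
  })

  surv <- tick("survival", {
    subj <- models$subject_probs
    surv_tab <- dplyr::distinct(
      cohort[cohort$patient_id %in% subj$patient_id, ],
      .data$patient_id, .data$pfs_months, .data$pfs_event)
    dat <- dplyr::left_join(subj, surv_tab, by = "patient_id")
    tryCatch(survival_contrast(dat, threshold = config$threshold,
                               t_max = config$t_max),
             error = function(e) e$message)
  })

  reports <- tick("explain", {
    te_probs <- models$test_probs
    te_rows <- feats[match(te_probs$lesion_id, feats$lesion_id), ]
    hyp <- default_hypotheses()
    queries <- lapply(seq_len(nrow(te_probs)), function(i) {
      categorize_patient(te_rows[i, ], te_probs$pT[i], te_probs$ppT[i])
    })
    names(queries) <- te_probs$lesion_id
    knowledge <- graph_to_triplets(bn$bnsl1, hyp, queries)
    vapply(seq_along(queries), function(i) {
      q <- queries[[i]]
      kn <- knowledge[knowledge$patient_id == names(queries)[i], , drop = FALSE]
      if (!nrow(kn)) return(generate_report(q, kn))
      ranked <- rank_features(q, kn)
      retained <- filter_by_relevancy_margin(ranked, config$tau)
      generate_report(q, retained)
    }, character(1))
  })

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    stage_timings_sec = lapply(timings, function(x) round(x, 3)),
    total_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    package_version = as.character(utils::packageVersion("radstack")),
    files = character(0)
  )

  run <- structure(list(cohort_features = feats, split = plan,
                        selection = sel, models = models, bnsl = bn,
                        survival = surv, reports = reports,
                        manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    run$manifest$files <- write_pipeline_outputs(run, out_dir)
    yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  }
  run
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    features = file.path(out_dir, "features.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    predictions = file.path(out_dir, "predictions.csv"),
    dag_edges = file.path(out_dir, "dag_edges.csv"),
    reports = file.path(out_dir, "reports.md")
  )
  write.csv(run$cohort_features, paths["features"], row.names = FALSE)
  write.csv(run$models$metrics, paths["metrics"], row.names = FALSE)
  write.csv(run$models$predictions, paths["predictions"], row.names = FALSE)
  write.csv(run$bnsl$bnsl1$dag, paths["dag_edges"], row.names = FALSE)
  writeLines(run$reports, paths["reports"])
  inv <- as.list(tools::md5sum(unname(paths)))
  names(inv) <- basename(names(inv))
  inv
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$models$metrics)
  if (inherits(x$survival, "survival_contrast")) print(x$survival)
  invisible(x)
}

#' Validate a cohort directory
#'
#' Checks every lesion's NIfTI volume/mask shape agreement, clinical table
#' column completeness and value ranges. Always returns a report rather
#' than erroring.
#'
#' @param dir Directory written by [write_cohort()] (NIfTI pairs +
#'   `cohort.csv`).
#' @return A tibble of issues (`item`, `issue`); zero rows when clean.
#' @export
validate_cohort_dir <- function(dir) {
  issues <- list()
  add <- function(item, issue) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(item = item, issue = issue)
  }
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) {
    add("cohort.csv", "missing clinical table")
    return(dplyr::bind_rows(issues))
  }
  clin <- read.csv(csv)
  need <- c("patient_id", "lesion_id", "lesion_type", "pdl1_score", "tmb",
            "smoking", "age", "sex", "outcome", "pfs_months", "pfs_event")
  for (col in setdiff(need, colnames(clin))) add("cohort.csv", paste("missing column", col))
  if ("pdl1_score" %in% colnames(clin) &&
      any(clin$pdl1_score < 0 | clin$pdl1_score > 100)) {
    add("pdl1_score", "values outside [0, 100]")
  }
  if ("tmb" %in% colnames(clin) && any(clin$tmb < 0)) add("tmb", "negative values")
  if ("age" %in% colnames(clin) && any(clin$age < 18 | clin$age > 110)) {
    add("age", "values outside [18, 110]")
  }
  if ("pfs_months" %in% colnames(clin) && any(clin$pfs_months < 0)) {
    add("pfs_months", "negative values")
  }
  if ("lesion_id" %in% colnames(clin)) {
    for (lid in clin$lesion_id) {
      vp <- file.path(dir, paste0(lid, "_ct.nii.gz"))
      mp <- file.path(dir, paste0(lid, "_mask.nii.gz"))
      if (!file.exists(vp)) { add(lid, "volume NIfTI missing"); next }
      if (!file.exists(mp)) { add(lid, "mask NIfTI missing"); next }
      v <- RNifti::readNifti(vp)
      m <- RNifti::readNifti(mp)
      if (!identical(dim(v), dim(m))) add(lid, "mask shape differs from volume")
      if (!any(m > 0)) add(lid, "empty tumor mask")
    }
  }
  if (!length(issues)) {
    return(tibble::tibble(item = character(0), issue = character(0)))
  }
  dplyr::bind_rows(issues)
}
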