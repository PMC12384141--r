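#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median quantile rbinom rexp rnorm runif rpois pchisq setNames predict
#' @importFrom utils head write.csv read.csv
NULL

# stop unless x is a 3D numeric array
assert_grid3d <- function(x, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort(paste0(what, " must be a 3D array"))
  }
  invisible(x)
}

# population variance (divide by n)
pop_var <- function(x) mean((x - mean(x))^2)

# rank-based AUC with ties counted 1/2 (Mann-Whitney)
auc_score <- function(prob, label) {
  label <- as.integer(label)
  if (length(unique(label)) < 2L) {
    abort("AUC undefined: labels contain a single class")
  }
  as.numeric(pROC::auc(pROC::roc(
    response = label, predictor = as.numeric(prob),
    levels = c(0L, 1L), direction = "<", quiet = TRUE
  )))
}

# stratified instance-level fold assignment (labels -> fold index);
# class members shuffled by the current RNG, sizes differ by at most one,
# larger folds come first
stratified_folds <- function(labels, n_folds) {
  labels <- as.integer(labels)
  if (n_folds < 2) abort("need at least 2 folds")
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) {
      abort(sprintf("class %s has fewer members (%d) than folds (%d)",
                    cl, length(idx), n_folds))
    }
    idx <- sample(idx)
    sizes <- rep(length(idx) %/% n_folds, n_folds)
    extra <- length(idx) %% n_folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold[idx] <- rep(seq_len(n_folds), times = sizes)
  }
  fold
}

# cap an internal CV fold count at the minority class size so tiny cohorts
# still cross-validate (the patient-level split plan stays strict)
cap_cv_folds <- function(labels, n_folds) {
  m <- min(table(as.integer(labels)))
  if (m < n_folds) {
    warn(sprintf("reducing CV folds from %d to %d (minority class size)",
                 n_folds, max(m, 2)))
    n_folds <- max(m, 2)
  }
  as.integer(n_folds)
}

# derive a reproducible child seed from a base seed and a stage tag
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483587)
}
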