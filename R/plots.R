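#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_line
#'   labs theme_minimal geom_col coord_flip
NULL

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$survival)) +
    geom_step() +
    labs(x = "Months", y = "Progression-free survival") +
    theme_minimal()
}

#' Plot the incremental feature-selection AUC curve
#'
#' @param object A `selected_features` from [incremental_auc_selection()].
#' @param ... Unused.
#' @return A ggplot with the chosen subset size highlighted.
#' @method autoplot selected_features
#' @export
autoplot.selected_features <- function(object, ...) {
  ggplot(object$auc_curve, aes(x = .data$subset_size, y = .data$mean_auc)) +
    geom_line() +
    geom_point(data = object$auc_curve[
      object$auc_curve$subset_size == object$chosen_size, ],
      colour = "red", size = 2) +
    labs(x = "Top-k features", y = "Mean out-of-fold AUC") +
    theme_minimal()
}

#' Plot the response-model metric matrix
#'
#' @param object A `response_matrix` from [run_response_matrix()].
#' @param ... Unused.
#' @return A ggplot bar chart of AUC by method.
#' @method autoplot response_matrix
#' @export
autoplot.response_matrix <- function(object, ...) {
  m <- object$metrics
  m$method <- factor(m$method, levels = rev(m$method))
  ggplot(m, aes(x = .data$method, y = .data$auc)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "AUC") +
    theme_minimal()
}

#' Plot both arms of a survival contrast
#'
#' @param object A `survival_contrast` from [survival_contrast()].
#' @param ... Unused.
#' @return A ggplot with one step curve per predicted group.
#' @method autoplot survival_contrast
#' @export
autoplot.survival_contrast <- function(object, ...) {
  dat <- dplyr::bind_rows(lapply(names(object$curves), function(g) {
    dplyr::mutate(object$curves[[g]], group = g)
  }))
  ggplot(dat, aes(x = .data$time, y = .data$survival, colour = .data$group)) +
    geom_step() +
    labs(x = "Months", y = "Progression-free survival", colour = NULL) +
    theme_minimal()
}
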