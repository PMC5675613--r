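#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a score matrix into long format
#'
#' @param x An `mda_scores` object.
#' @param known Optional binary association matrix adding an `is_known`
#'   column.
#' @param ... Unused.
#' @return A tibble (mirna, disease, score\[, is_known\]) sorted by
#'   descending score.
#' @exportS3Method generics::tidy
tidy.mda_scores <- function(x, known = NULL, ...) {
  scores_to_table(x, known = known)
}

#' @exportS3Method generics::glance
glance.mda_scores <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_mirnas = nrow(x$SS),
    n_diseases = ncol(x$SS),
    min_score = min(x$SS),
    max_score = max(x$SS)
  )
}

#' Tidy an ROC result into curve points
#'
#' @param x An `mda_roc` object.
#' @param ... Unused.
#' @return A tibble (threshold, fpr, tpr).
#' @exportS3Method generics::tidy
tidy.mda_roc <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}

#' @exportS3Method generics::glance
glance.mda_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_points = length(x$fpr))
}

#' Tidy a LOOCV result into one row per held-out association
#'
#' @param x An `mda_loocv` object.
#' @param ... Unused.
#' @return A tibble (mirna, disease, concordance).
#' @exportS3Method generics::tidy
tidy.mda_loocv <- function(x, ...) {
  x$holdouts
}

#' @exportS3Method generics::glance
glance.mda_loocv <- function(x, ...) {
  tibble::tibble(auc = x$auc, rounds = nrow(x$holdouts),
                 n_candidates = x$n_candidates)
}

#' Tidy a repeated cross-validation result
#'
#' @param x An `mda_cv` object.
#' @param ... Unused.
#' @return A tibble (repetition, auc).
#' @exportS3Method generics::tidy
tidy.mda_cv <- function(x, ...) {
  tibble::tibble(repetition = seq_along(x$per_repetition_auc),
                 auc = x$per_repetition_auc)
}

#' @exportS3Method generics::glance
glance.mda_cv <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, sd_auc = x$sd_auc, folds = x$folds,
                 repetitions = x$repetitions, seed = x$seed)
}

#' Plot an ROC curve
#'
#' @param object An `mda_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mda_roc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166AC", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate",
      y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.4f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mda_roc
#' @exportS3Method ggplot2::autoplot
autoplot.mda_loocv <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::labs(title = sprintf("LOOCV ROC (AUC = %.4f)", object$auc))
}

#' Plot per-repetition cross-validation AUCs
#'
#' @param object An `mda_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mda_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$repetition, y = .data$auc)) +
    ggplot2::geom_hline(yintercept = object$mean_auc, colour = "#B2182B") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Repetition", y = "AUC",
      title = sprintf("%d x %d-fold CV: mean AUC = %.4f (sd %.4f)",
                      object$repetitions, object$folds, object$mean_auc,
                      object$sd_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of prediction scores
#'
#' @param scores An `mda_scores` object or score matrix.
#' @return A ggplot tile map, miRNAs on rows and diseases on columns.
#' @export
plot_score_heatmap <- function(scores) {
  df <- scores_to_table(scores)
  df$mirna <- factor(df$mirna, levels = rev(rownames(as_score_matrix(scores))))
  df$disease <- factor(df$disease, levels = colnames(as_score_matrix(scores)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease, y = .data$mirna,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Disease", y = "miRNA", fill = "Score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
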