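# ggplot2 views of the result objects. autoplot() methods dispatch on class;
# the plot_*() wrappers are explicit-name aliases.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gene ranking
#'
#' Signed distance against rank, most atypical first; genes in the top
#' `top_fraction` of the list are highlighted as the called set.
#'
#' @param object An `atyp_ranking`.
#' @param top_fraction Highlighted head fraction (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot atyp_ranking
#' @export
autoplot.atyp_ranking <- function(object, top_fraction = 0.05, ...) {
  df <- tibble::as_tibble(object)
  n_called <- max(1L, round(top_fraction * nrow(df)))
  df$called <- df$rank <= n_called
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$signed_distance)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$called), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                                 name = sprintf("top %.0f%%", 100 * top_fraction)) +
    ggplot2::labs(x = "rank (most atypical first)",
                  y = "signed distance to decision boundary") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.atyp_ranking
#' @param ranking An `atyp_ranking`.
#' @export
plot_ranking <- function(ranking, top_fraction = 0.05) {
  autoplot(ranking, top_fraction = top_fraction)
}

#' Plot a ranking-stability profile
#'
#' Windowed Spearman correlation against nu, one curve per gamma: the view
#' used to pick parameters where the ranking is stable.
#'
#' @param object An `atyp_stability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot atyp_stability
#' @export
autoplot.atyp_stability <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nu, y = .data$rho,
                                   colour = .data$gamma_label)) +
    ggplot2::geom_point(size = 0.5, na.rm = TRUE) +
    ggplot2::labs(x = expression(nu), y = expression("windowed Spearman " * rho),
                  colour = expression(gamma)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.atyp_stability
#' @param profile An `atyp_stability`.
#' @export
plot_stability <- function(profile) {
  autoplot(profile)
}

#' Plot an ROC curve
#'
#' @param object An `atyp_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot atyp_eval
#' @export
autoplot.atyp_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.atyp_eval
#' @param eval_result An `atyp_eval`.
#' @export
plot_roc <- function(eval_result) {
  autoplot(eval_result)
}

#' Plot benchmark AUC distributions per feature set
#'
#' Boxplot of per-family AUC scores for each feature set, with the 0.5 line
#' marking the score expected for a random result.
#'
#' @param object An `atyp_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot atyp_benchmark
#' @export
autoplot.atyp_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spec, y = .data$auc)) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey50") +
    ggplot2::geom_boxplot(na.rm = TRUE) +
    ggplot2::labs(x = "feature set", y = "AUC (simulated outliers)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.atyp_benchmark
#' @param bm An `atyp_benchmark`.
#' @export
plot_benchmark <- function(bm) {
  autoplot(bm)
}
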