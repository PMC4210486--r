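#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gene ranking
#'
#' @param x An `atyp_ranking`.
#' @param ... Unused.
#' @return A plain tibble `rank`, `gene_id`, `signed_distance`.
#' @method tidy atyp_ranking
#' @export
tidy.atyp_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a gene ranking
#'
#' @param x An `atyp_ranking`.
#' @param ... Unused.
#' @return A tibble with the feature set, resolved parameters, number of
#'   ranked genes and the count of genes outside the boundary (negative
#'   signed distance).
#' @method glance atyp_ranking
#' @export
glance.atyp_ranking <- function(x, ...) {
  tibble::tibble(
    feature_set = attr(x, "spec")$name,
    dim = attr(x, "spec")$dim,
    nu = attr(x, "nu"),
    gamma = attr(x, "gamma"),
    n = attr(x, "n"),
    n_outside = sum(x$signed_distance < 0)
  )
}

#' Tidy a stability profile
#'
#' @param x An `atyp_stability`.
#' @param ... Unused.
#' @return A plain tibble `gamma_label`, `gamma`, `nu`, `rho`.
#' @method tidy atyp_stability
#' @export
tidy.atyp_stability <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Per-gamma summary of a stability profile
#'
#' @param x An `atyp_stability`.
#' @param ... Unused.
#' @return A tibble with, per gamma, mean rho, mean rho over nu > 0.8, and
#'   the fraction of non-degenerate fits.
#' @method glance atyp_stability
#' @export
glance.atyp_stability <- function(x, ...) {
  cov <- attr(x, "coverage")
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$gamma_label, .data$gamma) |>
    dplyr::summarise(
      mean_rho = mean(.data$rho, na.rm = TRUE),
      mean_rho_high_nu = mean(.data$rho[.data$nu > 0.8], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::left_join(cov, by = "gamma_label")
}

#' Tidy an evaluation result (ROC points)
#'
#' @param x An `atyp_eval`.
#' @param ... Unused.
#' @return A tibble `fpr`, `tpr`.
#' @method tidy atyp_eval
#' @export
tidy.atyp_eval <- function(x, ...) {
  x$roc_points
}

#' One-row summary of an evaluation result
#'
#' @param x An `atyp_eval`.
#' @param ... Unused.
#' @return A tibble `auc`, `success`, `n_pos`, `n_neg`, `n_called`.
#' @method glance atyp_eval
#' @export
glance.atyp_eval <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    success = x$success,
    n_pos = x$n_pos,
    n_neg = x$n_neg,
    n_called = length(x$called)
  )
}

#' @export
print.atyp_eval <- function(x, ...) {
  cat(sprintf("<atyp_eval> AUC = %.4f (%s); %d injected vs %d inherent; %d called\n",
              x$auc, x$success, x$n_pos, x$n_neg, length(x$called)))
  invisible(x)
}

#' Tidy a benchmark table
#'
#' @param x An `atyp_benchmark`.
#' @param ... Unused.
#' @return A plain tibble of per-(family, spec) results.
#' @method tidy atyp_benchmark
#' @export
tidy.atyp_benchmark <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a benchmark run
#'
#' @param x An `atyp_benchmark`.
#' @param ... Unused.
#' @return A tibble `n_families`, `n_specs`, `success_rate`,
#'   `semi_success_rate`, `median_auc` (over all cells).
#' @method glance atyp_benchmark
#' @export
glance.atyp_benchmark <- function(x, ...) {
  s <- summarize_benchmark(x)
  tibble::tibble(
    n_families = length(unique(x$family)),
    n_specs = length(unique(x$spec)),
    success_rate = s$success_rate,
    semi_success_rate = s$semi_success_rate,
    median_auc = stats::median(x$auc, na.rm = TRUE)
  )
}
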