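# Ranking-stability parameter selection: sweep (gamma, nu), measure how much
# the induced ranking changes between neighboring nu values with Spearman's
# rho, and prefer parameter regions where the ranking is stable.

#' The default nu grid: 1,000 equidistant values in (0, 1]
#'
#' @return Numeric vector `0.001, 0.002, ..., 1.000` (spacing exactly 0.001).
#' @export
nu_grid <- function() {
  seq_len(1000L) / 1000
}

#' The default gamma grid
#'
#' The wide exploration grid `1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.1, 1, 10, 100`
#' plus the rule-of-thumb value (2D)^-1 for the given feature dimension.
#'
#' @param D Feature-space dimensionality (used to resolve the rule of thumb).
#' @return Named numeric vector of 10 gamma values.
#' @export
gamma_grid <- function(D) {
  g <- c(1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.1, 1, 10, 100, resolve_gamma(as.numeric(D)))
  names(g) <- c("1e-06", "1e-05", "1e-04", "0.001", "0.01", "0.1",
                "1", "10", "100", "rule_of_thumb")
  g
}

#' Spearman's rank correlation between two rankings
#'
#' Standard Spearman correlation of two equal-length rank (or score) vectors;
#' ties use the mid-rank convention. 1 means identical orderings, -1 reversed.
#'
#' @param rank_a,rank_b Numeric vectors of equal length >= 2.
#' @return A number in \\[-1, 1\\].
#' @examples
#' spearman_rho(1:4, c(1, 2, 4, 3))  # 0.8
#' @export
spearman_rho <- function(rank_a, rank_b) {
  if (length(rank_a) != length(rank_b)) {
    abort_validation("`rank_a` and `rank_b` must have equal length.")
  }
  if (length(rank_a) < 2L) {
    abort_validation("Spearman correlation needs at least 2 elements.")
  }
  # A fully tied vector has no defined rank correlation; report NA rather
  # than warn (arises in sweeps when a fit collapses to constant distances).
  rho <- suppressWarnings(stats::cor(rank_a, rank_b, method = "spearman"))
  if (is.nan(rho)) NA_real_ else rho
}

#' Ranking-stability sweep over (gamma, nu)
#'
#' For each gamma and each nu on the grid the one-class SVM ranking is
#' computed; the stability at nu_i is the average of the Spearman correlation
#' of its ranking with the rankings at nu_{i-1} and nu_{i+1} (boundary grid
#' points use their single neighbor). Degenerate fits are recorded as missing
#' values rather than aborting the sweep.
#'
#' The full default grid is 10 gamma values times 1,000 nu values; for
#' exploratory use pass reduced grids.
#'
#' @param fm A standardized feature table.
#' @param gammas Numeric vector of gamma values (may be named); defaults to
#'   [gamma_grid()] at the table's dimension.
#' @param nus Numeric vector of nu values in (0, 1]; defaults to [nu_grid()].
#' @return A tibble of class `atyp_stability` with columns `gamma_label`,
#'   `gamma`, `nu`, `rho`; attribute `coverage` gives the fraction of
#'   non-degenerate fits per gamma.
#' @export
stability_sweep <- function(fm, gammas = NULL, nus = nu_grid()) {
  if (!inherits(fm, "atyp_features") || !isTRUE(attr(fm, "standardized"))) {
    abort_validation("`fm` must be a standardized feature table.")
  }
  x <- feature_values(fm)
  if (is.null(gammas)) gammas <- gamma_grid(ncol(x))
  if (is.null(names(gammas))) names(gammas) <- as.character(gammas)
  if (any(gammas <= 0)) abort_parameter("All gamma values must be positive.")
  nus <- sort(unique(nus))
  if (any(nus <= 0 | nus > 1)) abort_parameter("All nu values must lie in (0, 1].")
  if (length(nus) < 2L) abort_parameter("The nu grid needs at least 2 values.")

  res <- purrr::map(seq_along(gammas), function(gi) {
    gamma <- gammas[[gi]]
    dists <- purrr::map(nus, function(nu) {
      tryCatch(ocsvm_decision(x, nu, gamma), atyp_degenerate_fit = function(e) NULL)
    })
    rho <- purrr::map_dbl(seq_along(nus), function(i) {
      if (is.null(dists[[i]])) return(NA_real_)
      nb <- c(i - 1L, i + 1L)
      nb <- nb[nb >= 1L & nb <= length(nus)]
      vals <- purrr::map_dbl(nb, function(j) {
        if (is.null(dists[[j]])) return(NA_real_)
        spearman_rho(dists[[i]], dists[[j]])
      })
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    })
    tibble::tibble(
      gamma_label = names(gammas)[gi],
      gamma = gamma,
      nu = nus,
      rho = rho,
      fit_ok = !purrr::map_lgl(dists, is.null)
    )
  })
  out <- dplyr::bind_rows(res)
  coverage <- out |>
    dplyr::group_by(.data$gamma_label) |>
    dplyr::summarise(coverage = mean(.data$fit_ok), .groups = "drop")
  out$fit_ok <- NULL
  structure(
    out,
    class = c("atyp_stability", class(tibble::tibble())),
    coverage = coverage,
    spec = attr(fm, "spec")
  )
}

#' Write a stability profile as TSV
#'
#' Columns: `gamma`, `nu`, `rho`.
#'
#' @param profile An `atyp_stability` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stability_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("gamma", "nu", "rho")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
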