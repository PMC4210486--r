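# Signed-distance ranking with a one-class nu-SVM (Gaussian kernel). The
# solver is libsvm via e1071; everything around it — the standardization
# contract, the signed-distance convention, the tie rule and the ranking —
# is defined here.

# Solver termination tolerance, fixed for reproducibility. Tight enough that
# decision values are invariant to row order well below the 1e-9 scale at
# which ranking equivariance is guaranteed (at 1e-6 the residual solver noise
# reorders near-boundary points).
SVM_TOLERANCE <- 1e-12

#' Resolve the Gaussian-kernel width
#'
#' The token `"rule_of_thumb"` resolves to \eqn{(2D)^{-1}}, where D is the
#' dimensionality of the feature space; numeric values pass through.
#'
#' @param spec Feature-set name/alias, or directly the integer dimension D.
#' @param gamma Positive number or the token `"rule_of_thumb"`.
#' @return A positive numeric gamma.
#' @examples
#' resolve_gamma("gc_content", "rule_of_thumb")  # 0.5
#' resolve_gamma("tetra", "rule_of_thumb")       # 1/512
#' @export
resolve_gamma <- function(spec, gamma = "rule_of_thumb") {
  D <- if (is.numeric(spec)) {
    if (!is_scalar_number(spec) || spec < 1) abort_parameter("`spec` as a dimension must be >= 1.")
    as.integer(spec)
  } else {
    canonical_spec(spec)$dim
  }
  if (identical(gamma, "rule_of_thumb")) {
    return(1 / (2 * D))
  }
  if (!is_scalar_number(gamma) || gamma <= 0) {
    abort_parameter("`gamma` must be a positive number or \"rule_of_thumb\".")
  }
  gamma
}

check_nu <- function(nu) {
  if (!is_scalar_number(nu) || nu <= 0 || nu > 1) {
    abort_parameter("`nu` must lie in (0, 1].")
  }
  nu
}

# Fit a one-class SVM and return the decision-function values of `score_x`
# (defaults to the training matrix). Negative values lie outside the learned
# boundary. Degenerate fits surface as atyp_degenerate_fit.
ocsvm_decision <- function(train_x, nu, gamma, score_x = train_x, context = "") {
  fit <- tryCatch(
    e1071::svm(train_x, y = NULL, type = "one-classification",
               kernel = "radial", gamma = gamma, nu = nu,
               scale = FALSE, tolerance = SVM_TOLERANCE),
    error = function(e) abort_degenerate(paste0(
      "One-class SVM fit failed", if (nzchar(context)) paste0(" for ", context),
      " (nu=", signif(nu, 6), ", gamma=", signif(gamma, 6), "): ",
      conditionMessage(e)
    ))
  )
  pred <- stats::predict(fit, score_x, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  if (anyNA(dv) || any(!is.finite(dv))) {
    abort_degenerate(paste0(
      "One-class SVM produced non-finite decision values",
      if (nzchar(context)) paste0(" for ", context), "."
    ))
  }
  dv
}

new_ranking <- function(gene_id, signed_distance, spec, nu, gamma, extra = list()) {
  ord <- order(signed_distance, seq_along(signed_distance))  # ties: ingest order
  tbl <- tibble::tibble(
    rank = seq_along(ord),
    gene_id = gene_id[ord],
    signed_distance = signed_distance[ord]
  )
  structure(
    tbl,
    class = c("atyp_ranking", class(tibble::tibble())),
    spec = spec, nu = nu, gamma = gamma,
    n = length(ord), extra = extra
  )
}

#' Rank genes from most atypical to most typical
#'
#' Fits a one-class nu-SVM with a Gaussian kernel on all rows of a
#' standardized feature table and ranks genes by their signed distance to the
#' decision boundary, ascending: points outside the boundary have negative
#' distances, so the most atypical genes come first. Ties break on dataset
#' ingest order. Defaults are nu = 0.2 and gamma = (2D)^-1.
#'
#' @param fm A standardized feature table (see [standardize_features()]).
#' @param nu Expected outlier fraction bound, in (0, 1]; default 0.2.
#' @param gamma Gaussian kernel width; positive number or `"rule_of_thumb"`
#'   for (2D)^-1.
#' @return A tibble of class `atyp_ranking` with columns `rank`, `gene_id`,
#'   `signed_distance`, most atypical first. Attributes record the feature
#'   spec and resolved parameters.
#' @examples
#' g <- generate_family("Toy", n_genes = 30, length_codons = c(30, 60), seed = 1)
#' fm <- standardize_features(gene_features(g, "mono"))
#' rank_genes(fm, nu = 0.2)
#' @export
rank_genes <- function(fm, nu = 0.2, gamma = "rule_of_thumb") {
  if (!inherits(fm, "atyp_features")) {
    abort_validation("`fm` must be a feature table from gene_features().")
  }
  if (!isTRUE(attr(fm, "standardized"))) {
    abort_validation("`fm` must be standardized (see standardize_features()).")
  }
  check_nu(nu)
  x <- feature_values(fm)
  gamma <- resolve_gamma(ncol(x), gamma)
  dv <- ocsvm_decision(x, nu, gamma,
                       context = paste0(nrow(x), "-gene feature table"))
  new_ranking(fm$gene_id, dv, attr(fm, "spec"), nu, gamma)
}

#' GC-content baseline ranking
#'
#' The one-dimensional baseline: genes are ranked by their deviation from the
#' median GC content of the family, largest deviation first. The GC content
#' is not supplied to the SVM. The `signed_distance` column stores the
#' negated absolute deviation so the ascending-order convention of
#' [rank_genes()] holds.
#'
#' @param genes A gene table with at least 4 encodable genes.
#' @return A tibble of class `atyp_ranking`.
#' @export
gc_baseline_rank <- function(genes) {
  fm <- gene_features(genes, "gc_content")
  gc <- feature_values(fm)[, 1L]
  dev <- abs(gc - stats::median(gc))
  new_ranking(fm$gene_id, -dev, attr(fm, "spec"), nu = NA_real_, gamma = NA_real_,
              extra = list(median_gc = stats::median(gc)))
}

#' Rank genome segments against a background
#'
#' Sliding-window mode: the SVM is trained on background feature rows and the
#' segments are scored by the fitted decision function. With
#' `background = "self"` the statistics come from the segment set itself
#' (equivalent to [rank_genes()] on the segment matrix); with a gene table as
#' background, family-level statistics are used, which lets segment scoring
#' borrow strength from all genes of the family.
#'
#' @param segments A segment table from [sliding_window()] (or any table with
#'   `segment_id`/`gene_id` and `seq`).
#' @param background `"self"` or a gene table providing the training rows
#'   (>= 4 encodable rows).
#' @param spec Feature-set name; default tetranucleotide frequencies.
#' @param nu,gamma SVM parameters as in [rank_genes()].
#' @return A tibble of class `atyp_ranking` over the segment ids.
#' @export
rank_segments <- function(segments, background = "self", spec = "tetra",
                          nu = 0.2, gamma = "rule_of_thumb") {
  if (!is.data.frame(segments) || nrow(segments) == 0L) {
    abort_validation("`segments` must be a non-empty data frame.")
  }
  seg <- segments
  if (!"gene_id" %in% names(seg)) {
    if (!"segment_id" %in% names(seg)) {
      abort_validation("`segments` needs a `segment_id` (or `gene_id`) column.")
    }
    seg$gene_id <- seg$segment_id
  }
  check_nu(nu)

  if (identical(background, "self")) {
    fm <- standardize_features(gene_features(seg, spec))
    return(rank_genes(fm, nu = nu, gamma = gamma))
  }
  check_gene_table(background, require_family = FALSE, arg = "background")
  bg_fm <- standardize_features(gene_features(background, spec))
  bg_x <- feature_values(bg_fm)
  gamma <- resolve_gamma(ncol(bg_x), gamma)

  seg_fm <- gene_features(seg, spec, min_rows = 1L)
  seg_x <- scale_with(feature_values(seg_fm),
                      attr(bg_fm, "center"), attr(bg_fm, "scale"))
  dv <- ocsvm_decision(bg_x, nu, gamma, score_x = seg_x,
                       context = "segment background")
  new_ranking(seg_fm$gene_id, dv, attr(bg_fm, "spec"), nu, gamma,
              extra = list(background = "family"))
}

#' Write a ranking as TSV with a JSON sidecar
#'
#' TSV columns: `rank`, `gene_id`, `signed_distance`, most atypical first.
#' The sidecar records the feature spec, resolved parameters and exclusions.
#'
#' @param ranking An `atyp_ranking`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @param extra Named list merged into the sidecar (e.g. seed, input checksums).
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path, extra = list()) {
  utils::write.table(as.data.frame(ranking)[, c("rank", "gene_id", "signed_distance")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- attr(ranking, "spec")
  sidecar <- c(list(
    feature_set = spec$name,
    dim = spec$dim,
    nu = attr(ranking, "nu"),
    gamma = attr(ranking, "gamma"),
    n_ranked = attr(ranking, "n")
  ), extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
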