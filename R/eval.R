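# Simulated-outlier evaluation: inject alien genes into a family, rank, and
# score the ranking against the injected labels with ROC/AUC.

#' Inject artificial outlier genes into a family
#'
#' Amends a family with genes sampled uniformly at random (without
#' replacement) from a pool of genes belonging to other families, so that the
#' chosen fraction of the amended family consists of outliers. With base size
#' n the injected count is `m = max(1, round(n * fraction / (1 - fraction)))`,
#' which makes `m / (n + m)` hit the target fraction where divisible and
#' guarantees at least one outlier.
#'
#' Note the caveat inherited from real data: any true (pre-existing) atypical
#' genes in the base family remain unlabeled and compete with the injected
#' ones.
#'
#' @param base Gene table of a single family.
#' @param pool Gene table of candidate outliers; every pool family must
#'   differ from the base family.
#' @param fraction Target outlier fraction of the amended family (default
#'   0.05).
#' @param seed Integer seed; the same seed yields the identical injected set.
#' @return The amended gene table (base rows first, injected rows after, each
#'   in ingest order) with extra columns `source_family` and `label`
#'   (`"inherent"` / `"injected"`); attributes `base_family`, `n_injected`,
#'   `seed`.
#' @export
inject_outliers <- function(base, pool, fraction = 0.05, seed = NULL) {
  check_gene_table(base, arg = "base")
  check_gene_table(pool, arg = "pool")
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1) {
    abort_parameter("`fraction` must lie strictly between 0 and 1.")
  }
  base_family <- unique(base$family)
  if (length(base_family) != 1L) {
    abort_validation("`base` must hold exactly one family.")
  }
  if (any(pool$family == base_family)) {
    abort_validation(paste0(
      "`pool` contains genes from the base family '", base_family, "'."
    ))
  }
  n <- nrow(base)
  m <- max(1L, round(n * fraction / (1 - fraction)))
  if (nrow(pool) < m) {
    abort_validation(paste0(
      "Pool holds ", nrow(pool), " genes but ", m, " outliers are required."
    ))
  }
  picked <- with_seed(seed, pool[sample.int(nrow(pool), m), , drop = FALSE])

  inj_ids <- picked$gene_id
  clash <- inj_ids %in% base$gene_id
  inj_ids[clash] <- paste0("inj_", inj_ids[clash])

  out <- dplyr::bind_rows(
    dplyr::mutate(base,
                  source_family = .data$family,
                  label = "inherent"),
    tibble::tibble(
      gene_id = inj_ids,
      family = base_family,
      seq = picked$seq,
      length_nt = nchar(picked$seq),
      source_family = picked$family,
      label = "injected"
    )
  )
  structure(out,
            base_family = base_family,
            n_injected = m,
            seed = seed)
}

#' A uniformly random gene ranking
#'
#' Replaces the SVM with a random permutation: the null model against which
#' signal is judged (expected AUC 0.5).
#'
#' @param gene_ids Character vector of gene ids to rank.
#' @param seed Optional integer seed.
#' @return A tibble of class `atyp_ranking`.
#' @export
random_ranking <- function(gene_ids, seed = NULL) {
  gene_ids <- as.character(gene_ids)
  perm <- with_seed(seed, sample.int(length(gene_ids)))
  reg <- tibble::tibble(name = "random", alias = "random", k = NA_integer_, dim = NA_integer_)
  new_ranking(gene_ids[perm], seq_along(perm), reg, nu = NA_real_, gamma = NA_real_)
}

#' ROC/AUC of a ranking against outlier labels
#'
#' AUC over all cutoffs of the ranking, positives being the injected genes.
#' Tied signed distances are handled by the pair-counting convention (each
#' tied positive-negative pair contributes 1/2), which equals the trapezoidal
#' area under the ROC curve drawn with one point per tie block. The genes in
#' the top `top_fraction` of the list are reported as the called set of
#' predicted atypical genes.
#'
#' @param ranking An `atyp_ranking`.
#' @param labels Either a data frame with columns `gene_id` and `label`, or a
#'   character vector named by gene_id; labels are `"injected"` /
#'   `"inherent"`.
#' @param top_fraction Fraction of the list reported as called (default 0.05).
#' @return An object of class `atyp_eval`: a list with elements `auc`,
#'   `roc_points` (tibble `fpr`, `tpr`), `called` (gene ids), `success`
#'   (see [classify_success()]), `n_pos`, `n_neg`, `top_fraction`.
#' @export
compute_auc <- function(ranking, labels, top_fraction = 0.05) {
  if (!inherits(ranking, "atyp_ranking")) {
    abort_validation("`ranking` must be an atyp_ranking.")
  }
  lab <- normalize_labels(labels)
  missing <- setdiff(ranking$gene_id, names(lab))
  if (length(missing) > 0L) {
    abort_validation(paste0(
      "Labels missing for ranked gene(s): ",
      paste(utils::head(missing, 5L), collapse = ", ")
    ))
  }
  y <- lab[ranking$gene_id] == "injected"
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    abort_validation("Labels must contain at least one injected and one inherent gene.")
  }

  # One ROC point per distinct signed distance (tie block), walking the list
  # from most atypical to most typical.
  blocks <- cumsum(!duplicated(ranking$signed_distance))
  tp <- unname(cumsum(y)); fp <- unname(cumsum(!y))
  last <- !duplicated(blocks, fromLast = TRUE)
  roc <- tibble::tibble(
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)

  n_called <- max(1L, round(top_fraction * nrow(ranking)))
  structure(
    list(
      auc = auc,
      roc_points = roc,
      called = ranking$gene_id[seq_len(n_called)],
      success = classify_success(auc),
      n_pos = n_pos,
      n_neg = n_neg,
      top_fraction = top_fraction
    ),
    class = "atyp_eval"
  )
}

normalize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("gene_id", "label") %in% names(labels))) {
      abort_validation("`labels` data frame needs `gene_id` and `label` columns.")
    }
    stats::setNames(as.character(labels$label), labels$gene_id)
  } else if (is.character(labels) && !is.null(names(labels))) {
    labels
  } else {
    abort_validation("`labels` must be a data frame or a named character vector.")
  }
}

#' Classify an AUC score as success / semi-success / none
#'
#' A prediction is successful if the AUC exceeds 0.9 and semi-successful if
#' it only exceeds 0.8 ("exceeds" read strictly, so 0.8 and 0.9 exactly fall
#' in the lower category).
#'
#' @param auc Numeric vector of AUC scores in \\[0, 1\\].
#' @return Character vector over `{"success", "semi_success", "none"}`.
#' @examples
#' classify_success(c(0.95, 0.85, 0.80))
#' @export
classify_success <- function(auc) {
  if (!is.numeric(auc) || anyNA(auc) || any(auc < 0 | auc > 1)) {
    abort_parameter("`auc` values must lie in [0, 1].")
  }
  dplyr::case_when(
    auc > 0.9 ~ "success",
    auc > 0.8 ~ "semi_success",
    .default = "none"
  )
}

#' Simulated-outlier benchmark over a set of families
#'
#' For each family with more than three genes: inject outliers drawn from the
#' genes of all other families, extract each requested feature set,
#' standardize, rank with the one-class SVM (the GC-content spec instead uses
#' the median-deviation baseline), and evaluate the ranking against the
#' injected labels. Per-cell failures are recorded, not fatal.
#'
#' @param genes Gene table holding at least two families.
#' @param specs Character vector of feature-set names (default
#'   `"tetra"`, the best-performing signature).
#' @param nu,gamma SVM parameters (defaults nu = 0.2, gamma = (2D)^-1).
#' @param fraction Injected outlier fraction (default 0.05).
#' @param seed Integer seed; per-family injection seeds are derived as
#'   `seed + family index`.
#' @return A tibble of class `atyp_benchmark`: columns `family`, `spec`,
#'   `n_genes`, `n_injected`, `auc`, `success`, `error`. Attributes carry the
#'   run parameters; see [summarize_benchmark()].
#' @export
run_family_benchmark <- function(genes, specs = "tetra", nu = 0.2,
                                 gamma = "rule_of_thumb", fraction = 0.05,
                                 seed = 1L) {
  check_gene_table(genes)
  families <- unique(genes$family)
  if (length(families) < 2L) {
    abort_validation("The benchmark needs at least 2 families (each is the pool for the others).")
  }
  specs <- vapply(specs, function(s) canonical_spec(s)$name, character(1))

  rows <- purrr::map(seq_along(families), function(i) {
    fam <- families[i]
    base <- genes[genes$family == fam, , drop = FALSE]
    pool <- genes[genes$family != fam, , drop = FALSE]
    if (nrow(base) < 4L) {
      return(tibble::tibble(
        family = fam, spec = specs, n_genes = nrow(base), n_injected = NA_integer_,
        auc = NA_real_, success = NA_character_,
        error = "family has fewer than 4 genes"
      ))
    }
    sim <- inject_outliers(base, pool, fraction = fraction,
                           seed = if (is.null(seed)) NULL else seed + i)
    purrr::map(specs, function(sp) {
      cell <- tryCatch({
        rk <- if (sp == "gc_content") {
          gc_baseline_rank(sim)
        } else {
          rank_genes(standardize_features(gene_features(sim, sp)),
                     nu = nu, gamma = gamma)
        }
        ev <- compute_auc(rk, sim[, c("gene_id", "label")])
        tibble::tibble(auc = ev$auc, success = ev$success, error = NA_character_)
      }, atyp_error = function(e) {
        tibble::tibble(auc = NA_real_, success = NA_character_,
                       error = conditionMessage(e))
      })
      dplyr::bind_cols(
        tibble::tibble(family = fam, spec = sp,
                       n_genes = nrow(base),
                       n_injected = attr(sim, "n_injected")),
        cell
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    class = c("atyp_benchmark", class(tibble::tibble())),
    params = list(specs = specs, nu = nu, gamma = gamma,
                  fraction = fraction, seed = seed),
    caveat = paste(
      "True (pre-existing) atypical genes in the base families are unlabeled",
      "contamination; measured AUC is a lower bound in that sense."
    )
  )
}

#' Summaries of a benchmark run
#'
#' Per-spec median AUC across families, per-family best AUC over specs with
#' the family-level success call (a family counts as successful if at least
#' one feature set achieves success), and overall success / semi-success
#' rates.
#'
#' @param bm An `atyp_benchmark`.
#' @return A list with elements `per_spec`, `per_family`, `success_rate`,
#'   `semi_success_rate`, `caveat`.
#' @export
summarize_benchmark <- function(bm) {
  if (!inherits(bm, "atyp_benchmark")) {
    abort_validation("`bm` must come from run_family_benchmark().")
  }
  tbl <- tibble::as_tibble(bm)
  per_spec <- tbl |>
    dplyr::group_by(.data$spec) |>
    dplyr::summarise(median_auc = stats::median(.data$auc, na.rm = TRUE),
                     .groups = "drop")
  per_family <- tbl |>
    dplyr::filter(!is.na(.data$auc)) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(best_auc = max(.data$auc),
                     best_spec = .data$spec[which.max(.data$auc)],
                     .groups = "drop") |>
    dplyr::mutate(call = classify_success(.data$best_auc))
  list(
    per_spec = per_spec,
    per_family = per_family,
    success_rate = mean(per_family$call == "success"),
    semi_success_rate = mean(per_family$best_auc > 0.8),
    caveat = attr(bm, "caveat")
  )
}

#' Subsample an oversized family
#'
#' Families beyond `max_genes` genes are down-sampled uniformly at random
#' without replacement (the treatment applied to very large taxa); smaller
#' families pass through unchanged. Works per family on a multi-family table.
#'
#' @param genes A gene table.
#' @param max_genes Cap on genes per family (default 25000).
#' @param seed Integer seed; the same seed yields the same subset.
#' @return A gene table, ingest order preserved within each family.
#' @export
subsample_large_family <- function(genes, max_genes = 25000L, seed = NULL) {
  check_gene_table(genes)
  if (!is_scalar_number(max_genes) || max_genes < 4) {
    abort_parameter("`max_genes` must be at least 4.")
  }
  with_seed(seed, {
    keep <- unlist(lapply(unique(genes$family), function(fam) {
      idx <- which(genes$family == fam)
      if (length(idx) <= max_genes) idx else sort(sample(idx, max_genes))
    }))
    genes[sort(keep), , drop = FALSE]
  })
}

#' Write a benchmark table as TSV plus a JSON summary
#'
#' TSV columns: `family`, `spec`, `auc`, `success`. The JSON summary holds
#' per-spec medians, success rates and the run parameters.
#'
#' @param bm An `atyp_benchmark`.
#' @param path Output TSV path; summary goes to `<path stem>_summary.json`.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(bm, path) {
  utils::write.table(as.data.frame(bm)[, c("family", "spec", "auc", "success")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- summarize_benchmark(bm)
  json_path <- paste0(sub("\\.tsv$", "", path), "_summary.json")
  jsonlite::write_json(
    list(
      per_spec_median_auc = stats::setNames(as.list(s$per_spec$median_auc),
                                            s$per_spec$spec),
      success_rate = s$success_rate,
      semi_success_rate = s$semi_success_rate,
      params = attr(bm, "params"),
      caveat = s$caveat
    ),
    json_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
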