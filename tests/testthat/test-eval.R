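test_that("injected outlier counts solve m / (n + m) = fraction", {
  mk <- function(n, fam) {
    generate_family(fam, n_genes = n, length_codons = c(10, 12),
                    seed = nchar(fam) + n)
  }
  base19 <- mk(19, "B19")
  pool <- mk(50, "Pool")
  sim <- inject_outliers(base19, pool, fraction = 0.05, seed = 1)
  expect_equal(attr(sim, "n_injected"), 1L)
  expect_equal(sum(sim$label == "injected"), 1L)
  expect_equal(mean(sim$label == "injected"), 1 / 20)

  base95 <- mk(95, "B95")
  sim95 <- inject_outliers(base95, pool, fraction = 0.05, seed = 1)
  expect_equal(attr(sim95, "n_injected"), 5L)
  expect_equal(mean(sim95$label == "injected"), 5 / 100)

  # determinism: same seed, same injected set
  sim_a <- inject_outliers(base19, pool, seed = 77)
  sim_b <- inject_outliers(base19, pool, seed = 77)
  expect_equal(sim_a$gene_id, sim_b$gene_id)
  expect_equal(sim_a$seq, sim_b$seq)

  # injected genes always come from another family
  expect_true(all(sim95$source_family[sim95$label == "injected"] != "B95"))
  expect_error(inject_outliers(base19, base19, seed = 1),
               class = "atyp_validation_error")
  expect_error(inject_outliers(base19, pool[0, ], seed = 1),
               class = "atyp_validation_error")
  expect_error(inject_outliers(base95, pool[1:2, ], fraction = 0.5, seed = 1),
               class = "atyp_validation_error")
})

make_ranking <- function(scores, ids = sprintf("g%02d", seq_along(scores))) {
  # higher score = more atypical; signed distance is its negation
  reg <- tibble::tibble(name = "manual", alias = "manual",
                        k = NA_integer_, dim = NA_integer_)
  atypicalr:::new_ranking(ids, -scores, reg, nu = NA_real_, gamma = NA_real_)
}

test_that("AUC equals pair counting on canonical configurations", {
  # all positives above all negatives
  rk <- make_ranking(c(4, 3, 2, 1))
  labels <- stats::setNames(c("injected", "injected", "inherent", "inherent"),
                            rk$gene_id)
  expect_equal(compute_auc(rk, labels)$auc, 1.0)

  # interleaved (+,-,+,-): 3 of 4 pairs correctly ordered
  labels2 <- stats::setNames(c("injected", "inherent", "injected", "inherent"),
                             rk$gene_id)
  expect_equal(compute_auc(rk, labels2)$auc, 0.75)

  expect_error(compute_auc(rk, stats::setNames(rep("inherent", 4), rk$gene_id)),
               class = "atyp_validation_error")
})

test_that("AUC matches the exhaustive pair-counting oracle on all labelings up to n = 8", {
  for (n in 2:8) {
    scores <- rev(seq_len(n))  # distinct, ranking = ids in order
    rk <- make_ranking(scores)
    for (mask in 1:(2^n - 2)) {
      pos <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      labels <- stats::setNames(ifelse(pos, "injected", "inherent"), rk$gene_id)
      ev <- compute_auc(rk, labels)
      expect_equal(ev$auc, auc_pair_oracle(scores, pos), tolerance = 1e-12)
    }
  }
})

test_that("tied signed distances contribute half, matching oracle and pROC", {
  set.seed(31)
  ids <- sprintf("g%02d", 1:10)
  for (i in 1:25) {
    scores <- sample(1:4, 10, replace = TRUE)  # heavy ties
    pos <- seq_len(10) %in% sample.int(10, 3)
    rk <- make_ranking(as.numeric(scores), ids)
    labels <- stats::setNames(ifelse(pos, "injected", "inherent"), ids)
    ev <- compute_auc(rk, labels)
    expect_equal(ev$auc, auc_pair_oracle(scores, pos), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  scores <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  pos <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  rk <- make_ranking(scores, ids)
  labels <- stats::setNames(ifelse(pos, "injected", "inherent"), ids)
  expect_equal(
    compute_auc(rk, labels)$auc,
    as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                   direction = "<"))),
    tolerance = 1e-12
  )
})

test_that("AUC of a tie-free ranking reverses to 1 - AUC", {
  set.seed(32)
  for (i in 1:10) {
    scores <- sample(100, 12)
    pos <- seq_len(12) %in% sample.int(12, 4)
    labels_by_id <- function(rk) {
      stats::setNames(ifelse(pos, "injected", "inherent"),
                      sprintf("g%02d", 1:12))
    }
    a <- compute_auc(make_ranking(scores), labels_by_id())$auc
    b <- compute_auc(make_ranking(-scores), labels_by_id())$auc
    expect_equal(a + b, 1)
  }
})

test_that("the AUC equals the trapezoidal area of its own ROC points", {
  set.seed(33)
  scores <- c(stats::rnorm(20), stats::rnorm(5, 3))
  pos <- c(rep(FALSE, 20), rep(TRUE, 5))
  rk <- make_ranking(scores, sprintf("r%02d", 1:25))
  labels <- stats::setNames(ifelse(pos, "injected", "inherent"), rk$gene_id)
  ev <- compute_auc(rk, labels)
  trap <- sum(diff(ev$roc_points$fpr) *
                (utils::head(ev$roc_points$tpr, -1) + utils::tail(ev$roc_points$tpr, -1)) / 2)
  expect_equal(ev$auc, trap, tolerance = 1e-12)
  expect_equal(ev$roc_points$fpr[1], 0)
  expect_equal(utils::tail(ev$roc_points$tpr, 1), 1)
  # the top 5% called set has max(1, round(0.05 n)) members
  expect_length(ev$called, 1L)
})

test_that("random rankings score 0.5 on average", {
  g <- generate_family("R0", n_genes = 100, length_codons = c(10, 12), seed = 41)
  pool <- generate_family("R1", n_genes = 30, length_codons = c(10, 12), seed = 42)
  sim <- inject_outliers(g, pool, seed = 43)
  aucs <- withr::with_seed(44, vapply(1:200, function(i) {
    compute_auc(random_ranking(sim$gene_id), sim[, c("gene_id", "label")])$auc
  }, numeric(1)))
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-3)
})

test_that("success classification uses strict thresholds", {
  expect_equal(classify_success(0.95), "success")
  expect_equal(classify_success(0.85), "semi_success")
  expect_equal(classify_success(0.80), "none")
  expect_equal(classify_success(0.90), "semi_success")
  expect_equal(classify_success(c(1, 0, 0.5)), c("success", "none", "none"))
  expect_error(classify_success(1.2), class = "atyp_parameter_error")
  expect_error(classify_success(-0.1), class = "atyp_parameter_error")
})

test_that("the family benchmark separates two strongly divergent families", {
  # extreme divergence by construction: disjoint codon supports
  # (AT-rich codons for FamA, GC-rich codons for FamB)
  gc_count <- vapply(strsplit(atypicalr:::CODONS, ""),
                     function(b) sum(b %in% c("G", "C")), integer(1))
  sense <- !(atypicalr:::CODONS %in% c("TAA", "TAG", "TGA"))
  w1 <- stats::setNames(as.numeric(sense & gc_count <= 1), atypicalr:::CODONS)
  w2 <- stats::setNames(as.numeric(sense & gc_count >= 2), atypicalr:::CODONS)
  genes <- dplyr::bind_rows(
    generate_family("FamA", 60, length_codons = c(80, 150), codon_weights = w1 / sum(w1), seed = 53),
    generate_family("FamB", 60, length_codons = c(80, 150), codon_weights = w2 / sum(w2), seed = 54)
  )
  bm <- run_family_benchmark(genes, specs = "tetra", seed = 55)
  expect_equal(nrow(bm), 2L)
  expect_true(all(bm$auc > 0.9))
  expect_true(all(bm$success == "success"))

  # nearest-centroid oracle agrees that the construction is separable
  fam_a <- genes[genes$family == "FamA", ]
  pool <- genes[genes$family == "FamB", ]
  sim <- inject_outliers(fam_a, pool, seed = 56)
  x <- atypicalr:::feature_values(gene_features(sim, "tetra"))
  centroid <- colMeans(x[sim$label == "inherent", ])
  dist_to_centroid <- sqrt(rowSums(sweep(x, 2, centroid)^2))
  expect_gt(auc_pair_oracle(dist_to_centroid, sim$label == "injected"), 0.9)

  expect_error(run_family_benchmark(fam_a), class = "atyp_validation_error")
})

test_that("benchmark summaries aggregate medians and success calls by definition", {
  genes <- generate_benchmark(3, divergence = 1, per_family_n = 30,
                              length_codons = c(50, 80), seed = 57)
  bm <- run_family_benchmark(genes, specs = c("di", "gc_content"), seed = 58)
  s <- summarize_benchmark(bm)
  for (sp in unique(bm$spec)) {
    expect_equal(s$per_spec$median_auc[s$per_spec$spec == sp],
                 stats::median(bm$auc[bm$spec == sp], na.rm = TRUE))
  }
  best <- tapply(bm$auc, bm$family, max, na.rm = TRUE)
  expect_equal(s$per_family$best_auc[match(names(best), s$per_family$family)],
               as.numeric(best))
  expect_equal(s$success_rate, mean(best > 0.9))

  # a family below the size threshold is reported as a missing cell, not fatal
  with_tiny <- dplyr::bind_rows(
    genes, generate_family("Tiny", 4, c(50, 60), seed = 60)[1:3, ]
  )
  bm2 <- run_family_benchmark(with_tiny, specs = "di", seed = 61)
  expect_true(any(!is.na(bm2$error)))
  expect_true(all(is.na(bm2$auc[bm2$family == "Tiny"])))
})

test_that("oversized families are down-sampled deterministically", {
  g <- generate_family("Big", n_genes = 30, length_codons = c(10, 12), seed = 71)
  expect_equal(subsample_large_family(g, max_genes = 100, seed = 1), g)
  s10 <- subsample_large_family(g, max_genes = 10, seed = 2)
  expect_equal(nrow(s10), 10L)
  expect_true(all(s10$gene_id %in% g$gene_id))
  expect_equal(subsample_large_family(g, max_genes = 10, seed = 2), s10)
  expect_error(subsample_large_family(g, max_genes = 2),
               class = "atyp_parameter_error")
})
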