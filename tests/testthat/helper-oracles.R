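# Shared test oracles, all independent of the code paths they check.

# All permutations of 1..n (recursive enumeration).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Spearman's rho by the classical displacement formula (valid for
# permutations, i.e. no ties): 1 - 6 * sum(d^2) / (n (n^2 - 1)).
spearman_formula <- function(a, b) {
  n <- length(a)
  1 - 6 * sum((a - b)^2) / (n * (n^2 - 1))
}

# AUC by brute-force pair counting over positive-negative pairs, ties 1/2.
# `score` is atypicality (higher = ranked more atypical), `pos` logical.
auc_pair_oracle <- function(score, pos) {
  sp <- score[pos]
  sn <- score[!pos]
  tot <- 0
  for (p in sp) {
    for (q in sn) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(sp) * length(sn))
}

# Parzen (Gaussian kernel) density estimate at each row of x; same kernel
# width parameterization as the SVM: exp(-gamma * ||xi - xj||^2).
parzen_density <- function(x, gamma) {
  d2 <- as.matrix(stats::dist(x))^2
  rowSums(exp(-gamma * d2))
}

# Build a standardized feature table directly from a numeric matrix, for
# tests that need exact control of the geometry fed to the SVM.
features_from_matrix <- function(x, standardized = TRUE) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  tbl <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(x)))),
    tibble::as_tibble(as.data.frame(x))
  )
  reg <- tibble::tibble(name = "synthetic", alias = "synthetic",
                        k = NA_integer_, dim = ncol(x))
  atypicalr:::new_features(tbl, reg, standardized = standardized,
                           excluded = tibble::tibble(gene_id = character(0),
                                                     reason = character(0)))
}

# A sequence of given length with an exact number of G/C characters.
seq_with_gc <- function(len, n_gc) {
  paste0(strrep("G", n_gc), strrep("A", len - n_gc))
}

write_temp_fasta <- function(genes, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0(unique(genes$family)[1], ".fasta"))
  write_gene_fasta(genes, path)
  path
}
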