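# Reproducible end-to-end runs: each command wires the modules together and
# writes a machine-readable manifest (parameters, seed, package version,
# input checksums) next to its primary outputs.

write_manifest <- function(out_dir, command, params, inputs = character(0)) {
  checksums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    command = command,
    package = "atypicalr",
    version = as.character(utils::packageVersion("atypicalr")),
    params = params,
    input_md5 = checksums
  )
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Rank the genes of one family end to end
#'
#' Reads a family FASTA, reduces redundancy at the given identity level,
#' extracts and standardizes the chosen feature set, ranks with the one-class
#' SVM (or the GC baseline for `spec = "gc_content"`), and writes
#' `ranking.tsv` plus a JSON manifest to `out_dir`.
#'
#' @param fasta Path to the family FASTA (>= 4 genes after clustering).
#' @param out_dir Output directory (created if missing).
#' @param family Family label; defaults to the FASTA file name.
#' @param spec Feature-set name (default `"tetra"`, the best-performing
#'   signature).
#' @param nu,gamma SVM parameters (defaults nu = 0.2, gamma = (2D)^-1).
#' @param identity Redundancy-reduction identity level (default 0.95).
#' @param representatives Optional externally computed representative ids
#'   (skips the built-in clusterer).
#' @param gc_regression Experimental GC-residualized feature variant (see
#'   [gene_features()]).
#' @return The `atyp_ranking`, invisibly.
#' @export
run_rank <- function(fasta, out_dir, family = NULL, spec = "tetra",
                     nu = 0.2, gamma = "rule_of_thumb", identity = 0.95,
                     representatives = NULL, gc_regression = FALSE) {
  genes <- read_family_fasta(fasta, family = family)
  genes <- reduce_redundancy(genes, identity = identity,
                             representatives = representatives)
  check_family_size(genes, what = "family after redundancy reduction")
  rk <- if (canonical_spec(spec)$name == "gc_content") {
    gc_baseline_rank(genes)
  } else {
    rank_genes(standardize_features(gene_features(genes, spec,
                                                  gc_regression = gc_regression)),
               nu = nu, gamma = gamma)
  }
  ensure_out_dir(out_dir)
  write_ranking_tsv(rk, file.path(out_dir, "ranking.tsv"),
                    extra = list(identity = identity,
                                 n_input = nrow(cluster_table(genes)),
                                 n_representatives = nrow(genes)))
  write_manifest(out_dir, "rank",
                 params = list(fasta = fasta, family = family %||% NA,
                               spec = canonical_spec(spec)$name, nu = nu,
                               gamma = if (is.character(gamma)) gamma else gamma,
                               identity = identity),
                 inputs = fasta)
  invisible(rk)
}

#' Run the ranking-stability sweep end to end
#'
#' Reads a family FASTA, builds the standardized feature table and sweeps
#' (gamma, nu), writing `stability.tsv` (`gamma`, `nu`, `rho`) and a
#' manifest. Defaults are the full printed grids (10 gammas x 1,000 nus);
#' pass reduced grids for quick looks.
#'
#' @inheritParams run_rank
#' @param gammas,nus Optional reduced grids (see [stability_sweep()]).
#' @return The `atyp_stability` table, invisibly.
#' @export
run_sweep <- function(fasta, out_dir, family = NULL, spec = "tetra",
                      identity = 0.95, gammas = NULL, nus = NULL) {
  genes <- read_family_fasta(fasta, family = family)
  genes <- reduce_redundancy(genes, identity = identity)
  check_family_size(genes, what = "family after redundancy reduction")
  fm <- standardize_features(gene_features(genes, spec))
  prof <- stability_sweep(fm, gammas = gammas, nus = nus %||% nu_grid())
  ensure_out_dir(out_dir)
  write_stability_tsv(prof, file.path(out_dir, "stability.tsv"))
  write_manifest(out_dir, "sweep",
                 params = list(fasta = fasta, spec = canonical_spec(spec)$name,
                               identity = identity,
                               n_gammas = length(unique(prof$gamma)),
                               n_nus = length(unique(prof$nu))),
                 inputs = fasta)
  invisible(prof)
}

#' Run the simulated-outlier benchmark end to end
#'
#' Either over a directory of family FASTA files (`fasta_dir`, one family per
#' file) or over a generated synthetic benchmark. Writes `benchmark.tsv`,
#' `benchmark_summary.json` and a manifest.
#'
#' @param out_dir Output directory.
#' @param fasta_dir Directory of `.fasta`/`.fa` files, one family each; if
#'   `NULL`, a synthetic benchmark is generated.
#' @param specs Feature sets to evaluate (default `"tetra"`).
#' @param nu,gamma,fraction,seed As in [run_family_benchmark()].
#' @param n_families,divergence,per_family_n,gc_matched Synthetic-benchmark
#'   parameters (used when `fasta_dir` is `NULL`); see
#'   [generate_benchmark()].
#' @param identity Redundancy-reduction level applied to real input families.
#' @return The `atyp_benchmark`, invisibly.
#' @export
run_benchmark <- function(out_dir, fasta_dir = NULL, specs = "tetra",
                          nu = 0.2, gamma = "rule_of_thumb", fraction = 0.05,
                          seed = 1L, n_families = 10L, divergence = 1,
                          per_family_n = 200L, gc_matched = FALSE,
                          identity = 0.95) {
  if (!is.null(fasta_dir)) {
    files <- list.files(fasta_dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    if (length(files) < 2L) {
      abort_io(paste0("`fasta_dir` must hold at least 2 FASTA files: ", fasta_dir))
    }
    genes <- dplyr::bind_rows(lapply(files, read_family_fasta))
    genes <- reduce_redundancy(genes, identity = identity)
    inputs <- files
  } else {
    genes <- generate_benchmark(n_families, divergence,
                                per_family_n = per_family_n,
                                gc_matched = gc_matched, seed = seed)
    inputs <- character(0)
  }
  bm <- run_family_benchmark(genes, specs = specs, nu = nu, gamma = gamma,
                             fraction = fraction, seed = seed)
  ensure_out_dir(out_dir)
  write_benchmark_tsv(bm, file.path(out_dir, "benchmark.tsv"))
  write_manifest(out_dir, "benchmark",
                 params = list(fasta_dir = fasta_dir %||% NA,
                               specs = specs, nu = nu,
                               gamma = if (is.character(gamma)) gamma else gamma,
                               fraction = fraction, seed = seed,
                               n_families = if (is.null(fasta_dir)) n_families else NA,
                               divergence = if (is.null(fasta_dir)) divergence else NA,
                               per_family_n = if (is.null(fasta_dir)) per_family_n else NA,
                               gc_matched = if (is.null(fasta_dir)) gc_matched else NA),
                 inputs = inputs)
  invisible(bm)
}

#' Sliding-window segment ranking of a single genome
#'
#' Segments the first record of `fasta` with a sliding window and ranks the
#' segments either against themselves (`background = "self"`) or against a
#' family FASTA (family-level statistics). Writes `segments.tsv` and a
#' manifest.
#'
#' @inheritParams run_rank
#' @param window,step Window and step sizes in nt.
#' @param background `"self"` or a path to a family FASTA.
#' @return The `atyp_ranking` over segments, invisibly.
#' @export
run_windows <- function(fasta, out_dir, window, step, background = "self",
                        spec = "tetra", nu = 0.2, gamma = "rule_of_thumb") {
  genome <- read_family_fasta(fasta, family = "genome")
  segs <- sliding_window(genome$seq[1], window = window, step = step,
                         source_genome = genome$gene_id[1])
  bg <- if (identical(background, "self")) "self" else read_family_fasta(background)
  rk <- rank_segments(segs, background = bg, spec = spec, nu = nu, gamma = gamma)
  ensure_out_dir(out_dir)
  write_ranking_tsv(rk, file.path(out_dir, "segments.tsv"),
                    extra = list(window = window, step = step,
                                 background = if (identical(background, "self")) "self" else background))
  write_manifest(out_dir, "windows",
                 params = list(fasta = fasta, window = window, step = step,
                               background = if (identical(background, "self")) "self" else background,
                               spec = canonical_spec(spec)$name, nu = nu,
                               gamma = if (is.character(gamma)) gamma else gamma),
                 inputs = c(fasta, if (!identical(background, "self")) background))
  invisible(rk)
}

#' Build and write a simulated dataset with injected outliers
#'
#' Reads a base-family FASTA and a pool FASTA (genes from other families),
#' injects outliers at the given fraction, and writes the amended family as
#' FASTA plus a `gene_id<TAB>label` TSV and a manifest.
#'
#' @inheritParams run_rank
#' @param pool_fasta FASTA of candidate outlier genes.
#' @param fraction Injected outlier fraction (default 0.05).
#' @param seed Integer seed for the uniform draw.
#' @param pool_family Family label for the pool file (defaults to its file
#'   name).
#' @return The amended gene table, invisibly.
#' @export
run_simulate <- function(fasta, pool_fasta, out_dir, fraction = 0.05,
                         seed = 1L, family = NULL, pool_family = NULL) {
  base <- read_family_fasta(fasta, family = family)
  pool <- read_family_fasta(pool_fasta, family = pool_family)
  sim <- inject_outliers(base, pool, fraction = fraction, seed = seed)
  ensure_out_dir(out_dir)
  write_gene_fasta(sim, file.path(out_dir, "simulated.fasta"))
  utils::write.table(as.data.frame(sim)[, c("gene_id", "label")],
                     file.path(out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "simulate",
                 params = list(fasta = fasta, pool_fasta = pool_fasta,
                               fraction = fraction, seed = seed,
                               n_injected = attr(sim, "n_injected")),
                 inputs = c(fasta, pool_fasta))
  invisible(sim)
}

#' Generate and write a synthetic benchmark to disk
#'
#' One FASTA per family plus a `gene_id<TAB>family` manifest TSV and a config
#' manifest, so a benchmark can be re-run from its files alone.
#'
#' @inheritParams run_benchmark
#' @param length_codons As in [generate_family()].
#' @return The generated gene table, invisibly.
#' @export
run_generate <- function(out_dir, n_families = 10L, divergence = 1,
                         per_family_n = 200L, length_codons = c(100L, 300L),
                         gc_matched = FALSE, seed = 1L) {
  genes <- generate_benchmark(n_families, divergence,
                              per_family_n = per_family_n,
                              length_codons = length_codons,
                              gc_matched = gc_matched, seed = seed)
  ensure_out_dir(out_dir)
  for (fam in unique(genes$family)) {
    write_gene_fasta(genes[genes$family == fam, ],
                     file.path(out_dir, paste0(fam, ".fasta")))
  }
  utils::write.table(genes[, c("gene_id", "family")],
                     file.path(out_dir, "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_manifest(out_dir, "generate",
                 params = list(n_families = n_families, divergence = divergence,
                               per_family_n = per_family_n,
                               length_codons = length_codons,
                               gc_matched = gc_matched, seed = seed))
  invisible(genes)
}
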