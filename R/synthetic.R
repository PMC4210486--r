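# Synthetic virus families with controlled compositional signatures. Genes
# are i.i.d. draws from a family-specific codon source distribution: a
# start codon, L internal sense codons, one terminal stop. A codon-level
# source (rather than a nucleotide Markov chain) makes codon-usage,
# amino-acid, position-specific and oligonucleotide signatures all inherit
# the family structure from one parameter set.

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

#' Random codon source distribution
#'
#' Dirichlet(alpha) weights over the 61 sense codons; stop codons carry zero
#' weight (stops are terminal-only in generated genes).
#'
#' @param alpha Dirichlet concentration (default 1, i.e. uniform over the
#'   simplex).
#' @param seed Optional integer seed.
#' @return Named numeric vector over all 64 codons summing to 1.
#' @export
random_codon_weights <- function(alpha = 1, seed = NULL) {
  with_seed(seed, {
    g <- stats::rgamma(length(SENSE_CODONS), shape = alpha)
    w <- stats::setNames(numeric(64L), CODONS)
    w[SENSE_CODONS] <- g / sum(g)
    w
  })
}

# Family-unique distribution at matched GC: permute the base weights within
# groups of sense codons having equal G+C count, so the expected GC content
# is unchanged while codon (and hence word) usage diverges.
gc_permuted_weights <- function(base) {
  gc_count <- vapply(strsplit(SENSE_CODONS, ""), function(b) sum(b %in% c("G", "C")),
                     integer(1))
  w <- base
  for (g in unique(gc_count)) {
    grp <- SENSE_CODONS[gc_count == g]
    w[grp] <- base[sample(grp)]
  }
  w
}

check_codon_weights <- function(codon_weights) {
  if (!is.numeric(codon_weights) || is.null(names(codon_weights)) ||
      !setequal(names(codon_weights), CODONS)) {
    abort_parameter("`codon_weights` must be a numeric vector named by all 64 codons.")
  }
  if (any(codon_weights < 0) || anyNA(codon_weights)) {
    abort_parameter("`codon_weights` must be non-negative.")
  }
  w <- codon_weights[CODONS]
  w[STOP_CODONS] <- 0  # stops are terminal-only
  if (sum(w) <= 0) {
    abort_parameter("`codon_weights` must put positive mass on sense codons.")
  }
  w / sum(w)
}

#' Generate one synthetic virus family
#'
#' Each gene is `ATG` + L internal codons drawn i.i.d. from `codon_weights`
#' (L uniform over `length_codons`) + one stop codon (uniform over TAA, TAG,
#' TGA). Internal stop weights are forced to zero, so every gene is a clean
#' in-frame CDS.
#'
#' @param family_id Family label; also prefixes gene ids.
#' @param n_genes Number of genes (>= 4).
#' @param length_codons Integer pair `(min, max)` of internal codon counts;
#'   default `c(100, 300)` (300-900 nt internal, a typical viral CDS scale).
#' @param codon_weights Codon source distribution (see
#'   [random_codon_weights()]); `NULL` draws a fresh random one.
#' @param seed Optional integer seed; identical seeds give identical
#'   families.
#' @return A gene table (see [gene_table()]).
#' @examples
#' generate_family("Toy", n_genes = 5, length_codons = c(10, 10), seed = 1)
#' @export
generate_family <- function(family_id, n_genes, length_codons = c(100L, 300L),
                            codon_weights = NULL, seed = NULL) {
  if (!is_scalar_number(n_genes) || n_genes < 4) {
    abort_parameter("`n_genes` must be an integer >= 4.")
  }
  if (!is.numeric(length_codons) || length(length_codons) != 2L ||
      any(length_codons < 1) || length_codons[1] > length_codons[2]) {
    abort_parameter("`length_codons` must be an increasing pair of positive integers.")
  }
  with_seed(seed, {
    w <- if (is.null(codon_weights)) random_codon_weights() else check_codon_weights(codon_weights)
    n_genes <- as.integer(n_genes)
    lens <- sample.int(length_codons[2] - length_codons[1] + 1L, n_genes,
                       replace = TRUE) + as.integer(length_codons[1]) - 1L
    internal <- sample(SENSE_CODONS, sum(lens), replace = TRUE,
                       prob = w[SENSE_CODONS])
    stops <- sample(STOP_CODONS, n_genes, replace = TRUE)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs <- vapply(seq_len(n_genes), function(i) {
      paste0("ATG", paste0(internal[starts[i]:ends[i]], collapse = ""), stops[i])
    }, character(1))
    gene_table(
      gene_id = sprintf("%s_g%04d", family_id, seq_len(n_genes)),
      family = family_id,
      seq = seqs
    )
  })
}

#' Generate a multi-family synthetic benchmark
#'
#' All families share a common base codon distribution; each family's own
#' distribution is the mixture `(1 - d) * base + d * unique`, where `unique`
#' is family-specific and `d` is the divergence handle. At `d = 0` all
#' families are statistically identical (no signal); at `d = 1` they are
#' maximally distinct.
#'
#' With `gc_matched = TRUE` each family's unique distribution is a
#' permutation of the base weights within groups of codons of equal G+C
#' count: expected GC content is then identical across families while codon
#' and word usage still diverge, which isolates signature information beyond
#' GC.
#'
#' @param n_families Number of families (>= 2).
#' @param divergence Divergence handle d in \\[0, 1\\].
#' @param per_family_n Genes per family (default 200).
#' @param length_codons As in [generate_family()].
#' @param gc_matched Hold expected GC constant across families (default
#'   FALSE).
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   output.
#' @return A gene table holding all families.
#' @export
generate_benchmark <- function(n_families, divergence, per_family_n = 200L,
                               length_codons = c(100L, 300L),
                               gc_matched = FALSE, seed = NULL) {
  if (!is_scalar_number(n_families) || n_families < 2) {
    abort_parameter("`n_families` must be an integer >= 2.")
  }
  if (!is_scalar_number(divergence) || divergence < 0 || divergence > 1) {
    abort_parameter("`divergence` must lie in [0, 1].")
  }
  with_seed(seed, {
    base <- random_codon_weights()
    fams <- lapply(seq_len(as.integer(n_families)), function(i) {
      unique_w <- if (gc_matched) gc_permuted_weights(base) else random_codon_weights()
      w <- (1 - divergence) * base + divergence * unique_w
      generate_family(sprintf("Fam%02d", i), per_family_n,
                      length_codons = length_codons, codon_weights = w)
    })
    dplyr::bind_rows(fams)
  })
}
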