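# Compositional signatures of coding sequences: oligonucleotide word
# frequencies (k = 1..4), codon usage, relative (synonymous-family) codon
# usage, amino-acid frequencies, position-specific nucleotide frequencies and
# GC content. All counting skips windows/codons containing non-ACGT letters.

CODONS <- sort(apply(
  expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"), c("A", "C", "G", "T")),
  1, paste0, collapse = ""
))
AMINO_ACIDS <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
BASES <- c("A", "C", "G", "T")

#' The feature-set registry
#'
#' The nine compositional signatures and their dimensionalities: word
#' frequencies for k = 1..4 (4, 16, 64, 256 dimensions), codon usage (64),
#' relative codon usage (64), amino-acid frequencies (20), position-specific
#' nucleotide frequencies (12) and GC content (1).
#'
#' @return A tibble with columns `name`, `alias`, `k`, `dim`.
#' @export
feature_specs <- function() {
  tibble::tibble(
    name = c("mono", "di", "tri", "tetra", "codon_usage",
             "relative_codon_usage", "amino_acid", "position_nt", "gc_content"),
    alias = c("mono", "di", "tri", "tetra", "codon", "relcodon", "aa", "posnt", "gc"),
    k = c(1L, 2L, 3L, 4L, NA_integer_, NA_integer_, NA_integer_, NA_integer_, NA_integer_),
    dim = c(4L, 16L, 64L, 256L, 64L, 64L, 20L, 12L, 1L)
  )
}

# Internal: resolve a user-supplied spec name or alias to the canonical name.
canonical_spec <- function(spec) {
  reg <- feature_specs()
  if (!is.character(spec) || length(spec) != 1L) {
    abort_parameter("`spec` must be a single feature-set name.")
  }
  hit <- which(reg$name == spec | reg$alias == spec)
  if (length(hit) != 1L) {
    abort_parameter(paste0(
      "Unknown feature set '", spec, "'. Available: ",
      paste(reg$name, collapse = ", ")
    ))
  }
  reg[hit, , drop = FALSE]
}

#' Dimensionality of a feature set
#'
#' @param spec Feature-set name or alias (see [feature_specs()]).
#' @return Integer dimension D.
#' @export
feature_dim <- function(spec) {
  canonical_spec(spec)$dim
}

# ---- per-sequence operations -------------------------------------------------

#' Oligonucleotide word frequencies of one sequence
#'
#' Counts overlapping k-mers over the ACGT-only windows of `seq` and divides
#' by the number of valid windows. Words are in lexicographic order
#' (AAA... < ... < TTT...).
#'
#' @param seq Nucleotide string.
#' @param k Word length, 1..4.
#' @return Named numeric vector of length `4^k` summing to 1.
#' @examples
#' oligo_freqs("ACGT", k = 1)
#' @export
oligo_freqs <- function(seq, k) {
  if (!is_scalar_number(k) || !(k %in% 1:4)) {
    abort_parameter("`k` must be one of 1, 2, 3, 4.")
  }
  single_row(feat_oligo(as_dna(seq), as.integer(k)), seq)
}

#' GC content of one sequence
#'
#' The proportion of C and G among the ACGT characters; other characters are
#' excluded from both numerator and denominator.
#'
#' @param seq Nucleotide string with at least one ACGT character.
#' @return A fraction in \\[0, 1\\].
#' @examples
#' gc_content("ACGT")
#' @export
gc_content <- function(seq) {
  unname(single_row(feat_gc(as_dna(seq)), seq))
}

#' Codon usage of one sequence
#'
#' Frequencies of the 64 codons among the valid (ACGT-only) codons read in
#' frame 0. A trailing partial codon is dropped with a warning.
#'
#' @param seq Nucleotide string of length >= 3.
#' @return Named numeric vector of length 64 summing to 1 (lexicographic
#'   codon order).
#' @examples
#' codon_usage("ATGAAATAA")
#' @export
codon_usage <- function(seq) {
  single_row(feat_codon_usage(as_dna(seq)), seq)
}

#' Relative codon usage of one sequence
#'
#' Codon frequencies normalized within each synonymous-codon family of the
#' standard genetic code (stop codons form their own family). A family with
#' zero observed codons is imputed uniform 1/|family| so rows stay comparable.
#'
#' @inheritParams codon_usage
#' @param genetic_code NCBI genetic code table id (default "1", the standard
#'   code).
#' @return Named numeric vector of length 64; each synonymous family sums
#'   to 1.
#' @examples
#' relative_codon_usage("AAAAAG")
#' @export
relative_codon_usage <- function(seq, genetic_code = "1") {
  single_row(feat_relative_codon_usage(as_dna(seq), genetic_code), seq)
}

#' Amino-acid frequencies of one sequence
#'
#' Translates frame-0 codons with the (standard, by default) genetic code and
#' returns frequencies over the 20 amino acids in alphabetical one-letter
#' order. Stop codons are excluded.
#'
#' @inheritParams relative_codon_usage
#' @return Named numeric vector of length 20 summing to 1.
#' @examples
#' amino_acid_freqs("ATGAAATAA")
#' @export
amino_acid_freqs <- function(seq, genetic_code = "1") {
  single_row(feat_amino_acid(as_dna(seq), genetic_code), seq)
}

#' Position-specific nucleotide frequencies of one sequence
#'
#' For each codon position p in 1..3, the frequency of A, C, G, T at that
#' position over the valid codons; each position-triplet of four entries
#' sums to 1.
#'
#' @inheritParams codon_usage
#' @return Named numeric vector of length 12 (`p1_A` ... `p3_T`).
#' @examples
#' position_nt_freqs("ATGGTA")
#' @export
position_nt_freqs <- function(seq) {
  single_row(feat_position_nt(as_dna(seq)), seq)
}

# ---- vectorized internals ----------------------------------------------------

as_dna <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  if (any(!nzchar(seqs)) || anyNA(seqs)) {
    abort_validation("Sequences must be non-empty.")
  }
  tryCatch(
    Biostrings::DNAStringSet(seqs),
    error = function(e) abort_validation(paste0(
      "Sequences contain characters outside the IUPAC DNA alphabet: ",
      conditionMessage(e)
    ))
  )
}

single_row <- function(core, seq) {
  if (!core$encodable[1L]) {
    abort_unencodable(paste0("Sequence is unencodable for this feature set: ",
                             core$reason[1L]))
  }
  core$values[1L, ]
}

feat_oligo <- function(set, k) {
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  tot <- rowSums(counts)
  vals <- counts / ifelse(tot > 0, tot, 1)
  list(values = vals, encodable = tot > 0,
       reason = ifelse(tot > 0, "", sprintf("no valid %d-mer window", k)))
}

feat_gc <- function(set) {
  lf <- Biostrings::letterFrequency(set, letters = c("A", "C", "G", "T"))
  tot <- rowSums(lf)
  gc <- (lf[, "C"] + lf[, "G"]) / ifelse(tot > 0, tot, 1)
  vals <- matrix(gc, ncol = 1, dimnames = list(NULL, "GC"))
  list(values = vals, encodable = tot > 0,
       reason = ifelse(tot > 0, "", "no ACGT characters"))
}

# Frame-0 codon counts; trailing partial codons are silently absent from the
# window enumeration, but we warn once naming the affected genes.
codon_counts <- function(set, warn_partial = TRUE) {
  if (any(Biostrings::width(set) < 3L)) {
    # handled downstream as unencodable (zero valid codons)
  }
  partial <- Biostrings::width(set) %% 3L != 0L
  if (warn_partial && any(partial)) {
    ids <- names(set) %||% as.character(which(partial))
    warning(sprintf(
      "%d sequence(s) have length not divisible by 3; trailing partial codon dropped (e.g. %s).",
      sum(partial), paste(utils::head(ids[partial], 3L), collapse = ", ")
    ), call. = FALSE)
  }
  ok <- Biostrings::width(set) >= 3L
  counts <- matrix(0L, nrow = length(set), ncol = 64L,
                   dimnames = list(NULL, CODONS))
  if (any(ok)) {
    counts[ok, ] <- Biostrings::oligonucleotideFrequency(set[ok], width = 3L, step = 3L)
  }
  counts
}

feat_codon_usage <- function(set) {
  counts <- codon_counts(set)
  tot <- rowSums(counts)
  vals <- counts / ifelse(tot > 0, tot, 1)
  list(values = vals, encodable = tot > 0,
       reason = ifelse(tot > 0, "", "no valid codon"))
}

codon_families <- function(genetic_code = "1") {
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  aa <- unname(code[CODONS])
  split(seq_along(CODONS), aa)
}

feat_relative_codon_usage <- function(set, genetic_code = "1") {
  counts <- codon_counts(set)
  tot <- rowSums(counts)
  fams <- codon_families(genetic_code)
  vals <- matrix(0, nrow = nrow(counts), ncol = 64L,
                 dimnames = list(NULL, CODONS))
  imputed <- 0L
  for (fam in fams) {
    sub <- counts[, fam, drop = FALSE]
    fam_tot <- rowSums(sub)
    zero <- fam_tot == 0
    vals[, fam] <- sub / ifelse(fam_tot > 0, fam_tot, 1)
    if (any(zero)) {
      vals[zero, fam] <- 1 / length(fam)
      imputed <- imputed + sum(zero)
    }
  }
  list(values = vals, encodable = tot > 0,
       reason = ifelse(tot > 0, "", "no valid codon"),
       imputed_families = imputed)
}

feat_amino_acid <- function(set, genetic_code = "1") {
  counts <- codon_counts(set)
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  aa <- unname(code[CODONS])
  ind <- outer(aa, AMINO_ACIDS, "==") * 1  # 64 x 20, stops map nowhere
  aa_counts <- counts %*% ind
  colnames(aa_counts) <- paste0("aa_", AMINO_ACIDS)
  tot <- rowSums(aa_counts)
  vals <- aa_counts / ifelse(tot > 0, tot, 1)
  list(values = vals, encodable = tot > 0,
       reason = ifelse(tot > 0, "", "no sense codon"))
}

feat_position_nt <- function(set) {
  counts <- codon_counts(set)
  tot <- rowSums(counts)
  cols <- as.vector(outer(BASES, 1:3, function(b, p) paste0("p", p, "_", b)))
  ind <- matrix(0, nrow = 64L, ncol = 12L, dimnames = list(CODONS, cols))
  for (p in 1:3) {
    base_at_p <- substring(CODONS, p, p)
    for (b in BASES) {
      ind[base_at_p == b, paste0("p", p, "_", b)] <- 1
    }
  }
  vals <- (counts %*% ind) / ifelse(tot > 0, tot, 1)
  list(values = vals, encodable = tot > 0,
       reason = ifelse(tot > 0, "", "no valid codon"))
}

feature_core <- function(set, spec_name, genetic_code = "1") {
  switch(spec_name,
    mono = feat_oligo(set, 1L),
    di = feat_oligo(set, 2L),
    tri = feat_oligo(set, 3L),
    tetra = feat_oligo(set, 4L),
    codon_usage = feat_codon_usage(set),
    relative_codon_usage = feat_relative_codon_usage(set, genetic_code),
    amino_acid = feat_amino_acid(set, genetic_code),
    position_nt = feat_position_nt(set),
    gc_content = feat_gc(set),
    abort_parameter(paste0("Unknown feature set '", spec_name, "'."))
  )
}

# ---- feature tables ----------------------------------------------------------

#' Build the genes-by-dimensions feature table for a family
#'
#' One row per encodable gene, in dataset (ingest) order; unencodable genes
#' are excluded and reported in the `excluded` attribute. Frequency rows sum
#' to 1 over their normalization group.
#'
#' @param genes A gene table with at least `gene_id` and `seq` columns.
#' @param spec Feature-set name or alias (see [feature_specs()]).
#' @param genetic_code NCBI genetic code table id (default "1").
#' @param min_rows Minimum number of encodable genes required (default 4, the
#'   analyzable-family threshold).
#' @param gc_regression Experimental: replace each feature column by the
#'   residuals of its least-squares regression on the genes' GC content
#'   before any standardization. Not part of the default feature sets; kept
#'   as an explicitly flagged option for exploring GC-bias removal.
#' @return A tibble of class `atyp_features`: column `gene_id` followed by D
#'   feature columns. Attributes: `spec` (one-row registry entry),
#'   `standardized` (FALSE), `excluded` (tibble `gene_id`, `reason`).
#' @examples
#' g <- generate_family("Toy", n_genes = 5, length_codons = c(10, 20), seed = 1)
#' gene_features(g, "mono")
#' @export
gene_features <- function(genes, spec, genetic_code = "1", min_rows = 4L,
                          gc_regression = FALSE) {
  check_gene_table(genes, require_family = FALSE)
  reg <- canonical_spec(spec)
  set <- as_dna(genes$seq)
  names(set) <- genes$gene_id
  core <- feature_core(set, reg$name, genetic_code)

  excluded <- tibble::tibble(
    gene_id = genes$gene_id[!core$encodable],
    reason = core$reason[!core$encodable]
  )
  n_ok <- sum(core$encodable)
  if (n_ok < min_rows) {
    abort_validation(paste0(
      "Only ", n_ok, " gene(s) are encodable for feature set '", reg$name,
      "'; at least ", min_rows, " required."
    ))
  }
  vals <- core$values[core$encodable, , drop = FALSE]
  if (isTRUE(gc_regression) && reg$name != "gc_content") {
    gc_core <- feat_gc(set)
    gc <- gc_core$values[core$encodable, 1L]
    vals <- apply(vals, 2, function(col) stats::lsfit(gc, col)$residuals)
  }
  out <- tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes$gene_id[core$encodable]), out
  )
  ft <- new_features(out, reg, standardized = FALSE, excluded = excluded,
                     imputed = core$imputed_families %||% 0L)
  attr(ft, "gc_regressed") <- isTRUE(gc_regression)
  ft
}

new_features <- function(tbl, reg, standardized, excluded,
                         center = NULL, scale = NULL, imputed = 0L) {
  structure(
    tbl,
    class = c("atyp_features", class(tibble::tibble())),
    spec = reg,
    standardized = standardized,
    excluded = excluded,
    center = center,
    scale = scale,
    imputed_families = imputed
  )
}

feature_values <- function(fm) {
  as.matrix(fm[, setdiff(names(fm), "gene_id"), drop = FALSE])
}

#' Standardize a feature table to zero mean and unit variance
#'
#' Column-wise z-scores using the population standard deviation (so results
#' are bit-reproducible across implementations); columns with zero variance
#' map to all-zeros. The data is standardized before it is supplied to the
#' SVM.
#'
#' @param fm A feature table from [gene_features()], at least 2 rows.
#' @return The standardized feature table; attributes `center` and `scale`
#'   record the transformation so new points (e.g. genome segments) can be
#'   projected onto the same scale.
#' @export
standardize_features <- function(fm) {
  if (!inherits(fm, "atyp_features")) {
    abort_validation("`fm` must be a feature table from gene_features().")
  }
  x <- feature_values(fm)
  if (nrow(x) < 2L) {
    abort_validation("Standardization requires at least 2 rows.")
  }
  ctr <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, ctr)^2))  # population sd
  z <- scale_with(x, ctr, sdv)
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = fm$gene_id),
    tibble::as_tibble(as.data.frame(z, check.names = FALSE))
  )
  new_features(out, attr(fm, "spec"), standardized = TRUE,
               excluded = attr(fm, "excluded"),
               center = ctr, scale = sdv,
               imputed = attr(fm, "imputed_families"))
}

scale_with <- function(x, center, scale) {
  z <- sweep(x, 2, center)
  nz <- scale > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, scale[nz], "/")
  z[, !nz] <- 0
  z
}

#' Write / read a feature table as TSV
#'
#' Header row holds the feature names; the first column is `gene_id`.
#'
#' @param fm A feature table.
#' @param path Output path.
#' @return `path` invisibly (writer); a plain tibble (reader).
#' @export
write_features_tsv <- function(fm, path) {
  utils::write.table(as.data.frame(fm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  if (!file.exists(path)) abort_io(paste0("Cannot read: ", path))
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE,
                                      colClasses = NA, quote = ""))
}
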