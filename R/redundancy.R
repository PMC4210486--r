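#' Reduce sequence redundancy by greedy clustering
#'
#' Collapses near-identical sequences to single representatives before
#' statistics are collected, in the spirit of CD-HIT-style redundancy
#' reduction. The clusterer is a greedy incremental pass: genes are sorted by
#' length descending (ties keep ingest order); each gene joins the first
#' existing cluster whose representative shares at least `identity` of the
#' shorter sequence's k-mers (shared-k-mer containment, `k = 5`), otherwise it
#' founds a new cluster. Representatives are the cluster founders, returned in
#' ingest order.
#'
#' The method being served only needs redundancy reduction, not exact
#' clustering, so a k-mer containment estimate of identity is used instead of
#' alignment. Users with an external CD-HIT run can bypass the built-in
#' clusterer via `representatives`.
#'
#' When `genes` holds several families, clustering is performed within each
#' family independently.
#'
#' @param genes A gene table (see [read_family_fasta()]).
#' @param identity Identity level in (0, 1]; default 0.95.
#' @param k Word size for the k-mer containment estimate (default 5).
#' @param representatives Optional character vector of gene_ids computed by an
#'   external clustering tool; if given, the built-in clusterer is skipped and
#'   the table is simply filtered to these ids.
#' @return A gene table of cluster representatives (subset of the input rows,
#'   ingest order preserved), with a `clusters` attribute: a tibble
#'   `gene_id`, `representative_id` covering every input gene.
#' @examples
#' g <- gene_table(c("a", "b", "c"),
#'                 "Toyviridae",
#'                 c("ATGAAACCCGGGTTTAAACCC", "ATGAAACCCGGGTTTAAACCC", "TTTTTTTTTTGGGGGGGGGG"))
#' reduce_redundancy(g, identity = 0.95)
#' @export
reduce_redundancy <- function(genes, identity = 0.95, k = 5L, representatives = NULL) {
  check_gene_table(genes, require_family = FALSE)
  if (!is_scalar_number(identity) || identity <= 0 || identity > 1) {
    abort_parameter("`identity` must be a single number in (0, 1].")
  }
  if (!is.null(representatives)) {
    keep <- genes$gene_id %in% representatives
    unknown <- setdiff(representatives, genes$gene_id)
    if (length(unknown) > 0L) {
      abort_validation(paste0(
        "Unknown representative gene_id(s): ", paste(unknown, collapse = ", ")
      ))
    }
    out <- genes[keep, , drop = FALSE]
    attr(out, "clusters") <- tibble::tibble(
      gene_id = genes$gene_id,
      representative_id = ifelse(keep, genes$gene_id, NA_character_)
    )
    return(out)
  }

  groups <- if ("family" %in% names(genes)) genes$family else rep("all", nrow(genes))
  rep_of <- character(nrow(genes))
  names(rep_of) <- genes$gene_id

  for (fam in unique(groups)) {
    idx <- which(groups == fam)
    sub <- genes[idx, , drop = FALSE]
    rep_of[sub$gene_id] <- cluster_greedy(sub$seq, sub$gene_id, identity, k)
  }

  keep <- genes$gene_id %in% unique(rep_of)
  out <- genes[keep, , drop = FALSE]
  attr(out, "clusters") <- tibble::tibble(
    gene_id = genes$gene_id,
    representative_id = unname(rep_of[genes$gene_id])
  )
  out
}

# Greedy one-pass clustering over one family. Returns, for each input id,
# the id of its cluster representative.
cluster_greedy <- function(seqs, ids, identity, k) {
  ord <- order(-nchar(seqs))  # length descending, stable for ties
  kmer_sets <- lapply(seqs, kmer_set, k = k)

  rep_ids <- character(0)      # representatives, in founding order
  rep_kmers <- list()
  rep_seqs <- character(0)
  assign <- character(length(seqs))
  names(assign) <- ids

  for (i in ord) {
    placed <- FALSE
    if (length(rep_ids) > 0L) {
      for (j in seq_along(rep_ids)) {
        est <- containment_identity(kmer_sets[[i]], rep_kmers[[j]],
                                    seqs[i], rep_seqs[j])
        if (est >= identity) {
          assign[ids[i]] <- rep_ids[j]
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, ids[i])
      rep_kmers <- c(rep_kmers, kmer_sets[i])
      rep_seqs <- c(rep_seqs, seqs[i])
      assign[ids[i]] <- ids[i]
    }
  }
  assign
}

# Distinct k-mers of a sequence (ACGT-only windows).
kmer_set <- function(seq, k) {
  if (nchar(seq) < k) return(character(0))
  n <- nchar(seq) - k + 1L
  words <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  unique(words[!grepl("[^ACGT]", words)])
}

# Identity estimate: fraction of the shorter sequence's k-mers contained in
# the representative's k-mer set. Sequences too short to carry k-mers fall
# back to exact string equality.
containment_identity <- function(km_query, km_rep, seq_query, seq_rep) {
  shorter <- if (nchar(seq_query) <= nchar(seq_rep)) km_query else km_rep
  other <- if (nchar(seq_query) <= nchar(seq_rep)) km_rep else km_query
  if (length(shorter) == 0L) {
    return(if (identical(seq_query, seq_rep)) 1 else 0)
  }
  sum(shorter %in% other) / length(shorter)
}

#' Cluster membership table from a redundancy-reduced gene table
#'
#' @param reduced The result of [reduce_redundancy()].
#' @return A tibble `gene_id`, `representative_id`.
#' @export
cluster_table <- function(reduced) {
  cl <- attr(reduced, "clusters")
  if (is.null(cl)) {
    abort_validation("`reduced` carries no cluster table; was it produced by reduce_redundancy()?")
  }
  cl
}
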