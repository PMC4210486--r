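#' Read a virus-family FASTA into a gene table
#'
#' Reads a multi-record FASTA of coding nucleotide sequences (CDS) and returns
#' a tibble with one row per gene. Headers are parsed to the first
#' whitespace-delimited token; sequences are uppercased on ingest. IUPAC
#' ambiguity codes are tolerated (downstream word counting skips windows that
#' contain non-ACGT characters).
#'
#' @param path Path to a readable FASTA file (wrapped or unwrapped).
#' @param family Family label attached to every gene. Defaults to the file
#'   name without extension.
#' @return A tibble with columns `gene_id`, `family`, `seq`, `length_nt`,
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 some description", "ATGAAATAA", ">g2", "atgccctaa"), fa)
#' read_family_fasta(fa, family = "Toyviridae")
#' @export
read_family_fasta <- function(path, family = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_io(paste0("Cannot read FASTA file: ", paste(path, collapse = ", ")))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_io(paste0("Failed to parse FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort_validation(paste0("FASTA file '", path, "' contains no records."))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort_validation(paste0(
      "Duplicate gene_id in '", path, "': ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort_validation("FASTA contains records with empty sequences.")
  }
  family <- family %||% sub("\\.[^.]*$", "", basename(path))
  gene_table(gene_id = ids, family = family, seq = unname(seqs))
}

#' Assemble a gene table from ids, families and sequences
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Enforces the gene-table invariants: non-empty unique ids, non-empty
#' uppercase sequences, stable ingest order.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param family Character vector (or scalar) of family labels.
#' @param seq Character vector of nucleotide sequences.
#' @return A tibble with columns `gene_id`, `family`, `seq`, `length_nt`.
#' @export
gene_table <- function(gene_id, family, seq) {
  gene_id <- as.character(gene_id)
  seq <- toupper(as.character(seq))
  if (length(gene_id) != length(seq)) {
    abort_validation("`gene_id` and `seq` must have equal length.")
  }
  if (any(!nzchar(gene_id)) || anyNA(gene_id)) {
    abort_validation("gene_id values must be non-empty.")
  }
  if (anyDuplicated(gene_id)) {
    abort_validation(paste0(
      "gene_id values must be unique; duplicated: ",
      paste(unique(gene_id[duplicated(gene_id)]), collapse = ", ")
    ))
  }
  if (any(!nzchar(seq)) || anyNA(seq)) {
    abort_validation("Sequences must be non-empty.")
  }
  tibble::tibble(
    gene_id = gene_id,
    family = as.character(family),
    seq = seq,
    length_nt = nchar(seq)
  )
}

#' Read a gene table from a FASTA plus a gene-to-family map
#'
#' Single-file mode: one FASTA holding genes from several families and a
#' two-column tab-separated map `gene_id<TAB>family` (no header).
#'
#' @param fasta_path Path to the FASTA file.
#' @param map_path Path to the TSV mapping file.
#' @return A tibble as in [read_family_fasta()], families taken from the map.
#' @export
read_gene_table <- function(fasta_path, map_path) {
  genes <- read_family_fasta(fasta_path, family = "unassigned")
  if (!file.exists(map_path)) {
    abort_io(paste0("Cannot read family map: ", map_path))
  }
  map <- utils::read.table(map_path, sep = "\t", header = FALSE,
                           col.names = c("gene_id", "family"),
                           colClasses = "character", quote = "")
  missing <- setdiff(genes$gene_id, map$gene_id)
  if (length(missing) > 0L) {
    abort_validation(paste0(
      "Family map lacks entries for: ",
      paste(utils::head(missing, 5L), collapse = ", "),
      if (length(missing) > 5L) ", ..." else ""
    ))
  }
  genes$family <- map$family[match(genes$gene_id, map$gene_id)]
  genes
}

#' Write a gene table to FASTA (and optionally a family map)
#'
#' @param genes A gene table.
#' @param path Output FASTA path.
#' @param map_path Optional path for a `gene_id<TAB>family` TSV manifest.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, path, map_path = NULL) {
  check_gene_table(genes)
  set <- Biostrings::BStringSet(genes$seq)
  names(set) <- genes$gene_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  if (!is.null(map_path)) {
    utils::write.table(genes[, c("gene_id", "family")], map_path,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Internal: validate the minimal gene-table contract (gene_id + seq columns,
# invariants as in gene_table()). `require_family` additionally demands the
# family column.
check_gene_table <- function(genes, require_family = TRUE, arg = "genes") {
  if (!is.data.frame(genes)) {
    abort_validation(paste0("`", arg, "` must be a data frame."))
  }
  needed <- c("gene_id", "seq", if (require_family) "family")
  miss <- setdiff(needed, names(genes))
  if (length(miss) > 0L) {
    abort_validation(paste0(
      "`", arg, "` lacks required column(s): ", paste(miss, collapse = ", ")
    ))
  }
  if (nrow(genes) == 0L) {
    abort_validation(paste0("`", arg, "` contains no genes."))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort_validation(paste0(
      "`", arg, "` has duplicated gene_id: ",
      paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")
    ))
  }
  invisible(genes)
}

# Internal: families with more than three genes are analyzable.
check_family_size <- function(genes, min_genes = 4L, what = "dataset") {
  if (nrow(genes) < min_genes) {
    abort_validation(paste0(
      "The ", what, " holds ", nrow(genes), " gene(s); at least ", min_genes,
      " are required (families with more than three genes are analyzable)."
    ))
  }
  invisible(genes)
}
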