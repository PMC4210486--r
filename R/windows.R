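#' Segment a genome with a sliding window
#'
#' Produces segments starting at 0, `step`, 2*`step`, ... (0-based, half-open
#' coordinates). After the last full window, a trailing truncated segment is
#' kept if its length is at least `window / 2`, otherwise dropped.
#'
#' @param genome_seq Nucleotide string of the genome (coding strand as given;
#'   no reverse-complement canonicalization).
#' @param window Window size in nt (>= 1, <= genome length).
#' @param step Step size in nt (>= 1).
#' @param source_genome Label used to build segment ids.
#' @return A tibble with columns `segment_id`, `source_genome`, `start`,
#'   `end`, `seq`.
#' @examples
#' sliding_window("ACGTACGTACG", window = 4, step = 4)
#' @export
sliding_window <- function(genome_seq, window, step, source_genome = "genome") {
  if (!is.character(genome_seq) || length(genome_seq) != 1L || !nzchar(genome_seq)) {
    abort_validation("`genome_seq` must be a single non-empty nucleotide string.")
  }
  genome_seq <- toupper(genome_seq)
  len <- nchar(genome_seq)
  if (!is_scalar_number(window) || window < 1 || window != floor(window)) {
    abort_parameter("`window` must be a positive integer.")
  }
  if (!is_scalar_number(step) || step < 1 || step != floor(step)) {
    abort_parameter("`step` must be a positive integer.")
  }
  window <- as.integer(window); step <- as.integer(step)
  if (window > len) {
    abort_validation(paste0("`window` (", window, ") exceeds genome length (", len, ")."))
  }

  full_starts <- seq.int(0L, len - window, by = step)
  starts <- full_starts
  ends <- full_starts + window
  # Trailing truncated segment after the last full window.
  trail <- full_starts[length(full_starts)] + step
  if (trail < len && (len - trail) >= window / 2) {
    starts <- c(starts, trail)
    ends <- c(ends, len)
  }

  tibble::tibble(
    segment_id = sprintf("%s:%d-%d", source_genome, starts, ends),
    source_genome = source_genome,
    start = starts,
    end = ends,
    seq = substring(genome_seq, starts + 1L, ends)
  )
}
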