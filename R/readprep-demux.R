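#' Demultiplex paired reads by the read-2 inline barcode
#'
#' Assigns each read pair to the unique sample whose barcode is within
#' `max_mismatch` of the read-2 prefix; unassignable pairs go to the
#' `"undetermined"` bin. The barcode table must have pairwise Hamming
#' distances greater than `2 * max_mismatch` so assignments are unambiguous.
#'
#' @param reads tibble with at least `id` and `seq2` (e.g. from
#'   [read_fastq_pairs()] or [pool_libraries()]).
#' @param barcode_table named character vector, sample label -> barcode.
#' @param max_mismatch maximum Hamming distance to accept (default 0).
#' @return The input tibble with a `sample` column added; the per-sample
#'   tally is attached as attribute `"summary"` (also via
#'   [demux_summary()]).
#' @export
demultiplex <- function(reads, barcode_table, max_mismatch = 0L) {
  blen <- unique(nchar(barcode_table))
  if (length(blen) != 1L) abort("barcodes must all have the same length")
  dmat <- outer(barcode_table, barcode_table,
                Vectorize(function(a, b) sum(charToRaw(a) != charToRaw(b))))
  min_d <- min(dmat[upper.tri(dmat)], Inf)
  if (min_d <= 2L * max_mismatch) {
    abort(sprintf(
      "ambiguous barcode table: minimum pairwise distance %d is not > 2 * max_mismatch = %d",
      min_d, 2L * max_mismatch))
  }
  mm <- vapply(barcode_table, function(b) prefix_mismatches(reads$seq2, b),
               integer(nrow(reads)))
  mm <- matrix(mm, nrow = nrow(reads))
  best <- max.col(-mm, ties.method = "first")
  ok <- mm[cbind(seq_len(nrow(reads)), best)] <= max_mismatch
  out <- reads %>%
    mutate(sample = ifelse(ok, names(barcode_table)[best], "undetermined"))
  attr(out, "summary") <- out %>% count(.data$sample, name = "n")
  out
}

#' Per-sample read-pair counts from a demultiplexed tibble
#' @param reads a [demultiplex()] result.
#' @return Tibble with `sample` and `n`.
#' @export
demux_summary <- function(reads) {
  attr(reads, "summary") %||% count(reads, .data$sample, name = "n")
}
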