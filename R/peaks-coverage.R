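#' Strand-specific read-start pileup
#'
#' Builds a per-base coverage profile for one transcript strand: every
#' usable read contributes a unit interval of `extsize` bases extending
#' 3'-ward (in transcript orientation) from its 5' end, clipped at contig
#' bounds. All reads are counted -- deduplication has already happened
#' upstream, so no further duplicate collapsing is applied here.
#'
#' @param alignments usable-read tibble with `transcript_strand`.
#' @param genome `artr_genome`, contig tibble, or named length vector.
#' @param strand `"+"` or `"-"`: transcript strand to profile.
#' @param extsize extension length (nt) from each 5' end.
#' @return Object of class `artr_coverage`: per-contig
#'   [S4Vectors::Rle] pileups plus `strand`, `n_reads`, `extsize`,
#'   `contig_lengths`.
#' @export
build_coverage <- function(alignments, genome, strand, extsize = 30L) {
  stopifnot(strand %in% c("+", "-"))
  cl <- contig_lengths(genome)
  a <- alignments %>% filter(.data$transcript_strand == strand)
  if (nrow(a) > 0 && !all(a$chrom %in% names(cl))) {
    abort(sprintf("alignments on unknown contig(s): %s",
                  paste(setdiff(unique(a$chrom), names(cl)), collapse = ", ")))
  }
  # 5' end in transcript orientation; extension runs 3'-ward
  p5 <- if (strand == "+") a$start else a$end
  lo <- if (strand == "+") p5 else p5 - extsize
  hi <- lo + extsize
  cov <- lapply(names(cl), function(ch) {
    sel <- a$chrom == ch
    if (!any(sel)) return(S4Vectors::Rle(0L, cl[[ch]]))
    s <- pmax(lo[sel], 0L)
    e <- pmin(hi[sel], cl[[ch]])
    keep <- e > s
    IRanges::coverage(IRanges::IRanges(s[keep] + 1L, e[keep]),
                      width = cl[[ch]])
  })
  names(cov) <- names(cl)
  structure(list(cov = cov, strand = strand, n_reads = nrow(a),
                 extsize = extsize, contig_lengths = cl),
            class = "artr_coverage")
}

#' @export
print.artr_coverage <- function(x, ...) {
  cat(sprintf("<artr_coverage> strand %s, %d reads, extsize %d, %d contig(s)\n",
              x$strand, x$n_reads, x$extsize, length(x$cov)))
  invisible(x)
}

#' Total pileup mass of a coverage object
#' @param cov an `artr_coverage`.
#' @return Numeric scalar: sum of the per-base pileup over all contigs.
#' @export
coverage_sum <- function(cov) {
  sum(vapply(cov$cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                        S4Vectors::runLength(r)), numeric(1)))
}

#' Depth-normalised coverage track (bins per million)
#'
#' Scales the pileup so the summed bin values equal 10^6: each bin's value is
#' its pileup times 1e6 over the summed pileup of all bins. With
#' `binsize = 1` this is the per-base BPM normalisation used for browser
#' tracks; the result is run-compressed and serialisable as bedGraph via
#' [write_bedgraph()].
#'
#' @param cov an `artr_coverage`.
#' @param binsize bin width (nt).
#' @return Tibble `chrom`, `start`, `end`, `value` (adjacent equal-valued
#'   bins merged).
#' @export
normalize_track <- function(cov, binsize = 1L) {
  stopifnot(inherits(cov, "artr_coverage"))
  total <- coverage_sum(cov) / binsize
  if (total <= 0) abort("cannot normalise a zero-coverage track")
  out <- lapply(names(cov$cov), function(ch) {
    r <- cov$cov[[ch]]
    if (binsize > 1L) {
      len <- length(r)
      nb <- ceiling(len / binsize)
      idx <- rep(seq_len(nb), each = binsize)[seq_len(len)]
      v <- as.numeric(tapply(as.numeric(r), idx, sum)) / binsize
      r <- S4Vectors::Rle(v, rep(binsize, nb))
      r <- r[seq_len(len)]
    }
    rl <- S4Vectors::runLength(r)
    rv <- as.numeric(S4Vectors::runValue(r))
    e <- cumsum(rl)
    tibble(chrom = ch, start = as.integer(e - rl), end = as.integer(e),
           value = rv * 1e6 / total)
  })
  bind_rows(out)
}

#' Write a normalised track as bedGraph
#' @param track a [normalize_track()] tibble.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track %>% filter(.data$value != 0),
                   path, col_names = FALSE)
  invisible(path)
}
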