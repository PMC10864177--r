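#' Distance from each peak to the nearest strand-matched motif occurrence
#'
#' Scans the reference for the motif (forward occurrences annotate the "+"
#' strand, reverse-complement occurrences the "-" strand) and reports, per
#' peak, the absolute distance between the peak centre and the nearest
#' same-strand occurrence centre. Peaks on a chrom/strand without any
#' occurrence get `Inf` and are excluded (with a count) from cumulative
#' fractions computed by [summarize_motif_distance()].
#'
#' @param peaks peak tibble.
#' @param motif motif string (RNA or DNA alphabet).
#' @param genome `artr_genome` or [Biostrings::DNAStringSet].
#' @return `peaks` with a `motif_distance` column.
#' @export
motif_distance <- function(peaks, motif, genome) {
  seqs <- genome_seq(genome)
  motif_dna <- rna2dna(motif)
  occ <- motif_occurrences(seqs, motif_dna)
  dist <- rep(Inf, nrow(peaks))
  centre <- (peaks$start + peaks$end) %/% 2L
  for (key in unique(paste(peaks$chrom, peaks$strand))) {
    sel <- paste(peaks$chrom, peaks$strand) == key
    oc <- occ$centre[paste(occ$chrom, occ$strand) == key]
    if (length(oc) == 0L) next
    oc <- sort(oc)
    i <- findInterval(centre[sel], oc)
    lo <- oc[pmax(i, 1L)]
    hi <- oc[pmin(i + 1L, length(oc))]
    dist[sel] <- pmin(abs(centre[sel] - lo), abs(centre[sel] - hi))
  }
  peaks %>% mutate(motif_distance = dist)
}

# all occurrence centres of motif (both orientations) in a DNAStringSet
motif_occurrences <- function(seqs, motif_dna) {
  mlen <- nchar(motif_dna)
  out <- list()
  for (ci in seq_along(seqs)) {
    for (ori in c("+", "-")) {
      pat <- if (ori == "+") motif_dna else rc_chr(motif_dna)
      m <- Biostrings::matchPattern(pat, seqs[[ci]])
      if (length(m) > 0L) {
        out[[length(out) + 1L]] <- tibble(
          chrom = names(seqs)[ci],
          centre = IRanges::start(m) - 1L + mlen %/% 2L,
          strand = ori)
      }
    }
  }
  bind_rows(out)
}

#' Cumulative fraction of peaks within given distances of the motif
#'
#' @param peaks a [motif_distance()] result.
#' @param d distances (nt) at which to report cumulative fractions.
#' @return Tibble `d`, `n_within`, `fraction`; attribute `"n_excluded"`
#'   counts peaks with no same-strand occurrence on their contig.
#' @export
summarize_motif_distance <- function(peaks, d = c(200, 300, 500)) {
  finite <- is.finite(peaks$motif_distance)
  x <- peaks$motif_distance[finite]
  out <- tibble(d = d,
                n_within = vapply(d, function(k) sum(x <= k), integer(1)),
                fraction = vapply(d, function(k) mean(x <= k), numeric(1)))
  attr(out, "n_excluded") <- sum(!finite)
  out
}

#' Scan protein-coding genes for pyrimidine-rich (CU-enriched) regions
#'
#' Slides a `width`-nt window (1-nt step) along every protein-coding gene
#' span and keeps windows whose strand-aware C+U content (C+T on the sense
#' DNA strand) strictly exceeds `ct_min`; overlapping windows are merged.
#'
#' @param genome `artr_genome` or [Biostrings::DNAStringSet].
#' @param index an [feature_index()] (needed when `genome` is a plain
#'   sequence set).
#' @param width window width (nt).
#' @param ct_min exclusive lower bound on the C+U fraction.
#' @return Tibble `chrom`, `start`, `end`, `strand`, `gene_id` of merged
#'   regions (0-based half-open).
#' @export
scan_cu_regions <- function(genome, index = NULL, width = 80L,
                            ct_min = 0.70) {
  if (is.null(index)) {
    if (!inherits(genome, "artr_genome")) {
      abort("`index` is required when `genome` is not an `artr_genome`")
    }
    index <- feature_index(genome)
  }
  seqs <- genome_seq(genome)
  genes <- index$genes %>% filter(.data$protein_coding)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$end - g$start < width) next
    sub <- Biostrings::subseq(seqs[[g$chrom]], g$start + 1L, g$end)
    letters <- if (g$strand == "+") c("C", "T") else c("G", "A")
    cnt <- Biostrings::letterFrequencyInSlidingView(sub, width, letters)
    frac <- rowSums(cnt) / width
    sig <- which(frac > ct_min)  # window starts, 1-based within gene
    if (length(sig) == 0L) next
    ws <- g$start + sig - 1L     # genomic 0-based window starts
    merged <- merge_windows(ws, width)
    out[[length(out) + 1L]] <- merged %>%
      mutate(chrom = g$chrom, strand = g$strand, gene_id = g$gene_id)
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), gene_id = character(0)))
  }
  bind_rows(out) %>% select("chrom", "start", "end", "strand", "gene_id")
}

# merge overlapping fixed-width windows given their sorted starts
merge_windows <- function(starts, width) {
  brk <- c(TRUE, diff(starts) >= width)
  grp <- cumsum(brk)
  tibble(start = as.integer(tapply(starts, grp, min)),
         end = as.integer(tapply(starts, grp, max)) + as.integer(width))
}

#' Per-read sequence composition and motif content
#'
#' Computes, on the transcript-strand (sense) sequence of each read, the C+U
#' fraction and whether the read contains at least one motif occurrence.
#' Under reverse strandedness the sequenced read 1 is cDNA, so its reverse
#' complement is the sense sequence.
#'
#' @param reads alignment tibble with a `seq` column, or a trimmed read
#'   tibble.
#' @param motif motif string (RNA or DNA alphabet).
#' @param strandedness `"reverse"` (default) or `"forward"`.
#' @return Tibble `id`, `ct_fraction`, `has_motif`; attribute
#'   `"motif_fraction"` is the fraction of reads containing the motif.
#' @export
read_seq_stats <- function(reads, motif,
                           strandedness = c("reverse", "forward")) {
  strandedness <- match.arg(strandedness)
  if (nrow(reads) == 0L) abort("empty read set")
  s <- reads$seq
  if (strandedness == "reverse") s <- rc_chr(s)
  motif_dna <- rna2dna(motif)
  out <- tibble(
    id = if ("read_id" %in% names(reads)) reads$read_id else reads$id,
    ct_fraction = stringi::stri_count_charclass(s, "[CT]") / nchar(s),
    has_motif = stringi::stri_detect_fixed(s, motif_dna))
  attr(out, "motif_fraction") <- mean(out$has_motif)
  out
}

#' Percentage of peaks containing at least one site
#'
#' Strand-aware interval overlap after extending the peaks symmetrically by
#' `slop` nt. Sites without strand information (`"*"`) match either strand.
#'
#' @param peaks peak tibble.
#' @param sites site tibble (`chrom`, `start`, `end`, optional `strand`).
#' @param slop symmetric extension (nt) applied to peaks before overlap.
#' @return One-row tibble `n_peaks`, `n_with_site`, `percent`.
#' @export
site_overlap <- function(peaks, sites, slop = 0L) {
  if (nrow(peaks) == 0L) {
    return(tibble(n_peaks = 0L, n_with_site = 0L, percent = NaN))
  }
  pk <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(pmax(peaks$start - slop, 0L) + 1L, peaks$end + slop),
    strand = peaks$strand)
  st <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$start + 1L, sites$end),
    strand = if ("strand" %in% names(sites)) sites$strand else "*")
  hit <- GenomicRanges::countOverlaps(pk, st, ignore.strand = FALSE) > 0
  tibble(n_peaks = nrow(peaks), n_with_site = sum(hit),
         percent = 100 * mean(hit))
}
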