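#' Anchored read-density matrix and mean profile
#'
#' Extracts the depth-normalised coverage (bins-per-million per base) in a
#' window of `2 * flank` positions around each anchor, orienting rows so
#' position runs 5' to 3' (minus-strand rows reversed). Anchor windows
#' extending past a contig end are zero-padded and flagged.
#'
#' @param cov an [build_coverage()] object.
#' @param anchors tibble with `chrom`, `pos` (0-based; e.g. peak summits or
#'   region centres) and optionally `strand` (defaults to the coverage
#'   strand).
#' @param flank half-window (nt); columns cover `[-flank, flank)`.
#' @param normalize scale to bins-per-million (default) or keep raw pileup.
#' @return Object of class `artr_profile`: `matrix` (anchors x positions),
#'   `positions` (relative offsets), `mean` (column means), `clipped`
#'   (logical per anchor).
#' @export
profile_matrix <- function(cov, anchors, flank, normalize = TRUE) {
  stopifnot(inherits(cov, "artr_coverage"))
  scale <- if (normalize) 1e6 / coverage_sum(cov) else 1
  strand <- if ("strand" %in% names(anchors)) anchors$strand
            else rep(cov$strand, nrow(anchors))
  n <- nrow(anchors)
  mat <- matrix(0, nrow = n, ncol = 2L * flank)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    ch <- anchors$chrom[i]
    r <- cov$cov[[ch]]
    if (is.null(r)) abort(sprintf("anchor on unknown contig '%s'", ch))
    len <- length(r)
    lo <- anchors$pos[i] - flank      # 0-based inclusive
    hi <- anchors$pos[i] + flank      # exclusive
    clo <- max(lo, 0L); chi <- min(hi, len)
    if (clo > lo || chi < hi) clipped[i] <- TRUE
    if (chi > clo) {
      vals <- as.numeric(S4Vectors::window(r, clo + 1L, chi)) * scale
      mat[i, (clo - lo + 1L):(chi - lo)] <- vals
    }
    if (strand[i] == "-") mat[i, ] <- rev(mat[i, ])
  }
  rownames(mat) <- if ("name" %in% names(anchors)) anchors$name else NULL
  structure(list(matrix = mat, positions = seq(-flank, flank - 1L),
                 mean = colMeans(mat), clipped = clipped),
            class = "artr_profile")
}

#' @export
print.artr_profile <- function(x, ...) {
  cat(sprintf("<artr_profile> %d anchors x %d positions (%d clipped)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$clipped)))
  invisible(x)
}

#' Metagene distribution of peaks along the 5'UTR/CDS/3'UTR axis
#'
#' Maps each exonic mRNA peak centre to a fractional transcript coordinate
#' within its feature (5'UTR, CDS or 3'UTR of the assigned gene, using the
#' longest-transcript partition), bins the three segments into `bins` bins
#' and normalises the density to sum to 1 over the whole axis.
#'
#' @param peaks peak tibble (a feature/gene assignment is computed via
#'   [assign_peaks()] when absent).
#' @param index an [feature_index()] object.
#' @param bins integer vector `(n5, nCDS, n3)` of bins per segment.
#' @return Tibble `bin`, `segment`, `position` (axis midpoint in `[0, 1]`),
#'   `density`; attribute `"n_dropped"` counts non-mRNA-exonic peaks.
#' @export
metagene_peaks <- function(peaks, index, bins = c(25L, 50L, 25L)) {
  if (!"feature" %in% names(peaks)) peaks <- assign_peaks(peaks, index)
  mrna <- c("five_prime_utr", "CDS", "three_prime_utr")
  px <- peaks %>% filter(.data$feature %in% mrna)
  if (nrow(px) == 0L) abort("no peaks in mRNA exonic features (5'UTR/CDS/3'UTR)")
  feats <- index$features
  frac <- numeric(nrow(px))
  for (i in seq_len(nrow(px))) {
    centre <- (px$start[i] + px$end[i]) %/% 2L
    f <- feats %>%
      filter(.data$gene_id == px$gene_id[i],
             .data$feature == as.character(px$feature[i]))
    # transcript order: genomic order on "+", reversed on "-"
    f <- if (f$strand[1] == "+") f %>% arrange(.data$start)
         else f %>% arrange(dplyr::desc(.data$start))
    lens <- f$end - f$start
    total <- sum(lens)
    cum <- cumsum(c(0L, lens[-length(lens)]))
    inside <- which(centre >= f$start & centre < f$end)
    if (length(inside) == 0L) {
      # centre fell in an intron of the same gene: clamp to nearest piece
      dist <- pmin(abs(centre - f$start), abs(centre - (f$end - 1L)))
      inside <- which.min(dist)
      centre <- pmin(pmax(centre, f$start[inside]), f$end[inside] - 1L)
    }
    j <- inside[1]
    off <- if (f$strand[j] == "+") centre - f$start[j]
           else f$end[j] - 1L - centre
    frac[i] <- (cum[j] + off + 0.5) / total
  }
  seg <- factor(as.character(px$feature), levels = mrna)
  nb <- setNames(bins, mrna)
  bin_in_seg <- pmin(ceiling(frac * nb[as.character(seg)]), nb[as.character(seg)])
  bin_in_seg[bin_in_seg < 1] <- 1L
  offset <- setNames(c(0L, bins[1], bins[1] + bins[2]), mrna)
  bin <- offset[as.character(seg)] + bin_in_seg
  total_bins <- sum(bins)
  counts <- tabulate(bin, nbins = total_bins)
  tibble(
    bin = seq_len(total_bins),
    segment = factor(rep(mrna, bins), levels = mrna),
    position = (seq_len(total_bins) - 0.5) / total_bins,
    density = counts / sum(counts)
  )
}

#' Length-matched random exonic regions
#'
#' For each peak, draws one interval of identical length placed uniformly at
#' random within the merged exonic space (every admissible placement equally
#' likely). Peaks longer than every exonic interval are skipped and counted.
#'
#' @param peaks peak tibble (lengths are taken from `end - start`).
#' @param index an [feature_index()] object.
#' @param seed integer seed (private RNG stream).
#' @return Tibble `chrom`, `start`, `end`, `strand` of random regions, one
#'   per placeable peak; attribute `"n_skipped"` counts skipped peaks.
#' @export
shuffle_regions <- function(peaks, index, seed) {
  exonic <- merged_exonic_space(index)
  with_seed(seed, {
    lens <- peaks$end - peaks$start
    rows <- vector("list", length(lens))
    skipped <- 0L
    for (i in seq_along(lens)) {
      L <- lens[i]
      fit <- exonic %>% mutate(slots = .data$end - .data$start - L + 1L) %>%
        filter(.data$slots > 0L)
      if (nrow(fit) == 0L) { skipped <- skipped + 1L; next }
      j <- sample.int(nrow(fit), 1L, prob = fit$slots)
      s <- fit$start[j] + sample.int(fit$slots[j], 1L) - 1L
      rows[[i]] <- tibble(chrom = fit$chrom[j], start = s, end = s + L,
                          strand = fit$strand[j])
    }
    out <- bind_rows(rows)
    attr(out, "n_skipped") <- skipped
    out
  })
}

# merged exonic intervals (UTR/CDS/noncoding exon pieces joined when abutting
# within a gene), with strand retained
merged_exonic_space <- function(index) {
  ex <- index$features %>%
    filter(.data$feature %in% c("five_prime_utr", "CDS", "three_prime_utr",
                                "noncoding_exon")) %>%
    arrange(.data$chrom, .data$strand, .data$start)
  if (nrow(ex) == 0L) abort("annotation has no exonic features")
  grp_break <- c(TRUE, ex$chrom[-1] != ex$chrom[-nrow(ex)] |
                   ex$strand[-1] != ex$strand[-nrow(ex)] |
                   ex$start[-1] > cummax_end(ex)[-nrow(ex)])
  grp <- cumsum(grp_break)
  ex %>%
    mutate(grp = grp) %>%
    group_by(.data$grp) %>%
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), strand = .data$strand[1],
              .groups = "drop") %>%
    select("chrom", "start", "end", "strand")
}

cummax_end <- function(ex) {
  key <- paste(ex$chrom, ex$strand)
  out <- numeric(nrow(ex))
  for (k in unique(key)) {
    sel <- key == k
    out[sel] <- cummax(ex$end[sel])
  }
  as.integer(out)
}
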