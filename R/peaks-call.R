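#' Strand-separated Poisson peak calling against an input control
#'
#' Per-base enrichment test on one transcript strand. The local background
#' rate at each base is `lambda_local = max(lambda_bg, lambda_ext,
#' lambda_1k, lambda_10k)`, the windowed means computed from the control
#' pileup and scaled by the depth ratio (treatment reads / control reads);
#' `lambda_ext` uses a fragment-sized (`extsize`) window, which keeps the
#' local rate honest at sharp coverage boundaries such as gene edges, where
#' kilobase windows dilute the control rate with flanking zeros. Without a
#' control, the genome-wide rate of the treatment itself is used. Each base
#' with nonzero treatment pileup gets an upper-tail Poisson p-value
#' `P(X >= pileup | lambda_local)`; Benjamini-Hochberg correction is applied
#' over exactly that family. Significant bases (`q < qcut`) are merged when
#' separated by at most `merge_gap`, peaks shorter than `min_len` are
#' dropped, the summit is the leftmost pileup maximum, and the fold
#' enrichment (signal value) is `(pileup + pc) / (lambda_local + pc)` at the
#' summit.
#'
#' @param treat treatment [build_coverage()] object.
#' @param ctrl matching-strand control coverage, or `NULL`.
#' @param qcut q-value cutoff for significant bases.
#' @param min_len minimum peak length (nt).
#' @param merge_gap maximum gap (nt) bridged when merging significant bases;
#'   defaults to the treatment `extsize`.
#' @param pc pseudocount in the fold-enrichment ratio.
#' @param lambda_windows window widths for the local background; defaults to
#'   `c(extsize, 1000, 10000)`.
#' @return Peak tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `summit` (0-based position), `pileup`, `fold_enrichment`,
#'   `p_value`, `q_value`.
#' @export
call_peaks <- function(treat, ctrl = NULL, qcut = 0.05, min_len = 30L,
                       merge_gap = NULL, pc = 0.1, lambda_windows = NULL) {
  stopifnot(inherits(treat, "artr_coverage"))
  if (treat$n_reads == 0L) abort("zero-depth treatment: no reads on this strand")
  if (!is.null(ctrl)) {
    stopifnot(inherits(ctrl, "artr_coverage"))
    if (ctrl$strand != treat$strand) {
      abort("treatment and control must be on the same strand")
    }
    if (ctrl$n_reads == 0L) ctrl <- NULL
  }
  merge_gap <- merge_gap %||% treat$extsize
  lambda_windows <- lambda_windows %||% c(treat$extsize, 1000L, 10000L)
  genome_len <- sum(treat$contig_lengths)
  ratio <- if (!is.null(ctrl)) treat$n_reads / ctrl$n_reads else NA_real_
  lambda_bg <- if (!is.null(ctrl)) {
    coverage_sum(ctrl) * ratio / genome_len
  } else {
    coverage_sum(treat) / genome_len
  }

  per_base <- lapply(names(treat$cov), function(ch) {
    t_rle <- treat$cov[[ch]]
    tvec <- as.integer(t_rle)
    idx <- which(tvec > 0L)  # 1-based
    if (length(idx) == 0L) return(NULL)
    lam <- rep(lambda_bg, length(idx))
    if (!is.null(ctrl)) {
      cs <- c(0, cumsum(as.numeric(ctrl$cov[[ch]])))
      n <- length(tvec)
      for (w in lambda_windows) {
        half <- w %/% 2L
        wm <- (cs[pmin(n, idx + half) + 1L] - cs[pmax(idx - half, 0L) + 1L]) /
          w * ratio
        lam <- pmax(lam, wm)
      }
    }
    tibble(chrom = ch, pos = idx - 1L, pileup = tvec[idx], lambda = lam,
           p = ppois(tvec[idx] - 1L, lam, lower.tail = FALSE))
  })
  per_base <- bind_rows(per_base)
  if (nrow(per_base) == 0L) return(empty_peaks(treat$strand))
  per_base$q <- p.adjust(per_base$p, method = "BH")

  sig <- per_base %>% filter(.data$q < qcut)
  if (nrow(sig) == 0L) return(empty_peaks(treat$strand))
  sig <- sig %>% arrange(.data$chrom, .data$pos)
  new_run <- c(TRUE, diff(sig$pos) - 1L > merge_gap |
                 sig$chrom[-1] != sig$chrom[-nrow(sig)])
  sig$run <- cumsum(new_run)

  peaks <- sig %>%
    group_by(.data$run) %>%
    summarise(chrom = .data$chrom[1],
              start = min(.data$pos),
              end = max(.data$pos) + 1L,
              .groups = "drop") %>%
    filter(.data$end - .data$start >= min_len)
  if (nrow(peaks) == 0L) return(empty_peaks(treat$strand))

  details <- purrr::pmap_dfr(
    peaks %>% select("chrom", "start", "end"),
    function(chrom, start, end) {
      win <- as.integer(S4Vectors::window(treat$cov[[chrom]], start + 1L, end))
      s_off <- which.max(win)  # leftmost maximum
      summit <- start + s_off - 1L
      row <- per_base[per_base$chrom == chrom & per_base$pos == summit, ]
      tibble(summit = summit, pileup = as.numeric(row$pileup[1]),
             fold_enrichment = (row$pileup[1] + pc) / (row$lambda[1] + pc),
             p_value = row$p[1], q_value = row$q[1])
    })
  bind_cols(peaks %>% select("chrom", "start", "end"), details) %>%
    mutate(strand = treat$strand) %>%
    select("chrom", "start", "end", "strand", "summit", "pileup",
           "fold_enrichment", "p_value", "q_value")
}

empty_peaks <- function(strand = character(0)) {
  tibble(chrom = character(0), start = integer(0), end = integer(0),
         strand = character(0), summit = integer(0), pileup = numeric(0),
         fold_enrichment = numeric(0), p_value = numeric(0),
         q_value = numeric(0))
}

#' Combine peak sets called separately on the two strands
#'
#' Plain concatenation with strand labels preserved: the strands are called
#' against their matching-strand controls and never merged across strands,
#' so overlapping sense/antisense peaks both survive.
#'
#' @param peaks_plus,peaks_minus peak tibbles from [call_peaks()].
#' @return Peak tibble sorted by position.
#' @export
combine_strands <- function(peaks_plus, peaks_minus) {
  bind_rows(peaks_plus, peaks_minus) %>%
    arrange(.data$chrom, .data$start, .data$strand)
}

#' Export peaks in narrowPeak (BED6+4) format
#'
#' `signalValue` carries the fold enrichment; `pValue`/`qValue` are
#' -log10-transformed; the 10th column is the summit offset from `start`.
#'
#' @param peaks peak tibble.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = pmin(1000L, as.integer(round(10 * peaks$fold_enrichment))),
    strand = peaks$strand,
    signalValue = round(peaks$fold_enrichment, 5),
    pValue = round(-log10(pmax(peaks$p_value, 1e-300)), 5),
    qValue = round(-log10(pmax(peaks$q_value, 1e-300)), 5),
    peak = peaks$summit - peaks$start)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
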