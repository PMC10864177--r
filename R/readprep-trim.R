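#' Trim read 1: extract the UMI, strip adapter and low-quality tail
#'
#' Processing order per read: (1) the leading `umi_length` bases move to the
#' `umi` column; (2) the 3' tail is quality-trimmed with a simplified
#' two-colour rule (trailing bases removed while below `q_cutoff` or part of
#' a trailing G run, G being the dark base); (3) the 3' adapter is removed at
#' the leftmost position where the read suffix matches a prefix of the
#' adapter with at least `min_overlap` nt overlap and at most
#' `max_error_rate` mismatches; (4) a further `tail_trim` bases are removed
#' from the 3' end (the imperfectly paired random-primer bases); (5) reads
#' shorter than `min_len` are discarded (counted, not an error).
#'
#' @param reads tibble with `id` plus `seq1`/`qual1` (paired input) or
#'   `seq`/`qual`; a `sample` column, if present, is carried through.
#' @param adapter 3' adapter sequence.
#' @param umi_length UMI length at the start of read 1.
#' @param tail_trim extra 3' bases removed after adapter removal.
#' @param min_len minimum surviving insert length.
#' @param q_cutoff Phred cutoff for tail trimming.
#' @param max_error_rate mismatch fraction tolerated in the adapter overlap.
#' @param min_overlap minimum adapter overlap (nt).
#' @return Tibble with `id`, `seq`, `qual`, `umi` (+ `sample` when present)
#'   for kept reads. Attribute `"n_discarded"` counts reads dropped at the
#'   length filter.
#' @export
trim_reads <- function(reads, adapter, umi_length = 8L, tail_trim = 4L,
                       min_len = 24L, q_cutoff = 20L, max_error_rate = 0.1,
                       min_overlap = 3L) {
  seqcol <- if ("seq1" %in% names(reads)) "seq1" else "seq"
  qualcol <- if ("qual1" %in% names(reads)) "qual1" else "qual"
  s <- reads[[seqcol]]
  q <- reads[[qualcol]]
  if (any(nchar(s) <= umi_length)) {
    abort("reads no longer than `umi_length` cannot be trimmed")
  }
  umi <- stringi::stri_sub(s, 1L, umi_length)
  s <- stringi::stri_sub(s, umi_length + 1L)
  q <- stringi::stri_sub(q, umi_length + 1L)

  keep_n <- quality_keep_length(s, q, q_cutoff)
  s <- stringi::stri_sub(s, 1L, keep_n)
  q <- stringi::stri_sub(q, 1L, keep_n)

  apos <- find_adapter(s, adapter, min_overlap, max_error_rate)
  cut <- ifelse(is.na(apos), nchar(s), apos - 1L)
  cut <- pmax(cut - tail_trim, 0L)
  s <- stringi::stri_sub(s, 1L, cut)
  q <- stringi::stri_sub(q, 1L, cut)

  keep <- nchar(s) >= min_len
  out <- tibble(id = reads$id[keep], seq = s[keep], qual = q[keep],
                umi = umi[keep])
  if ("sample" %in% names(reads)) out$sample <- reads$sample[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

# Length to keep after stripping the 3' tail of bases that are below the
# quality cutoff or are dark-cycle Gs (two-colour chemistry), iterating from
# the read end inwards.
quality_keep_length <- function(s, q, q_cutoff) {
  n <- nchar(s)
  thr <- 33L + as.integer(q_cutoff)
  active <- which(n > 0L)
  while (length(active) > 0L) {
    last_b <- stringi::stri_sub(s[active], n[active], n[active])
    last_q <- as.integer(charToRaw(paste(
      stringi::stri_sub(q[active], n[active], n[active]), collapse = "")))
    bad <- last_b == "G" | last_q < thr
    n[active[bad]] <- n[active[bad]] - 1L
    active <- active[bad]
    active <- active[n[active] > 0L]
  }
  n
}

# Leftmost read position at which a prefix of `adapter` overlaps the read
# suffix with >= min_overlap bases and <= max_error_rate mismatches.
# Returns the 1-based position of the adapter start, NA when absent.
# Reads are grouped by length and scanned as byte matrices in chunks.
find_adapter <- function(seqs, adapter, min_overlap = 3L,
                         max_error_rate = 0.1) {
  res <- rep(NA_integer_, length(seqs))
  if (length(seqs) == 0L) return(res)
  ab <- as.integer(charToRaw(adapter))
  nA <- length(ab)
  n <- nchar(seqs)
  for (len in sort(unique(n))) {
    if (len < min_overlap) next
    idx <- which(n == len)
    for (ch in split(idx, ceiling(seq_along(idx) / 100000L))) {
      m <- matrix(as.integer(charToRaw(paste(seqs[ch], collapse = ""))),
                  nrow = length(ch), ncol = len, byrow = TRUE)
      pos <- rep(NA_integer_, length(ch))
      for (i in seq_len(len - min_overlap + 1L)) {
        need <- which(is.na(pos))
        if (length(need) == 0L) break
        L <- min(nA, len - i + 1L)
        allowed <- floor(max_error_rate * L)
        block <- m[need, i:(i + L - 1L), drop = FALSE]
        mm <- rowSums(block != matrix(ab[seq_len(L)], nrow = length(need),
                                      ncol = L, byrow = TRUE))
        pos[need[mm <= allowed]] <- i
      }
      res[ch] <- pos
    }
  }
  res
}
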