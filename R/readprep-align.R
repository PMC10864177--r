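#' Exact/1-mismatch fixture aligner for synthetic reads
#'
#' Ungapped search of each read against both strands of the reference,
#' tolerating up to `max_mismatch` (0 or 1) substitutions. Reads with exactly
#' one best-scoring locus are kept (`unique = TRUE`); multimappers and
#' unmapped reads are dropped and counted. Intended for error-free or
#' near-error-free synthetic reads; production data enters through
#' [read_sam()] from an external aligner.
#'
#' The library is reverse-stranded by default: read 1 carries the cDNA
#' sense, so the transcript strand is the opposite of the alignment strand.
#'
#' @param reads trimmed read tibble from [trim_reads()] (`id`, `seq`, `umi`,
#'   optionally `sample`).
#' @param genome an `artr_genome` or named [Biostrings::DNAStringSet].
#' @param max_mismatch 0 (exact) or 1.
#' @param min_len minimum mapped length; shorter reads are not searched.
#' @param strandedness `"reverse"` (default) flips the alignment strand to
#'   obtain the transcript strand; `"forward"` keeps it.
#' @return Alignment tibble: `read_id`, `chrom`, `start` (0-based), `end`,
#'   `align_strand`, `transcript_strand`, `mapped_length`, `umi`, `seq`,
#'   `unique` (+ `sample` if present). Attributes `"n_unmapped"` and
#'   `"n_multimapped"` report dropped reads.
#' @export
align_exact <- function(reads, genome, max_mismatch = 0L, min_len = 24L,
                        strandedness = c("reverse", "forward")) {
  strandedness <- match.arg(strandedness)
  if (!max_mismatch %in% c(0L, 1L)) abort("`max_mismatch` must be 0 or 1")
  seqs <- genome_seq(genome)
  if (length(seqs) == 0L) abort("reference contains no contigs")
  long_enough <- nchar(reads$seq) >= min_len
  rd <- reads[long_enough, ]
  n <- nrow(rd)
  hits <- list()
  if (n > 0L) {
    widths <- nchar(rd$seq)
    sets <- list("+" = Biostrings::DNAStringSet(rd$seq),
                 "-" = Biostrings::reverseComplement(
                   Biostrings::DNAStringSet(rd$seq)))
    dicts <- lapply(sets, build_pdicts, widths = widths,
                    max_mismatch = max_mismatch)
    for (ci in seq_along(seqs)) {
      for (ori in c("+", "-")) {
        h <- pdict_hits(dicts[[ori]], sets[[ori]], seqs[[ci]], widths,
                        max_mismatch)
        if (nrow(h) > 0) {
          h$chrom <- names(seqs)[ci]
          h$align_strand <- ori
          h$ridx <- h$pidx
          hits[[length(hits) + 1L]] <- h
        }
      }
    }
  }
  hits <- bind_rows(hits)
  if (nrow(hits) == 0L) {
    out <- empty_alignments(rd)
    attr(out, "n_unmapped") <- n + sum(!long_enough)
    attr(out, "n_multimapped") <- 0L
    return(out)
  }
  best <- hits %>%
    group_by(.data$ridx) %>%
    filter(.data$mm == min(.data$mm)) %>%
    mutate(n_best = n()) %>%
    slice(1L) %>%
    ungroup()
  uni <- best %>% filter(.data$n_best == 1L)
  out <- tibble(
    read_id = rd$id[uni$ridx],
    chrom = uni$chrom,
    start = uni$start0,
    end = uni$start0 + nchar(rd$seq[uni$ridx]),
    align_strand = uni$align_strand,
    transcript_strand = flip_strand(uni$align_strand, strandedness),
    mapped_length = nchar(rd$seq[uni$ridx]),
    umi = rd$umi[uni$ridx],
    seq = rd$seq[uni$ridx],
    unique = TRUE
  )
  if ("sample" %in% names(rd)) out$sample <- rd$sample[uni$ridx]
  attr(out, "n_unmapped") <- n - dplyr::n_distinct(hits$ridx) + sum(!long_enough)
  attr(out, "n_multimapped") <- nrow(best) - nrow(uni)
  out
}

empty_alignments <- function(rd = NULL) {
  out <- tibble(read_id = character(0), chrom = character(0),
                start = integer(0), end = integer(0),
                align_strand = character(0), transcript_strand = character(0),
                mapped_length = integer(0), umi = character(0),
                seq = character(0), unique = logical(0))
  if (!is.null(rd) && "sample" %in% names(rd)) out$sample <- character(0)
  out
}

flip_strand <- function(strand, strandedness) {
  if (strandedness == "reverse") ifelse(strand == "+", "-", "+") else strand
}

# Trusted-band dictionaries over variable-width reads. Exact search needs a
# single leading-band PDict; the 1-mismatch search adds a trailing-band
# PDict so that by the pigeonhole principle every hit with one mismatch is
# found by at least one of the two passes (the mismatch cannot sit in both
# bands at once).
build_pdicts <- function(pats, widths, max_mismatch) {
  k <- min(widths) %/% if (max_mismatch > 0L) 2L else 1L
  out <- list(lead = Biostrings::PDict(pats, tb.start = 1L, tb.end = k))
  if (max_mismatch > 0L) {
    # trailing band realised as the leading band of the reversed patterns,
    # searched against the reversed subject
    out$trail <- Biostrings::PDict(Biostrings::reverse(pats),
                                   tb.start = 1L, tb.end = k)
  }
  out
}

# All hits of the reads in one subject with <= max_mismatch substitutions.
pdict_hits <- function(dicts, pats, subject, widths, max_mismatch) {
  collect <- function(mi) {
    cnt <- S4Vectors::elementNROWS(mi)
    if (sum(cnt) == 0L) {
      return(tibble(pidx = integer(0), start0 = integer(0)))
    }
    st <- IRanges::start(unlist(mi, use.names = FALSE))
    tibble(pidx = rep(seq_along(cnt), cnt), start0 = st - 1L)
  }
  h <- list(collect(Biostrings::matchPDict(dicts$lead, subject,
                                           max.mismatch = max_mismatch)))
  if (!is.null(dicts$trail)) {
    hr <- collect(Biostrings::matchPDict(dicts$trail,
                                         Biostrings::reverse(subject),
                                         max.mismatch = max_mismatch))
    if (nrow(hr) > 0) {
      hr$start0 <- length(subject) - (hr$start0 + widths[hr$pidx])
    }
    h[[2L]] <- hr
  }
  all <- bind_rows(h) %>% distinct(.data$pidx, .data$start0)
  if (nrow(all) == 0L) return(all %>% mutate(mm = integer(0)))
  if (max_mismatch == 0L) return(all %>% mutate(mm = 0L))
  # recount mismatches exactly (cheap: few hits per read)
  sub <- as.character(Biostrings::extractAt(
    subject, IRanges::IRanges(all$start0 + 1L, width = widths[all$pidx])))
  pat <- as.character(pats)[all$pidx]
  all$mm <- mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)), sub, pat,
                   USE.NAMES = FALSE)
  all %>% filter(.data$mm <= max_mismatch)
}

#' Ingest external alignments from SAM/BAM
#'
#' Accepts coordinate-sorted SAM/BAM from an external aligner. Uniqueness is
#' taken from the NH tag (`NH == 1`); the UMI is parsed from the read name
#' suffix after the final underscore (the usual "moved to the read name"
#' convention).
#'
#' @param path SAM or BAM file.
#' @param strandedness `"reverse"` or `"forward"` (see [align_exact()]).
#' @param contigs optional character vector of expected contig names; an
#'   alignment on a contig outside this set is an error.
#' @return Alignment tibble as in [align_exact()] (without `seq`).
#' @export
read_sam <- function(path, strandedness = c("reverse", "forward"),
                     contigs = NULL) {
  strandedness <- match.arg(strandedness)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam_path <- if (is_sam) Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
              else path
  b <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  if (length(b$qname) == 0L) return(empty_alignments())
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  chrom <- as.character(b$rname)
  if (!is.null(contigs) && !all(chrom %in% contigs)) {
    missing <- setdiff(unique(chrom), contigs)
    abort(sprintf("alignments on unknown contig(s): %s",
                  paste(missing, collapse = ", ")))
  }
  nh <- b$tag$NH %||% rep(1L, length(b$qname))
  nh[is.na(nh)] <- 1L
  strand <- as.character(b$strand)
  umi <- sub("^.*_", "", b$qname)
  umi[!grepl("_", b$qname)] <- NA_character_
  out <- tibble(
    read_id = b$qname, chrom = chrom,
    start = b$pos - 1L, end = b$pos - 1L + rw,
    align_strand = strand,
    transcript_strand = flip_strand(strand, strandedness),
    mapped_length = rw, umi = umi, unique = nh == 1L
  )
  out %>% filter(.data$unique)
}

#' Write alignments as a minimal SAM file
#'
#' Emits ungapped records (full-length match CIGAR, `NH:i:1`) so the fixture
#' aligner's output can be inspected with standard tools or re-ingested via
#' [read_sam()].
#'
#' @param alignments alignment tibble.
#' @param genome `artr_genome` or named contig-length vector (for `@SQ`).
#' @param path output `.sam` path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, genome, path) {
  cl <- contig_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(cl), cl))
  a <- alignments
  qname <- if (is.na(a$umi[1]) || !nrow(a)) a$read_id
           else paste0(a$read_id, "_", a$umi)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:1",
                 qname, ifelse(a$align_strand == "+", 0L, 16L), a$chrom,
                 a$start + 1L, a$mapped_length,
                 if ("seq" %in% names(a)) a$seq else rep("*", nrow(a)))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Remove alignments on decoy (rRNA-like) contigs
#'
#' @param alignments alignment tibble.
#' @param decoy_contigs character vector of decoy contig names.
#' @return Filtered tibble; attribute `"n_removed"` counts removals.
#' @export
filter_decoy <- function(alignments, decoy_contigs) {
  keep <- !alignments$chrom %in% decoy_contigs
  out <- alignments[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' UMI-exact deduplication to usable reads
#'
#' Keeps one representative per (chrom, 5' position on the alignment strand,
#' alignment strand, exact UMI string); UMIs are compared verbatim with no
#' clustering. The representative is the first record in (position, UMI,
#' read id) order, a deterministic tie-break. Idempotent.
#'
#' @param alignments alignment tibble with populated `umi`.
#' @return Deduplicated tibble; attribute `"n_removed"` counts duplicates.
#' @export
deduplicate <- function(alignments) {
  bad <- is.na(alignments$umi) | alignments$umi == ""
  if (any(bad)) {
    abort(sprintf("missing UMI for read(s): %s",
                  paste(head(alignments$read_id[bad], 3L), collapse = ", ")))
  }
  out <- alignments %>%
    mutate(.pos5 = ifelse(.data$align_strand == "+", .data$start, .data$end)) %>%
    arrange(.data$chrom, .data$.pos5, .data$align_strand, .data$umi,
            .data$read_id) %>%
    distinct(.data$chrom, .data$.pos5, .data$align_strand, .data$umi,
             .keep_all = TRUE) %>%
    select(-".pos5")
  attr(out, "n_removed") <- nrow(alignments) - nrow(out)
  out
}

#' Uniform subsampling of alignments without replacement
#'
#' @param alignments alignment tibble.
#' @param n number to keep; must not exceed the input size.
#' @param seed integer seed (private RNG stream; deterministic).
#' @return Subsampled tibble in original row order.
#' @export
subsample_alignments <- function(alignments, n, seed) {
  if (n > nrow(alignments)) {
    abort(sprintf("cannot subsample %d from %d alignments", n,
                  nrow(alignments)))
  }
  idx <- with_seed(seed, sort(sample.int(nrow(alignments), n)))
  alignments[idx, ]
}
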