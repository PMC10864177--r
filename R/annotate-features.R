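FEATURE_LEVELS <- c("three_prime_utr", "five_prime_utr", "CDS",
                    "noncoding_exon", "intron", "intergenic")

#' Build a strand-aware feature index from an annotation
#'
#' Collects gene spans and their 5'UTR/CDS/3'UTR/noncoding-exon/intron
#' pieces for overlap queries. When a gene has several transcripts (GTF
#' input), the longest transcript (summed exon length) defines the UTR/CDS
#' partition. Intergenic space is the complement of gene spans.
#'
#' @param x an `artr_genome` from [build_reference()], or a GTF file path.
#' @return Object of class `artr_features`: `genes` and `features` tibbles
#'   (0-based half-open).
#' @export
feature_index <- function(x) {
  if (inherits(x, "artr_genome")) {
    genes <- x$genes %>%
      select("gene_id", "chrom", "start", "end", "strand", "protein_coding")
    feats <- x$features
  } else {
    imported <- import_gtf_features(x)
    genes <- imported$genes
    feats <- imported$features
  }
  structure(list(genes = genes, features = feats), class = "artr_features")
}

# Reduce a GTF to the per-gene feature table, keeping the longest transcript.
import_gtf_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = if ("transcript_id" %in% names(S4Vectors::mcols(gr))) {
      gr$transcript_id
    } else {
      NA_character_
    }
  )
  gene_rows <- df %>% filter(.data$type == "gene")
  if (nrow(gene_rows) == 0L) {
    gene_rows <- df %>%
      group_by(.data$gene_id) %>%
      summarise(chrom = .data$chrom[1], start = min(.data$start),
                end = max(.data$end), strand = .data$strand[1],
                .groups = "drop")
  }
  tx_len <- df %>%
    filter(.data$type == "exon", !is.na(.data$transcript_id)) %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(len = sum(.data$end - .data$start), .groups = "drop") %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$len), .data$transcript_id) %>%
    slice(1L) %>%
    ungroup()
  keep_tx <- df %>%
    dplyr::semi_join(tx_len, by = c("gene_id", "transcript_id"))

  feats <- list()
  for (g in unique(gene_rows$gene_id)) {
    gt <- keep_tx %>% filter(.data$gene_id == g)
    grow <- gene_rows %>% filter(.data$gene_id == g)
    exons <- gt %>% filter(.data$type == "exon") %>% arrange(.data$start)
    cds <- gt %>% filter(.data$type == "CDS")
    pieces <- partition_exons(exons, cds)
    introns <- interval_complement(grow$start, grow$end, exons)
    feats[[g]] <- bind_rows(
      pieces %>% select("chrom", "start", "end", "strand", "feature",
                        "gene_id", "transcript_id"),
      if (nrow(introns) > 0) {
        introns %>% mutate(chrom = grow$chrom, strand = grow$strand,
                           feature = "intron", gene_id = g,
                           transcript_id = NA_character_)
      })
  }
  genes <- gene_rows %>%
    left_join(tx_len %>% select("gene_id"), by = "gene_id") %>%
    mutate(protein_coding = .data$gene_id %in%
             (keep_tx %>% filter(.data$type == "CDS") %>% pull("gene_id"))) %>%
    select("gene_id", "chrom", "start", "end", "strand", "protein_coding")
  list(genes = genes, features = bind_rows(feats) %>% arrange(.data$start))
}

# Split a transcript's exons into 5'UTR/CDS/3'UTR pieces from the CDS span
# (UTR rows in the GTF are ignored; the partition is derived). Exonic bases
# upstream of the CDS in transcript orientation are 5'UTR, downstream 3'UTR.
# Genes without CDS rows are noncoding.
partition_exons <- function(exons, cds) {
  if (nrow(cds) == 0L) {
    return(exons %>% mutate(feature = "noncoding_exon"))
  }
  lo <- min(cds$start); hi <- max(cds$end)
  plus <- exons$strand[1] == "+"
  out <- list()
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    segs <- tibble(
      start = c(e$start, max(e$start, lo), max(e$start, hi)),
      end = c(min(e$end, lo), min(e$end, hi), e$end),
      feature = c(if (plus) "five_prime_utr" else "three_prime_utr", "CDS",
                  if (plus) "three_prime_utr" else "five_prime_utr"))
    out[[i]] <- segs %>%
      filter(.data$end > .data$start) %>%
      mutate(chrom = e$chrom, strand = e$strand, gene_id = e$gene_id,
             transcript_id = e$transcript_id)
  }
  bind_rows(out)
}

# gaps of [start, end) not covered by the (sorted, disjoint) intervals in tbl
interval_complement <- function(start, end, tbl) {
  if (nrow(tbl) == 0L) return(tibble(start = start, end = end))
  s <- sort(tbl$start); e <- sort(tbl$end)
  gap_s <- c(start, e)
  gap_e <- c(s, end)
  keep <- gap_e > gap_s
  tibble(start = gap_s[keep], end = gap_e[keep])
}

features_granges <- function(index) {
  f <- index$features
  GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start + 1L, f$end),
                         strand = f$strand, feature = f$feature,
                         gene_id = f$gene_id)
}

#' Assign peaks to genomic features by longest overlap
#'
#' Strand-aware: only features on the peak's strand compete. The label is
#' the feature category with the largest total overlap in base pairs; exact
#' ties break by the fixed precedence 3'UTR > 5'UTR > CDS > noncoding exon >
#' intron. Peaks overlapping no same-strand feature are intergenic.
#'
#' @param peaks peak tibble (needs `chrom`, `start`, `end`, `strand`).
#' @param index an [feature_index()] object.
#' @return `peaks` with `feature` (factor over the six canonical labels) and
#'   `gene_id` (NA for intergenic) columns added.
#' @export
assign_peaks <- function(peaks, index) {
  if (nrow(peaks) == 0L) {
    return(peaks %>% mutate(feature = factor(character(0),
                                             levels = FEATURE_LEVELS),
                            gene_id = character(0)))
  }
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end),
                               strand = peaks$strand)
  ft <- features_granges(index)
  ov <- GenomicRanges::findOverlaps(pk, ft, ignore.strand = FALSE)
  olap <- IRanges::width(IRanges::pintersect(
    pk[S4Vectors::queryHits(ov)], ft[S4Vectors::subjectHits(ov)]))
  cand <- tibble(
    peak = S4Vectors::queryHits(ov),
    feature = ft$feature[S4Vectors::subjectHits(ov)],
    gene_id = ft$gene_id[S4Vectors::subjectHits(ov)],
    bp = olap
  ) %>%
    group_by(.data$peak, .data$feature, .data$gene_id) %>%
    summarise(bp = sum(.data$bp), .groups = "drop") %>%
    mutate(feature = factor(.data$feature, levels = FEATURE_LEVELS)) %>%
    group_by(.data$peak) %>%
    arrange(dplyr::desc(.data$bp), .data$feature, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup()
  feature <- factor(rep("intergenic", nrow(peaks)), levels = FEATURE_LEVELS)
  gene_id <- rep(NA_character_, nrow(peaks))
  feature[cand$peak] <- cand$feature
  gene_id[cand$peak] <- cand$gene_id
  peaks %>% mutate(feature = feature, gene_id = gene_id)
}

#' Per-feature fractions of usable reads
#'
#' Each read is assigned by the feature containing its 5' base (transcript
#' orientation, strand-aware); the six canonical fractions sum to 1.
#'
#' @param alignments usable-read tibble.
#' @param index an [feature_index()] object.
#' @return Tibble `feature`, `n`, `fraction` over all six labels.
#' @export
assign_reads <- function(alignments, index) {
  if (nrow(alignments) == 0L) abort("empty read set: nothing to assign")
  pos <- ifelse(alignments$transcript_strand == "+",
                alignments$start, alignments$end - 1L)
  pt <- GenomicRanges::GRanges(alignments$chrom,
                               IRanges::IRanges(pos + 1L, pos + 1L),
                               strand = alignments$transcript_strand)
  ft <- features_granges(index)
  ov <- GenomicRanges::findOverlaps(pt, ft, ignore.strand = FALSE)
  lab <- tibble(read = S4Vectors::queryHits(ov),
                feature = factor(ft$feature[S4Vectors::subjectHits(ov)],
                                 levels = FEATURE_LEVELS)) %>%
    arrange(.data$read, .data$feature) %>%
    distinct(.data$read, .keep_all = TRUE)
  feature <- factor(rep("intergenic", nrow(alignments)),
                    levels = FEATURE_LEVELS)
  feature[lab$read] <- lab$feature
  tibble(feature = factor(FEATURE_LEVELS, levels = FEATURE_LEVELS)) %>%
    left_join(tibble(feature = feature) %>% count(.data$feature),
              by = "feature") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           fraction = .data$n / sum(.data$n))
}

#' Count usable reads per gene (5' base in gene span, strand-matched)
#'
#' @param alignments usable-read tibble.
#' @param index an [feature_index()] object (or `artr_genome`).
#' @return Tibble `gene_id`, `n` covering every annotated gene (zeros kept);
#'   attribute `"depth"` is the library's usable-read count.
#' @export
count_gene_reads <- function(alignments, index) {
  if (inherits(index, "artr_genome")) index <- feature_index(index)
  genes <- index$genes
  pos <- ifelse(alignments$transcript_strand == "+",
                alignments$start, alignments$end - 1L)
  pt <- GenomicRanges::GRanges(alignments$chrom,
                               IRanges::IRanges(pos + 1L, pos + 1L),
                               strand = alignments$transcript_strand)
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end),
                               strand = genes$strand)
  ov <- GenomicRanges::findOverlaps(pt, gn, ignore.strand = FALSE)
  # resolve multi-gene hits by longest-overlap gene (ties by gene order)
  hit <- tibble(read = S4Vectors::queryHits(ov),
                gene = S4Vectors::subjectHits(ov),
                len = genes$end[S4Vectors::subjectHits(ov)] -
                  genes$start[S4Vectors::subjectHits(ov)]) %>%
    arrange(.data$read, dplyr::desc(.data$len), .data$gene) %>%
    distinct(.data$read, .keep_all = TRUE)
  out <- genes %>%
    select("gene_id") %>%
    left_join(tibble(gene = hit$gene) %>%
                count(.data$gene) %>%
                mutate(gene_id = genes$gene_id[.data$gene]) %>%
                select("gene_id", "n"),
              by = "gene_id") %>%
    mutate(n = as.integer(ifelse(is.na(.data$n), 0L, .data$n)))
  attr(out, "depth") <- nrow(alignments)
  out
}

#' Pad peaks symmetrically (e.g. for motif-discovery export)
#'
#' @param peaks peak tibble.
#' @param genome contig-length source for clipping.
#' @param pad extension (nt) added on both sides, floored at 0 and capped at
#'   the contig end.
#' @return Peaks with widened `start`/`end`.
#' @export
extend_peaks <- function(peaks, genome, pad = 20L) {
  cl <- contig_lengths(genome)
  peaks %>%
    mutate(start = pmax(.data$start - pad, 0L),
           end = pmin(.data$end + pad, unname(cl[.data$chrom])))
}
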