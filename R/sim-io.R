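# Serialisation of simulated truth and libraries: FASTA/GTF for the genome,
# FASTQ for reads, BED6 for sites, TSV for expression/enrichment/manifest.
# FASTQ is written uncompressed so that repeated runs are byte-identical.

#' Write paired reads to FASTQ
#'
#' @param reads tibble with `id`, `seq1`, `qual1`, `seq2`, `qual2` (an
#'   [simulate_library()] `reads` element or a [pool_libraries()] pool).
#' @param r1_path,r2_path output paths for read 1 / read 2.
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  if (inherits(reads, "artr_library")) reads <- reads$reads
  for (side in 1:2) {
    x <- Biostrings::DNAStringSet(reads[[paste0("seq", side)]])
    names(x) <- reads$id
    Biostrings::writeXStringSet(
      x, if (side == 1) r1_path else r2_path, format = "fastq",
      qualities = Biostrings::BStringSet(reads[[paste0("qual", side)]]))
  }
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read tibble
#'
#' @param r1_path,r2_path FASTQ paths (plain or gzip).
#' @return Tibble with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    tibble(id = sub(" .*$", "", names(x)),
           seq = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1_path); b <- rd(r2_path)
  if (!identical(a$id, b$id)) abort("read 1 / read 2 ids do not pair up")
  tibble(id = a$id, seq1 = a$seq, qual1 = a$qual,
         seq2 = b$seq, qual2 = b$qual)
}

#' Write the genome of a truth object as FASTA + GTF
#'
#' GTF features are emitted in the 1-based closed convention with `gene_id`
#' and `transcript_id` attributes; the volatile `##date` header is dropped so
#' identical runs produce identical bytes.
#'
#' @param genome an `artr_genome`.
#' @param fasta_path,gtf_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, gtf_path) {
  Biostrings::writeXStringSet(genome$seq, fasta_path)
  exonic <- c("five_prime_utr", "CDS", "three_prime_utr", "noncoding_exon")
  ex <- genome$features %>%
    filter(.data$feature %in% exonic) %>%
    arrange(.data$gene_id, .data$start) %>%
    group_by(.data$gene_id) %>%
    mutate(exon_grp = cumsum(c(TRUE, .data$start[-1] != .data$end[-n()]))) %>%
    group_by(.data$gene_id, .data$exon_grp) %>%
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), strand = .data$strand[1],
              transcript_id = .data$transcript_id[1], .groups = "drop") %>%
    mutate(feature = "exon")
  feats <- bind_rows(
    genome$genes %>%
      mutate(feature = "gene", transcript_id = NA_character_) %>%
      select("chrom", "start", "end", "strand", "feature", "gene_id",
             "transcript_id"),
    genome$genes %>%
      mutate(feature = "transcript",
             transcript_id = paste0(.data$gene_id, ".t1")) %>%
      select("chrom", "start", "end", "strand", "feature", "gene_id",
             "transcript_id"),
    ex %>% select("chrom", "start", "end", "strand", "feature", "gene_id",
                  "transcript_id"),
    genome$features %>% filter(.data$feature == "CDS")
  ) %>% arrange(.data$gene_id, .data$start)
  gr <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start + 1L, feats$end),
    strand = feats$strand, type = feats$feature,
    gene_id = feats$gene_id, transcript_id = feats$transcript_id)
  rtracklayer::export(gr, gtf_path, format = "gtf")
  lines <- readLines(gtf_path)
  writeLines(lines[!startsWith(lines, "##date")], gtf_path)
  invisible(c(fasta_path, gtf_path))
}

#' Write truth tables (sites BED6, expression/enrichment TSV)
#'
#' Sites are written 0-based half-open with the occupancy in the BED score
#' column; the tables round-trip losslessly through [read_truth()].
#'
#' @param truth an [build_reference()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- truth$sites
  if (nrow(s) > 0) {
    gr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start + 1L, s$end),
                                 strand = s$strand, name = s$site_id,
                                 score = s$occupancy)
    rtracklayer::export(gr, file.path(dir, "sites.bed"), format = "bed")
  } else {
    writeLines(character(0), file.path(dir, "sites.bed"))
  }
  readr::write_tsv(truth$sites %>% select("site_id", "gene_id"),
                   file.path(dir, "site_genes.tsv"))
  readr::write_tsv(truth$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(truth$enrichment, file.path(dir, "enrichment.tsv"))
  invisible(dir)
}

#' Read truth tables written by [write_truth()]
#'
#' @param dir directory containing `sites.bed`, `site_genes.tsv`,
#'   `expression.tsv`, `enrichment.tsv`.
#' @return A list with `sites`, `expression` and `enrichment` tibbles.
#' @export
read_truth <- function(dir) {
  bed <- file.path(dir, "sites.bed")
  sites <- if (file.size(bed) > 0) {
    read_bed(bed) %>%
      rename(site_id = "name", occupancy = "score") %>%
      left_join(readr::read_tsv(file.path(dir, "site_genes.tsv"),
                                show_col_types = FALSE),
                by = "site_id") %>%
      select("site_id", "gene_id", "chrom", "start", "end", "strand",
             "occupancy")
  } else {
    tibble(site_id = character(0), gene_id = character(0),
           chrom = character(0), start = integer(0), end = integer(0),
           strand = character(0), occupancy = numeric(0))
  }
  list(sites = sites,
       expression = readr::read_tsv(file.path(dir, "expression.tsv"),
                                    show_col_types = FALSE),
       enrichment = readr::read_tsv(file.path(dir, "enrichment.tsv"),
                                    show_col_types = FALSE))
}

#' Import a BED file as a 0-based half-open tibble
#'
#' @param path BED3/BED6 file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc) > 0) out <- bind_cols(out, as_tibble(mc))
  out %>% select("chrom", "start", "end", dplyr::any_of(c("name", "score")),
                 "strand")
}

#' Export intervals to BED6
#'
#' @param x tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1L, x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*",
    name = if ("name" %in% names(x)) x$name else paste0("region_", seq_len(nrow(x))),
    score = if ("score" %in% names(x)) x$score else 0)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
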