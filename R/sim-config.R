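#' Simulation configuration for synthetic RBP binding-site libraries
#'
#' Bundles every knob of the synthetic-data generator: a toy annotated
#' genome with planted, motif-anchored binding sites, and paired-end
#' libraries that emulate an antibody-guided in situ RT assay (8-nt UMI at
#' the start of read 1, 8-nt sample barcode at the start of read 2, adapter
#' read-through, PCR duplication, expression-proportional background).
#'
#' The IP library is a two-component mixture: with probability
#' `ip_signal_fraction` a molecule originates from a planted site (its
#' 5' start drawn from a Gaussian kernel of sd `site_kernel_sd` centred on
#' the site anchor, sites weighted by occupancy x gene expression),
#' otherwise from expression-proportional background uniform within a gene.
#' Input libraries use a site probability of zero.
#'
#' @param seed integer seed; identical configs give byte-identical outputs.
#' @param n_genes number of non-overlapping genes placed on the main contig.
#' @param gene_length_range integer range (nt) for gene lengths.
#' @param exons_per_gene integer range for the number of exons per gene.
#' @param motif binding motif in RNA or DNA alphabet (default `"UGCAUG"`).
#' @param n_sites total number of planted sites; ignored when
#'   `sites_per_gene` is given.
#' @param sites_per_gene optional exact per-gene site count; `0` plants no
#'   sites anywhere.
#' @param site_occupancy relative site strength multiplier, recycled across
#'   genes; scales a gene's chance of emitting site-origin reads.
#' @param site_kernel_sd sd (nt) of the read-start kernel around a site.
#' @param ip_signal_fraction probability that an IP molecule is site-origin.
#' @param expression_meanlog,expression_sdlog log-normal parameters of
#'   per-gene expression weights.
#' @param read_length sequenced read length (nt); must exceed
#'   `umi_length + 24`.
#' @param insert_length_range range (nt) of cDNA insert lengths.
#' @param n_reads reads per simulated library.
#' @param pcr_duplication_rate probability that a read is a PCR duplicate of
#'   a previously generated molecule.
#' @param barcode_table named character vector, sample label -> 8-nt barcode.
#' @param adapter_seq 3' adapter sequenced when a fragment is shorter than
#'   the read.
#' @param umi_length UMI length (nt), default 8.
#' @param error_rate per-base substitution rate applied to the cDNA insert.
#' @param gene_gap_range intergenic gap range (nt) between consecutive genes.
#' @param coding_fraction fraction of genes flagged protein-coding.
#' @param decoy_fraction fraction of molecules drawn from the rRNA-like
#'   decoy contig.
#' @param decoy_length length (nt) of the decoy contig.
#' @param site_ct_bias optional probability of C/T (on the sense strand) for
#'   bases within 40 nt of a planted site, emulating pyrimidine-rich sites;
#'   `NULL` leaves the background composition untouched.
#' @param strandedness `"reverse"` (read 1 is cDNA sense, the reverse
#'   complement of the RNA) or `"forward"`.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       gene_length_range = c(1500L, 3000L),
                       exons_per_gene = c(1L, 4L),
                       motif = "UGCAUG",
                       n_sites = n_genes,
                       sites_per_gene = NULL,
                       site_occupancy = 1,
                       site_kernel_sd = 50,
                       ip_signal_fraction = 0.5,
                       expression_meanlog = 0,
                       expression_sdlog = 1,
                       read_length = 76L,
                       insert_length_range = c(40L, 80L),
                       n_reads = 1e5,
                       pcr_duplication_rate = 0.2,
                       barcode_table = c(S1 = "AAAACCCC", S2 = "CCCCAAAA",
                                         S3 = "GGGGTTTT", S4 = "TTTTGGGG"),
                       adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAG",
                       umi_length = 8L,
                       error_rate = 0,
                       gene_gap_range = c(300L, 1500L),
                       coding_fraction = 0.8,
                       decoy_fraction = 0,
                       decoy_length = 2000L,
                       site_ct_bias = NULL,
                       strandedness = c("reverse", "forward")) {
  strandedness <- match.arg(strandedness)
  motif_dna <- rna2dna(motif)
  if (!nzchar(motif_dna) || !grepl("^[ACGT]+$", motif_dna)) {
    abort("`motif` must be a non-empty string over A/C/G/U/T")
  }
  for (p in c("ip_signal_fraction", "pcr_duplication_rate", "error_rate",
              "coding_fraction", "decoy_fraction")) {
    assert_probability(get(p), p)
  }
  if (!is.null(site_ct_bias)) assert_probability(site_ct_bias, "site_ct_bias")
  if (read_length <= umi_length + 24) {
    abort("`read_length` must exceed `umi_length` + 24")
  }
  if (!grepl("^[ACGT]+$", adapter_seq)) abort("`adapter_seq` must be DNA")
  if (is.null(names(barcode_table)) ||
      any(nchar(barcode_table) != nchar(barcode_table[1]))) {
    abort("`barcode_table` must be a named vector of equal-length barcodes")
  }
  if (!is.null(sites_per_gene)) {
    n_sites <- as.integer(n_genes * sites_per_gene)
  }
  if (gene_length_range[1] < 500L) {
    abort("genes shorter than 500 nt leave no room for sites and inserts")
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    exons_per_gene = as.integer(exons_per_gene),
    motif = motif_dna, n_sites = as.integer(n_sites),
    site_occupancy = site_occupancy, site_kernel_sd = site_kernel_sd,
    ip_signal_fraction = ip_signal_fraction,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    read_length = as.integer(read_length),
    insert_length_range = as.integer(insert_length_range),
    n_reads = as.integer(n_reads),
    pcr_duplication_rate = pcr_duplication_rate,
    barcode_table = barcode_table, adapter_seq = adapter_seq,
    umi_length = as.integer(umi_length), error_rate = error_rate,
    gene_gap_range = as.integer(gene_gap_range),
    coding_fraction = coding_fraction,
    decoy_fraction = decoy_fraction, decoy_length = as.integer(decoy_length),
    site_ct_bias = site_ct_bias, strandedness = strandedness
  ), class = "sim_config")
}
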