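test_that("peak feature assignment uses longest overlap with tie precedence", {
  idx <- toy_index()
  pk <- function(s, e, strand = "+") {
    tibble::tibble(chrom = "chr1", start = s, end = e, strand = strand)
  }
  # 3'UTR overlap 30 bp vs intron 50 bp (on gB scale): construct on gA:
  # [470, 550): CDS 30 bp, intron 50 bp -> intron wins by length
  out <- assign_peaks(pk(470L, 550L), idx)
  expect_equal(as.character(out$feature), "intron")
  expect_equal(out$gene_id, "gA")
  # exact 40/40 bp tie of CDS and intron -> CDS by precedence
  out <- assign_peaks(pk(460L, 540L), idx)
  expect_equal(as.character(out$feature), "CDS")
  # fully intergenic peak
  out <- assign_peaks(pk(1200L, 1300L), idx)
  expect_equal(as.character(out$feature), "intergenic")
  expect_true(is.na(out$gene_id))
  # strand mismatch means intergenic even over a gene body
  out <- assign_peaks(pk(300L, 400L, strand = "-"), idx)
  expect_equal(as.character(out$feature), "intergenic")
  # labels are always within the six canonical ones
  out <- assign_peaks(dplyr::bind_rows(pk(120L, 180L), pk(2100L, 2200L, "-"),
                                       pk(720L, 800L)), idx)
  expect_true(all(out$feature %in% c("three_prime_utr", "five_prime_utr",
                                     "CDS", "noncoding_exon", "intron",
                                     "intergenic")))
  expect_equal(as.character(out$feature),
               c("five_prime_utr", "noncoding_exon", "three_prime_utr"))
})

test_that("read feature fractions sum to one and flag empty input", {
  idx <- toy_index()
  aln <- tibble::tibble(
    read_id = paste0("r", 1:4), chrom = "chr1",
    start = c(520L, 520L, 2450L, 110L),
    end = c(560L, 560L, 2490L, 150L),
    transcript_strand = c("+", "+", "-", "+"))
  fr <- assign_reads(aln, idx)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$n[fr$feature == "intron"], 3L)  # 5' base of r3 is its end-1
  expect_equal(fr$n[fr$feature == "five_prime_utr"], 1L)
  expect_error(assign_reads(aln[0, ], idx), "empty read set")
})

test_that("reads from intron-planted sites raise the intronic fraction", {
  cfg <- sim_config(seed = 31L, n_genes = 10L, n_sites = 10L,
                    n_reads = 30000L, exons_per_gene = c(3L, 4L),
                    gene_length_range = c(2500L, 4000L),
                    pcr_duplication_rate = 0)
  tt <- build_reference(cfg)
  idx <- feature_index(tt$genome)
  intronic <- function(s, e, gid) {
    f <- idx$features
    any(f$gene_id == gid & f$feature == "intron" & s >= f$start & e <= f$end)
  }
  keep <- vapply(seq_len(nrow(tt$sites)), function(i) {
    intronic(tt$sites$start[i], tt$sites$end[i], tt$sites$gene_id[i])
  }, logical(1))
  skip_if(sum(keep) < 2, "seed placed too few intronic sites")
  tt$sites <- tt$sites[keep, ]
  ip <- manifest_alignments(simulate_library(tt, "IP", cfg, seed = 61L))
  inp <- manifest_alignments(simulate_library(tt, "input", cfg, seed = 62L))
  f_ip <- assign_reads(ip, idx)
  f_in <- assign_reads(inp, idx)
  expect_gt(f_ip$fraction[f_ip$feature == "intron"],
            f_in$fraction[f_in$feature == "intron"])
})

test_that("motif distances are centre-to-centre with an Inf sentinel", {
  seqs <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("A", 100), "TGCATG", strrep("A", 94)),
    chrB = strrep("A", 200)))
  pk <- tibble::tibble(chrom = c("chrA", "chrA", "chrB"),
                       start = c(97L, 140L, 10L), end = c(109L, 160L, 50L),
                       strand = "+")
  out <- motif_distance(pk, "UGCAUG", seqs)
  expect_equal(out$motif_distance[1], 0)          # peak centred on the motif
  expect_equal(out$motif_distance[2], abs(150 - 103))
  expect_true(is.infinite(out$motif_distance[3])) # no occurrence on chrB
  sm <- summarize_motif_distance(out, d = c(10, 100))
  expect_equal(attr(sm, "n_excluded"), 1L)
  expect_equal(sm$fraction, c(0.5, 1))
  # strand-aware: a "-" peak must use reverse-complement occurrences
  pk_m <- tibble::tibble(chrom = "chrA", start = 97L, end = 109L,
                         strand = "-")
  expect_true(is.infinite(motif_distance(pk_m, "UGCAUG",
                                          seqs)$motif_distance))
})

test_that("CU-region scanning matches brute-force window enumeration", {
  set.seed(77)
  n <- 30000L
  chr <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(0.15, 0.35, 0.15, 0.35)), collapse = "")
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chrZ",
                          start = c(0L, 15000L), end = c(14000L, 30000L),
                          strand = c("+", "-"), protein_coding = TRUE)
  idx <- structure(list(genes = genes, features = genes[0, ]),
                   class = "artr_features")
  seqs <- Biostrings::DNAStringSet(c(chrZ = chr))
  got <- scan_cu_regions(seqs, idx, width = 80L, ct_min = 0.70)
  want <- dplyr::bind_rows(lapply(1:2, function(i) {
    brute_cu_regions(chr, genes[i, ], 80L, 0.70) |>
      dplyr::mutate(gene_id = genes$gene_id[i])
  }))
  expect_equal(got[, c("start", "end", "gene_id")] |> as.data.frame(),
               want[, c("start", "end", "gene_id")] |> as.data.frame())
})

test_that("CU-window boundary is strict and pure-C runs are found", {
  chr <- paste0(strrep("A", 50), strrep("C", 80), strrep("A", 200))
  genes <- tibble::tibble(gene_id = "g", chrom = "c", start = 0L, end = 330L,
                          strand = "+", protein_coding = TRUE)
  idx <- structure(list(genes = genes, features = genes[0, ]),
                   class = "artr_features")
  out <- scan_cu_regions(Biostrings::DNAStringSet(c(c = chr)), idx)
  expect_equal(nrow(out), 1L)
  expect_true(out$start <= 50 && out$end >= 130)
  # exactly 56/80 CT (70.0%) is excluded by the strict inequality
  chr2 <- paste0(strrep("CT", 28), strrep("AG", 12), strrep("A", 100))
  out2 <- scan_cu_regions(
    Biostrings::DNAStringSet(c(c = chr2)),
    structure(list(genes = genes |> dplyr::mutate(end = 180L),
                   features = genes[0, ]), class = "artr_features"))
  expect_equal(nrow(out2), 0L)
})

test_that("read CT content and motif fraction follow the sense strand", {
  rd <- tibble::tibble(id = c("a", "b"),
                       seq = c("CCTT", "AAGG"))
  out <- read_seq_stats(rd, "UGCAUG", strandedness = "forward")
  expect_equal(out$ct_fraction, c(1, 0))
  expect_equal(attr(out, "motif_fraction"), 0)
  # reverse strandedness: the sense sequence is the reverse complement
  rd2 <- tibble::tibble(id = "c",
                        seq = as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString("AATGCATGAA"))))
  out2 <- read_seq_stats(rd2, "UGCAUG")
  expect_true(out2$has_motif)
  expect_error(read_seq_stats(rd[0, ], "UGCAUG"), "empty")
})

test_that("IP reads from CU-rich sites show higher CT content than input", {
  cfg <- sim_config(seed = 37L, n_genes = 8L, n_sites = 8L, n_reads = 20000L,
                    site_ct_bias = 0.9, site_kernel_sd = 15,
                    pcr_duplication_rate = 0)
  tt <- build_reference(cfg)
  lib_ip <- simulate_library(tt, "IP", cfg, seed = 71L)
  lib_in <- simulate_library(tt, "input", cfg, seed = 72L)
  trm_ip <- trim_reads(lib_ip$reads, cfg$adapter_seq)
  trm_in <- trim_reads(lib_in$reads, cfg$adapter_seq)
  ct_ip <- mean(read_seq_stats(trm_ip, cfg$motif)$ct_fraction)
  ct_in <- mean(read_seq_stats(trm_in, cfg$motif)$ct_fraction)
  expect_gt(ct_ip, ct_in)
})

test_that("profile matrices are anchored, oriented and zero-padded", {
  cov <- fake_coverage(list(chrS = rep(2, 1000)), "+", 100L)
  # uniform track -> flat mean profile
  pr <- profile_matrix(cov, tibble::tibble(chrom = "chrS", pos = 500L),
                       flank = 50L, normalize = FALSE)
  expect_true(all(pr$mean == 2))
  expect_equal(length(pr$mean), 100L)
  # single anchor: mean equals the row
  expect_equal(pr$mean, as.numeric(pr$matrix[1, ]))
  # ramp + minus strand: row is reversed
  cov2 <- fake_coverage(list(chrS = seq_len(1000)), "+", 100L)
  prp <- profile_matrix(cov2, tibble::tibble(chrom = "chrS", pos = 500L,
                                             strand = "+"), 10L,
                        normalize = FALSE)
  prm <- profile_matrix(cov2, tibble::tibble(chrom = "chrS", pos = 500L,
                                             strand = "-"), 10L,
                        normalize = FALSE)
  expect_equal(as.numeric(prm$matrix[1, ]), rev(as.numeric(prp$matrix[1, ])))
  # out-of-bounds anchor: padded with zeros and flagged
  pr0 <- profile_matrix(cov, tibble::tibble(chrom = "chrS", pos = 5L), 20L,
                        normalize = FALSE)
  expect_true(pr0$clipped[1])
  expect_equal(as.numeric(pr0$matrix[1, 1:15]), rep(0, 15))
})

test_that("mean IP profile peaks at the planted site centre", {
  cfg <- sim_config(seed = 41L, n_genes = 10L, n_sites = 10L,
                    n_reads = 50000L, gene_length_range = c(3000L, 5000L),
                    insert_length_range = c(40L, 60L),
                    pcr_duplication_rate = 0)
  tt <- build_reference(cfg)
  ip <- manifest_alignments(simulate_library(tt, "IP", cfg, seed = 81L))
  s <- tt$sites[tt$sites$strand == "+", ]
  # extension matched to the mean fragment length centres the pileup
  cov <- build_coverage(ip, tt$genome, "+", extsize = 50L)
  pr <- profile_matrix(cov, tibble::tibble(chrom = s$chrom,
                                           pos = s$start + 3L,
                                           strand = s$strand), flank = 300L)
  peak_at <- pr$positions[which.max(pr$mean)]
  expect_lte(abs(peak_at), 10)
})

test_that("metagene densities are normalised and concentrate where planted", {
  idx <- toy_index()
  # peaks at CDS midpoints of gA (CDS pieces [200,500) + [600,700))
  pk <- tibble::tibble(chrom = "chr1", start = c(290L, 320L, 350L),
                       end = c(310L, 340L, 370L), strand = "+")
  mg <- metagene_peaks(pk, idx, bins = c(5L, 10L, 5L))
  expect_equal(sum(mg$density), 1)
  expect_true(all(mg$density[mg$segment != "CDS"] == 0))
  cds <- mg[mg$segment == "CDS", ]
  expect_true(all(cds$density[cds$density > 0] > 0))
  # all mass in the first half of the CDS (centres at tx 190-260 of 400)
  expect_equal(sum(cds$density[1:5]), 1)
  expect_error(metagene_peaks(pk |> dplyr::mutate(start = 510L, end = 590L),
                              idx), "mRNA exonic")
})

test_that("metagene normalisation is preserved under peak subsampling", {
  idx <- toy_index()
  set.seed(5)
  pk <- tibble::tibble(chrom = "chr1",
                       start = sample(210:680, 40, replace = TRUE),
                       strand = "+") |>
    dplyr::mutate(end = start + 10L)
  m_all <- metagene_peaks(pk, idx)
  m_half <- metagene_peaks(pk[1:20, ], idx)
  expect_equal(sum(m_all$density), 1)
  expect_equal(sum(m_half$density), 1)
})

test_that("shuffled regions are length-matched, exonic and deterministic", {
  idx <- toy_index()
  pk <- tibble::tibble(chrom = "chr1", start = c(250L, 2100L),
                       end = c(330L, 2180L), strand = c("+", "-"))
  s1 <- shuffle_regions(pk, idx, seed = 9L)
  s2 <- shuffle_regions(pk, idx, seed = 9L)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_setequal(s1$end - s1$start, pk$end - pk$start)
  # a peak longer than every exonic interval is skipped with a report
  long <- tibble::tibble(chrom = "chr1", start = 0L, end = 5000L,
                         strand = "+")
  out <- shuffle_regions(long, idx, seed = 1L)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("shuffled placements are uniform over the exonic space", {
  idx <- toy_index()
  pk <- tibble::tibble(chrom = "chr1", start = rep(0L, 1000), end = 20L,
                       strand = "+")
  out <- shuffle_regions(pk, idx, seed = 33L)
  # merged exonic intervals: [100,500), [600,900), [2000,2400), [2600,3000)
  widths <- c(400, 300, 400, 400) - 20 + 1
  bins <- c(sum(out$start >= 100 & out$start < 500),
            sum(out$start >= 600 & out$start < 900),
            sum(out$start >= 2000 & out$start < 2400),
            sum(out$start >= 2600 & out$start < 3000))
  expect_equal(sum(bins), 1000L)
  p <- suppressWarnings(chisq.test(bins, p = widths / sum(widths))$p.value)
  expect_gt(p, 0.01)
})

test_that("site overlap respects slop and strand", {
  pk <- tibble::tibble(chrom = "c", start = 100L, end = 200L, strand = "+")
  site_in <- tibble::tibble(chrom = "c", start = 150L, end = 156L,
                            strand = "+")
  site_far <- tibble::tibble(chrom = "c", start = 450L, end = 456L,
                             strand = "+")
  expect_equal(site_overlap(pk, site_in)$percent, 100)
  expect_equal(site_overlap(pk, site_far, slop = 0L)$n_with_site, 0L)
  expect_equal(site_overlap(pk, site_far, slop = 300L)$n_with_site, 1L)
  expect_equal(site_overlap(pk, site_in |> dplyr::mutate(strand = "-")
                            )$n_with_site, 0L)
})

test_that("peak extension pads symmetrically and clips at contig bounds", {
  cl <- c(chrS = 1000)
  pk <- tibble::tibble(chrom = "chrS", start = c(100L, 5L, 950L),
                       end = c(150L, 40L, 990L), strand = "+")
  out <- extend_peaks(pk, cl, pad = 20L)
  expect_equal(out$start, c(80L, 0L, 930L))
  expect_equal(out$end, c(170L, 60L, 1000L))
  expect_true(all(out$end - out$start - (pk$end - pk$start) <= 40L))
})
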