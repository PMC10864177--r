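BC <- c(A = "AAAACCCC", B = "CCCCAAAA", C = "GGGGTTTT", D = "TTTTGGGG")
ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAG"

test_that("demultiplexing routes by read-2 prefix and partitions the input", {
  reads <- tibble::tibble(
    id = c("r1", "r2", "r3"),
    seq2 = c(paste0(BC[["A"]], "ACGT"),       # exact
             paste0("AAAACCCG", "ACGT"),      # distance 1 from A
             paste0("AGGGCCCG", "ACGT")))     # distance >1 from all
  d0 <- demultiplex(reads, BC, max_mismatch = 0L)
  expect_equal(d0$sample, c("A", "undetermined", "undetermined"))
  d1 <- demultiplex(reads, BC, max_mismatch = 1L)
  expect_equal(d1$sample, c("A", "A", "undetermined"))
  expect_equal(sum(demux_summary(d1)$n), nrow(reads))
})

test_that("ambiguous barcode tables are rejected", {
  expect_error(demultiplex(tibble::tibble(id = "r", seq2 = "AAAAAAAA"),
                           c(X = "AAAAAAAA", Y = "AAAAAATT"),
                           max_mismatch = 1L),
               "ambiguous")
})

test_that("a simulated multiplexed run demultiplexes exactly by manifest", {
  cfg <- sim_config(seed = 13L, n_genes = 6L, n_sites = 6L, n_reads = 2500L,
                    barcode_table = BC)
  tt <- build_reference(cfg)
  libs <- lapply(seq_along(BC), function(i) {
    simulate_library(tt, if (i <= 2) "IP" else "input", cfg,
                     seed = 30L + i, sample = names(BC)[i])
  })
  pool <- pool_libraries(libs)
  dmx <- demultiplex(pool$reads, BC, max_mismatch = 1L)
  got <- demux_summary(dmx)
  truth <- dplyr::count(pool$manifest, sample, name = "n_true")
  cmp <- dplyr::left_join(truth, got, by = "sample")
  expect_equal(cmp$n, cmp$n_true)
  expect_false("undetermined" %in% got$sample)
})

test_that("trimming matches a hand-constructed oracle", {
  umi <- "ACGTACGT"
  insert40 <- strrep("ACGTTGCA", 5)            # 40 nt, ends in A
  r <- function(seq) tibble::tibble(id = "r", seq = seq,
                                    qual = strrep("I", nchar(seq)))
  # UMI + 40-nt insert + full adapter -> 36-nt insert (40 - 4), UMI captured
  out <- trim_reads(r(paste0(umi, insert40, ADAPTER)), ADAPTER)
  expect_equal(out$seq, substr(insert40, 1, 36))
  expect_equal(out$umi, umi)
  # UMI + 20-nt insert + adapter -> discarded (20 - 4 < 24)
  out <- trim_reads(r(paste0(umi, substr(insert40, 1, 20), ADAPTER)), ADAPTER)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_discarded"), 1L)
  # no adapter, all Q40 -> read minus UMI minus 4 nt
  out <- trim_reads(r(paste0(umi, insert40)), ADAPTER)
  expect_equal(out$seq, substr(insert40, 1, 36))
  # partial terminal adapter (first 6 nt) is found at >= 3 nt overlap
  out <- trim_reads(r(paste0(umi, insert40, substr(ADAPTER, 1, 6))), ADAPTER)
  expect_equal(out$seq, substr(insert40, 1, 36))
  # one mismatch in a 30-nt adapter stays within the 10% tolerance
  mut <- paste0(substr(ADAPTER, 1, 10), "T", substr(ADAPTER, 12, 30))
  out <- trim_reads(r(paste0(umi, insert40, mut)), ADAPTER)
  expect_equal(out$seq, substr(insert40, 1, 36))
})

test_that("quality tail trimming removes low-quality and dark-G tails", {
  # last 6 bases below Q20: trimmed before adapter search
  seq <- paste0(strrep("A", 8), strrep("ACGTACTTACTTAGCA", 3), "ACATCA")
  qual <- paste0(strrep("I", 8 + 48), strrep("#", 6))
  out <- trim_reads(tibble::tibble(id = "r", seq = seq, qual = qual), ADAPTER)
  expect_equal(out$seq, substr(strrep("ACGTACTTACTTAGCA", 3), 1, 44))
  # trailing G run is treated as dark signal even at high quality
  seq2 <- paste0(strrep("A", 8), strrep("ACGTACTTACTTAGCA", 3), "GGGGGG")
  out2 <- trim_reads(tibble::tibble(id = "r", seq = seq2,
                                    qual = strrep("I", nchar(seq2))), ADAPTER)
  expect_equal(out2$seq, substr(strrep("ACGTACTTACTTAGCA", 3), 1, 44))
})

test_that("the fixture aligner honours strandedness and uniqueness", {
  set.seed(101)
  chr <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  # read = revcomp of the forward sequence at [500, 540)
  frag <- substr(chr, 501, 540)
  read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(frag)))
  rd <- tibble::tibble(id = "r1", seq = read, umi = "AAAAAAAA")
  aln <- align_exact(rd, genome)
  expect_equal(aln$start, 500L)
  expect_equal(aln$end, 540L)
  expect_equal(aln$align_strand, "-")
  expect_equal(aln$transcript_strand, "+")
  expect_true(aln$unique)
  # a read present at two loci is dropped
  chr2 <- paste0(chr, substr(chr, 401, 640))
  rd2 <- tibble::tibble(id = c("multi", "uniq"),
                        seq = c(substr(chr, 501, 540), substr(chr, 101, 140)),
                        umi = c("AAAAAAAA", "CCCCCCCC"))
  aln2 <- align_exact(rd2, Biostrings::DNAStringSet(c(chr1 = chr2)))
  expect_equal(aln2$read_id, "uniq")
  expect_equal(attr(aln2, "n_multimapped"), 1L)
  # missing contigs are an error at coverage time, empty reference here
  expect_error(align_exact(rd, Biostrings::DNAStringSet()), "no contigs")
})

test_that("an error-free simulated library aligns back to manifest loci", {
  cfg <- small_config()
  tt <- small_truth()
  lib <- small_ip_library()
  trm <- trim_reads(lib$reads, cfg$adapter_seq)
  aln <- align_exact(trm, tt$genome)
  m <- lib$manifest[match(aln$read_id, lib$manifest$read_id), ]
  pos5 <- ifelse(aln$align_strand == "+", aln$start, aln$end)
  expect_gte(mean(pos5 == m$pos5), 0.99)
  expect_gte(nrow(aln) / nrow(trm), 0.99)
  expect_true(all(aln$transcript_strand == m$transcript_strand))
  expect_true(all(aln$mapped_length >= 24))
})

test_that("1-mismatch alignment recovers reads with a single substitution", {
  set.seed(102)
  chr <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  starts <- seq(100, 4000, by = 120)
  reads <- vapply(starts, function(s) {
    x <- substr(chr, s + 1, s + 40)
    p <- 5 + (s %% 30)  # mismatch position varies across both halves
    cur <- substr(x, p, p)
    substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    x
  }, character(1))
  rd <- tibble::tibble(id = paste0("r", seq_along(starts)), seq = reads,
                       umi = "AAAAAAAA")
  aln0 <- align_exact(rd, genome, max_mismatch = 0L)
  aln1 <- align_exact(rd, genome, max_mismatch = 1L)
  expect_equal(nrow(aln0), 0L)
  expect_equal(sort(aln1$start), sort(as.integer(starts)))
})

test_that("SAM writing and re-ingestion preserve alignments", {
  tt <- small_truth()
  cfg <- small_config()
  lib <- small_ip_library()
  aln <- align_exact(trim_reads(lib$reads[1:300, ], cfg$adapter_seq),
                     tt$genome)
  d <- withr::local_tempdir()
  write_sam(aln, tt$genome, file.path(d, "a.sam"))
  back <- read_sam(file.path(d, "a.sam"))
  back <- back[match(paste0(aln$read_id, "_", aln$umi), back$read_id), ]
  expect_equal(back$start, aln$start)
  expect_equal(back$end, aln$end)
  expect_equal(back$align_strand, aln$align_strand)
  expect_equal(back$transcript_strand, aln$transcript_strand)
  expect_equal(back$umi, aln$umi)
  expect_error(read_sam(file.path(d, "a.sam"), contigs = "other_chrom"),
               "unknown contig")
})

test_that("decoy filtering removes rRNA-like contigs and reports counts", {
  aln <- tibble::tibble(read_id = paste0("r", 1:10),
                        chrom = rep(c("chrS", "decoy_rRNA"), 5))
  out <- filter_decoy(aln, "decoy_rRNA")
  expect_equal(nrow(out), 5L)
  expect_equal(attr(out, "n_removed"), 5L)
  expect_true(all(out$chrom == "chrS"))
  none <- filter_decoy(aln, character(0))
  expect_equal(nrow(none), 10L)
  all_gone <- filter_decoy(aln, c("chrS", "decoy_rRNA"))
  expect_equal(nrow(all_gone), 0L)
  expect_equal(attr(all_gone, "n_removed"), 10L)
})

test_that("simulated decoy fraction is removed at the configured rate", {
  cfg <- small_config(decoy_fraction = 0.05, n_reads = 20000L,
                      pcr_duplication_rate = 0)
  tt <- build_reference(cfg)
  lib <- simulate_library(tt, "input", cfg, seed = 8L)
  aln <- manifest_alignments(lib)
  out <- filter_decoy(aln, "decoy_rRNA")
  removed <- attr(out, "n_removed")
  sd3 <- 3 * sqrt(20000 * 0.05 * 0.95)
  expect_lt(abs(removed - 1000), sd3)
})

test_that("deduplication is exact-UMI, deterministic and idempotent", {
  base <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4", "r5"),
    chrom = "chrS", start = c(100L, 100L, 100L, 100L, 100L),
    end = c(140L, 140L, 140L, 140L, 140L),
    align_strand = "+",
    umi = c("AAAAAAAA", "AAAAAAAT", "AAAAAAAA", "AAAAAAAA", "AAAAAAAT"))
  out <- deduplicate(base)
  # near-identical UMIs are NOT merged (exact method, no clustering)
  expect_setequal(out$umi, c("AAAAAAAA", "AAAAAAAT"))
  # representative is the first read id within each group
  expect_setequal(out$read_id, c("r1", "r2"))
  expect_equal(attr(out, "n_removed"), 3L)
  again <- deduplicate(out)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(out),
               ignore_attr = TRUE)
  expect_equal(attr(again, "n_removed"), 0L)
  bad <- base; bad$umi[2] <- NA
  expect_error(deduplicate(bad), "r2")
})

test_that("dedup recovers the exact pre-PCR molecule count on simulations", {
  cfg <- small_config(pcr_duplication_rate = 0.5, n_reads = 20000L)
  tt <- build_reference(cfg)
  lib <- simulate_library(tt, "IP", cfg, seed = 17L)
  out <- deduplicate(manifest_alignments(lib))
  expect_equal(nrow(out), max(lib$manifest$molecule))
})

test_that("subsampling is uniform, deterministic and bounds-checked", {
  aln <- tibble::tibble(read_id = paste0("r", 1:100), x = 1:100)
  expect_equal(subsample_alignments(aln, 100L, seed = 1L), aln)
  expect_equal(nrow(subsample_alignments(aln, 0L, seed = 1L)), 0L)
  s1 <- subsample_alignments(aln, 30L, seed = 7L)
  s2 <- subsample_alignments(aln, 30L, seed = 7L)
  expect_identical(s1, s2)
  expect_error(subsample_alignments(aln, 101L, seed = 1L), "cannot subsample")
})

test_that("usable-read fraction is non-increasing with subsampled depth", {
  cfg <- small_config(pcr_duplication_rate = 0.4, n_reads = 20000L)
  tt <- build_reference(cfg)
  aln <- manifest_alignments(simulate_library(tt, "IP", cfg, seed = 19L))
  depths <- c(2000L, 8000L, 20000L)
  fr <- vapply(depths, function(d) {
    nrow(deduplicate(subsample_alignments(aln, d, seed = 5L))) / d
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})
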