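# Shared fixtures and independent oracles, built once per test run.

small_config <- function(...) {
  base <- list(seed = 3L, n_genes = 8L, n_sites = 8L, n_reads = 8000L,
               gene_length_range = c(1500L, 2500L))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# memoised small truth + one IP library, reused across test files
.fix <- new.env()

small_truth <- function() {
  if (is.null(.fix$truth)) .fix$truth <- build_reference(small_config())
  .fix$truth
}

small_ip_library <- function() {
  if (is.null(.fix$ip)) {
    .fix$ip <- simulate_library(small_truth(), "IP", small_config(),
                                seed = 11L, sample = "S1")
  }
  .fix$ip
}

# best argmax-membership agreement over all label permutations
label_agreement <- function(assigned, truth, k) {
  perms <- permutations_of(seq_len(k))
  max(vapply(perms, function(p) mean(p[assigned] == truth), numeric(1)))
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# brute-force MH common odds ratio and CMH statistic, written directly from
# the defining formulas (independent of the package implementation)
brute_mh_or <- function(a, b, c, d) {
  n <- a + b + c + d
  sum(a * d / n) / sum(b * c / n)
}

brute_cmh <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  v <- (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
  chi2 <- (abs(sum(a) - sum(e)))^2 / sum(v)
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# brute-force CU-window scan: every window checked by substring counting
brute_cu_regions <- function(seq_chr, gene, width, ct_min) {
  hits <- integer(0)
  for (s in gene$start:(gene$end - width)) {
    win <- substr(seq_chr, s + 1, s + width)
    letters <- if (gene$strand == "+") c("C", "T") else c("G", "A")
    cnt <- sum(strsplit(win, "")[[1]] %in% letters)
    if (cnt / width > ct_min) hits <- c(hits, s)
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  grp <- cumsum(c(TRUE, diff(hits) >= width))
  tibble::tibble(start = as.integer(tapply(hits, grp, min)),
                 end = as.integer(tapply(hits, grp, max)) + as.integer(width))
}

# construct an artr_coverage object directly from per-contig numeric vectors
fake_coverage <- function(vecs, strand, n_reads, extsize = 30L) {
  structure(list(
    cov = lapply(vecs, S4Vectors::Rle),
    strand = strand, n_reads = n_reads, extsize = extsize,
    contig_lengths = vapply(vecs, length, numeric(1))
  ), class = "artr_coverage")
}

# minimal hand-built feature index for annotation unit tests
toy_index <- function() {
  feats <- tibble::tribble(
    ~chrom, ~start, ~end, ~strand, ~feature, ~gene_id, ~transcript_id,
    "chr1", 100L, 200L, "+", "five_prime_utr", "gA", "gA.t1",
    "chr1", 200L, 500L, "+", "CDS", "gA", "gA.t1",
    "chr1", 500L, 600L, "+", "intron", "gA", NA,
    "chr1", 600L, 700L, "+", "CDS", "gA", "gA.t1",
    "chr1", 700L, 900L, "+", "three_prime_utr", "gA", "gA.t1",
    "chr1", 2000L, 2400L, "-", "noncoding_exon", "gB", "gB.t1",
    "chr1", 2400L, 2600L, "-", "intron", "gB", NA,
    "chr1", 2600L, 3000L, "-", "noncoding_exon", "gB", "gB.t1")
  genes <- tibble::tribble(
    ~gene_id, ~chrom, ~start, ~end, ~strand, ~protein_coding,
    "gA", "chr1", 100L, 900L, "+", TRUE,
    "gB", "chr1", 2000L, 3000L, "-", FALSE)
  structure(list(genes = genes, features = feats), class = "artr_features")
}
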