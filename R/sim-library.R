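#' Simulate one ARTR-style sequencing library
#'
#' Draws molecules from the configured IP mixture (site-origin with
#' probability `ip_signal_fraction`, else expression-proportional
#' background; input libraries are pure background), adds PCR duplicates,
#' UMIs and sample barcodes, and assembles paired reads:
#' read 1 = `[UMI][cDNA = reverse complement of the sense RNA fragment]`
#' plus adapter read-through when the fragment is shorter than the read;
#' read 2 starts with the sample's 8-nt barcode. A per-read manifest records
#' the truth origin of every read.
#'
#' @param truth an [build_reference()] truth object.
#' @param role `"IP"` or `"input"`; input forces the site probability to 0.
#' @param config the [sim_config()] used to build `truth`.
#' @param seed integer seed for this library's private RNG stream.
#' @param sample sample label; must name an entry of `config$barcode_table`.
#' @return A list of class `artr_library` with `reads` (tibble: `id`,
#'   `seq1`, `qual1`, `seq2`, `qual2`), `manifest` (tibble: truth origin,
#'   genomic fragment, UMI, molecule id, duplicate flag), `sample`, `role`,
#'   `depth`.
#' @export
simulate_library <- function(truth, role = c("IP", "input"), config, seed,
                             sample = names(config$barcode_table)[1]) {
  role <- match.arg(role)
  stopifnot(inherits(truth, "artr_truth"), inherits(config, "sim_config"))
  if (!sample %in% names(config$barcode_table)) {
    abort(sprintf("`sample` '%s' is not in `config$barcode_table`", sample))
  }
  if (all(truth$genome$genes$expression <= 0)) {
    abort("all genes have zero expression; no reads can be drawn")
  }
  with_seed(seed, simulate_library_impl(truth, role, config, sample))
}

simulate_library_impl <- function(truth, role, config, sample) {
  genome <- truth$genome
  genes <- genome$genes
  sites <- truth$sites
  D <- config$n_reads
  pi0 <- if (role == "IP" && nrow(sites) > 0) config$ip_signal_fraction else 0

  # --- PCR structure: which reads are duplicates of earlier molecules -------
  is_dup <- runif(D) < config$pcr_duplication_rate
  is_dup[1L] <- FALSE
  M <- sum(!is_dup)

  # --- molecule origins ------------------------------------------------------
  is_decoy <- runif(M) < config$decoy_fraction
  is_site <- !is_decoy & (runif(M) < pi0)
  n_site <- sum(is_site)
  n_bg <- sum(!is_decoy & !is_site)

  ins_len <- sample(config$insert_length_range[1]:config$insert_length_range[2],
                    M, replace = TRUE)
  chrom <- rep("chrS", M)
  start <- integer(M)
  gene_id <- rep(NA_character_, M)
  site_id <- rep(NA_character_, M)
  tstrand <- rep("+", M)

  if (n_site > 0) {
    sw <- sites$occupancy * genes$expression[match(sites$gene_id, genes$gene_id)]
    si <- sample.int(nrow(sites), n_site, replace = TRUE, prob = sw)
    g <- match(sites$gene_id[si], genes$gene_id)
    anchor_c <- (sites$start[si] + sites$end[si]) %/% 2L
    centre <- anchor_c + as.integer(round(rnorm(n_site, 0, config$site_kernel_sd)))
    L <- ins_len[is_site]
    a <- centre - L %/% 2L
    a <- pmax(genes$start[g], pmin(a, genes$end[g] - L))
    start[is_site] <- a
    gene_id[is_site] <- sites$gene_id[si]
    site_id[is_site] <- sites$site_id[si]
    tstrand[is_site] <- sites$strand[si]
  }
  if (n_bg > 0) {
    bg <- !is_decoy & !is_site
    gi <- sample.int(nrow(genes), n_bg, replace = TRUE, prob = genes$expression)
    L <- ins_len[bg]
    a <- genes$start[gi] +
      floor(runif(n_bg) * (genes$end[gi] - genes$start[gi] - L))
    start[bg] <- as.integer(a)
    gene_id[bg] <- genes$gene_id[gi]
    tstrand[bg] <- genes$strand[gi]
  }
  if (any(is_decoy)) {
    nd <- sum(is_decoy)
    L <- ins_len[is_decoy]
    chrom[is_decoy] <- "decoy_rRNA"
    start[is_decoy] <- as.integer(floor(runif(nd) * (config$decoy_length - L)))
    tstrand[is_decoy] <- sample(c("+", "-"), nd, replace = TRUE)
  }
  end <- start + ins_len
  origin <- ifelse(is_decoy, "decoy", ifelse(is_site, "site", "background"))

  # alignment-strand 5' position under reverse strandedness:
  # sense "+" fragments sequence as cDNA on the genomic "-" strand (5' = end),
  # sense "-" fragments align to "+" (5' = start).
  astrand <- ifelse(tstrand == "+", "-", "+")
  pos5 <- ifelse(astrand == "+", start, end)

  # --- UMIs: distinct within identical (chrom, pos5, strand) groups ---------
  umi <- random_dna(rep(config$umi_length, M))
  key <- paste(chrom, pos5, astrand, sep = ":")
  repeat {
    dup <- duplicated(paste(key, umi, sep = ":"))
    if (!any(dup)) break
    umi[dup] <- random_dna(rep(config$umi_length, sum(dup)))
  }

  # --- sequences -------------------------------------------------------------
  sense <- stringi::stri_sub(as.character(genome$seq[["chrS"]]),
                             start + 1L, end)
  dec <- chrom == "decoy_rRNA"
  if (any(dec)) {
    sense[dec] <- stringi::stri_sub(as.character(genome$seq[["decoy_rRNA"]]),
                                    start[dec] + 1L, end[dec])
  }
  neg <- tstrand == "-"
  sense[neg] <- rc_chr(sense[neg])
  cdna <- rc_chr(sense)
  if (config$error_rate > 0) cdna <- mutate_bases(cdna, config$error_rate)

  rl <- config$read_length
  read1 <- stringi::stri_sub(
    paste0(umi, cdna, config$adapter_seq,
           strrep("G", rl)), 1L, rl)
  barcode <- config$barcode_table[[sample]]
  read2 <- stringi::stri_sub(
    paste0(barcode, random_dna(rep(rl, M))), 1L, rl)

  # --- expand molecules to reads (duplicates copy a molecule verbatim) ------
  mol_of_read <- integer(D)
  mol_of_read[!is_dup] <- seq_len(M)
  n_dups <- sum(is_dup)
  if (n_dups > 0) mol_of_read[is_dup] <- sample.int(M, n_dups, replace = TRUE)

  id <- sprintf("%s_%s_%07d", sample, role, seq_len(D))
  m <- mol_of_read
  reads <- tibble(
    id = id,
    seq1 = read1[m], qual1 = strrep("I", rl),
    seq2 = read2[m], qual2 = strrep("I", rl)
  )
  manifest <- tibble(
    read_id = id, sample = sample, role = role,
    molecule = m, duplicate = is_dup,
    origin = origin[m], gene_id = gene_id[m], site_id = site_id[m],
    chrom = chrom[m], start = start[m], end = end[m],
    transcript_strand = tstrand[m], align_strand = astrand[m],
    pos5 = pos5[m], umi = umi[m]
  )
  structure(list(reads = reads, manifest = manifest, sample = sample,
                 role = role, depth = D),
            class = "artr_library")
}

# Uniform per-base substitutions at rate `rate` (insert bases only).
mutate_bases <- function(x, rate) {
  n_err <- rbinom(length(x), nchar(x), rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(nchar(x[i]), n_err[i])
    for (p in pos) {
      cur <- substr(x[i], p, p)
      stringi::stri_sub(x[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  x
}

#' Idealised alignments straight from a simulation manifest
#'
#' Converts a library's read manifest into the alignment tibble that a
#' perfect aligner would produce from its error-free reads (one ungapped
#' alignment per read at the fragment's genomic coordinates). Useful for
#' testing stages downstream of alignment at scales where round-tripping
#' through FASTQ adds nothing.
#'
#' @param lib an [simulate_library()] result.
#' @return Alignment tibble (`read_id`, `chrom`, `start`, `end`,
#'   `align_strand`, `transcript_strand`, `mapped_length`, `umi`, `unique`).
#' @export
manifest_alignments <- function(lib) {
  m <- if (inherits(lib, "artr_library")) lib$manifest else lib
  tibble(
    read_id = m$read_id, chrom = m$chrom,
    start = as.integer(m$start), end = as.integer(m$end),
    align_strand = m$align_strand, transcript_strand = m$transcript_strand,
    mapped_length = as.integer(m$end - m$start),
    umi = m$umi, unique = TRUE
  )
}

#' Pool several simulated libraries into one multiplexed run
#'
#' Concatenates reads and manifests, emulating samples sequenced together
#' and later demultiplexed by the read-2 barcode.
#'
#' @param libs list of [simulate_library()] results.
#' @return A list with `reads` and `manifest` tibbles.
#' @export
pool_libraries <- function(libs) {
  list(reads = bind_rows(lapply(libs, `[[`, "reads")),
       manifest = bind_rows(lapply(libs, `[[`, "manifest")))
}
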