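#' Build a toy annotated genome with planted binding sites
#'
#' Generates a random genome with `n_genes` non-overlapping genes on both
#' strands of one main contig (plus an rRNA-like decoy contig), an
#' exon/intron/UTR/CDS feature annotation, log-normal per-gene expression
#' weights, and planted binding sites whose genomic sequence carries the
#' configured motif on the gene strand. The returned truth object is the
#' ground-truth anchor for every downstream stage.
#'
#' Everything is deterministic given `config$seed`: rerunning with an
#' identical config reproduces byte-identical FASTA/GTF output.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `artr_truth` with elements `genome` (class
#'   `artr_genome`: `seq` as a [Biostrings::DNAStringSet], `contigs`,
#'   `genes`, `features` tibbles), `sites` (tibble, 0-based half-open,
#'   strand and occupancy), `expression`, and `enrichment` (per-gene
#'   expected IP/input read-rate ratio under the configured mixture).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, build_reference_impl(config))
}

build_reference_impl <- function(config) {
  ng <- config$n_genes
  mlen <- nchar(config$motif)

  # --- gene placement on the main contig ------------------------------------
  lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                 ng, replace = TRUE)
  gaps <- sample(config$gene_gap_range[1]:config$gene_gap_range[2],
                 ng + 1L, replace = TRUE)
  starts <- cumsum(gaps[seq_len(ng)]) + cumsum(c(0L, lens[-ng]))  # 0-based
  genes <- tibble(
    gene_id = sprintf("gene%03d", seq_len(ng)),
    chrom = "chrS",
    start = as.integer(starts),
    end = as.integer(starts + lens),
    strand = sample(c("+", "-"), ng, replace = TRUE),
    protein_coding = runif(ng) < config$coding_fraction,
    expression = rlnorm(ng, config$expression_meanlog, config$expression_sdlog)
  )
  main_len <- as.integer(genes$end[ng] + gaps[ng + 1L])

  seqs <- c(chrS = random_dna(main_len),
            decoy_rRNA = random_dna(config$decoy_length))

  # --- exon/intron structure and UTR/CDS partition --------------------------
  features <- purrr::pmap_dfr(genes, function(gene_id, chrom, start, end,
                                              strand, protein_coding, ...) {
    gene_features(gene_id, chrom, start, end, strand, protein_coding, config)
  })

  # --- planted sites --------------------------------------------------------
  sites <- plant_sites(genes, config)
  if (nrow(sites) > 0) {
    if (!is.null(config$site_ct_bias)) {
      seqs["chrS"] <- bias_site_windows(seqs["chrS"], sites, config)
    }
    motif_fwd <- config$motif
    motif_rev <- rc_chr(config$motif)
    ins <- ifelse(sites$strand == "+", motif_fwd, motif_rev)
    seqs["chrS"] <- stringi::stri_sub_replace_all(
      seqs[["chrS"]], from = sites$start + 1L, to = sites$start + mlen,
      replacement = ins)
  }

  # --- expected per-gene enrichment under the IP mixture --------------------
  pi0 <- if (nrow(sites) > 0) config$ip_signal_fraction else 0
  site_w <- sites %>%
    group_by(.data$gene_id) %>%
    summarise(w = sum(.data$occupancy), .groups = "drop")
  enr <- genes %>%
    left_join(site_w, by = "gene_id") %>%
    mutate(w = ifelse(is.na(.data$w), 0, .data$w) * .data$expression)
  total_w <- sum(enr$w)
  total_x <- sum(enr$expression)
  enrichment <- tibble(
    gene_id = enr$gene_id,
    expected_enrichment = if (total_w > 0) {
      pi0 * (enr$w / total_w) * (total_x / enr$expression) + (1 - pi0)
    } else {
      rep(1, ng)
    }
  )

  genome <- structure(list(
    seq = Biostrings::DNAStringSet(seqs),
    contigs = tibble(chrom = names(seqs),
                     length = c(main_len, config$decoy_length)),
    genes = genes,
    features = features,
    motif = config$motif,
    decoy_contigs = "decoy_rRNA"
  ), class = "artr_genome")

  structure(list(
    genome = genome,
    sites = sites,
    expression = genes %>% select("gene_id", "expression"),
    enrichment = enrichment,
    config = config
  ), class = "artr_truth")
}

# Split one gene into exon/intron pieces and partition the transcript into
# 5'UTR/CDS/3'UTR (protein-coding) or noncoding exons. Coordinates 0-based
# half-open on the genome; the transcript runs 5'->3' on the gene strand.
gene_features <- function(gene_id, chrom, start, end, strand,
                          protein_coding, config) {
  glen <- end - start
  k <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
  k <- max(1L, min(k, (glen %/% 80L + 1L) %/% 2L))
  pieces <- 2L * k - 1L
  if (pieces == 1L) {
    plen <- glen
  } else {
    w <- runif(pieces)
    extra <- glen - 80L * pieces
    plen <- 80L + floor(extra * w / sum(w))
    plen[pieces] <- glen - sum(plen[-pieces])
  }
  pstart <- start + cumsum(c(0L, plen[-pieces]))
  pend <- pstart + plen
  is_exon <- seq_len(pieces) %% 2L == 1L
  exons <- tibble(start = pstart[is_exon], end = pend[is_exon])
  introns <- tibble(start = pstart[!is_exon], end = pend[!is_exon])
  tx_id <- paste0(gene_id, ".t1")

  # transcript-order exons: genomic order for "+", reversed for "-"
  ex_tx <- if (strand == "+") exons else exons[rev(seq_len(nrow(exons))), ]
  ex_len <- ex_tx$end - ex_tx$start
  tx_len <- sum(ex_len)

  coding <- protein_coding && tx_len >= 300L
  if (coding) {
    utr5 <- max(30L, as.integer(round(0.15 * tx_len)))
    utr3 <- max(60L, as.integer(round(0.25 * tx_len)))
    bounds <- c(utr5, tx_len - utr3)  # transcript breakpoints
    labels <- c("five_prime_utr", "CDS", "three_prime_utr")
  } else {
    bounds <- integer(0)
    labels <- "noncoding_exon"
  }

  # walk transcript-order exons, cutting at the breakpoints
  cuts <- sort(unique(c(0L, bounds, tx_len)))
  seg_lab <- labels[findInterval(head(cuts, -1L), c(0L, bounds),
                                 rightmost.closed = FALSE)]
  out <- list()
  off <- 0L
  for (i in seq_len(nrow(ex_tx))) {
    e0 <- off; e1 <- off + ex_len[i]
    for (s in seq_along(seg_lab)) {
      s0 <- max(cuts[s], e0); s1 <- min(cuts[s + 1L], e1)
      if (s1 <= s0) next
      if (strand == "+") {
        g0 <- ex_tx$start[i] + (s0 - e0); g1 <- ex_tx$start[i] + (s1 - e0)
      } else {
        g1 <- ex_tx$end[i] - (s0 - e0); g0 <- ex_tx$end[i] - (s1 - e0)
      }
      out[[length(out) + 1L]] <- tibble(start = g0, end = g1,
                                        feature = seg_lab[s])
    }
    off <- e1
  }
  res <- bind_rows(out)
  if (nrow(introns) > 0) {
    res <- bind_rows(res, introns %>% mutate(feature = "intron"))
  }
  res %>%
    mutate(chrom = chrom, strand = strand, gene_id = gene_id,
           transcript_id = tx_id,
           start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    select("chrom", "start", "end", "strand", "feature", "gene_id",
           "transcript_id") %>%
    arrange(.data$start)
}

# Distribute n_sites across genes and pick non-overlapping interior anchors.
plant_sites <- function(genes, config) {
  ns <- config$n_sites
  empty <- tibble(site_id = character(0), gene_id = character(0),
                  chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), occupancy = numeric(0))
  if (ns == 0L) return(empty)
  ng <- nrow(genes)
  counts <- rep(ns %/% ng, ng)
  rem <- ns %% ng
  if (rem > 0) {
    idx <- sample(ng, rem)
    counts[idx] <- counts[idx] + 1L
  }
  occ <- rep_len(config$site_occupancy, ng)
  mlen <- nchar(config$motif)
  edge <- 150L
  rows <- list()
  for (g in seq_len(ng)) {
    if (counts[g] == 0L) next
    lo <- genes$start[g] + edge
    hi <- genes$end[g] - edge - mlen
    if (hi <= lo) {
      abort(sprintf(
        "cannot place sites in %s: gene too short for %d site(s); lower `sites_per_gene`/`n_sites` or raise `gene_length_range`",
        genes$gene_id[g], counts[g]))
    }
    placed <- integer(0)
    for (s in seq_len(counts[g])) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        a <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        if (all(abs(a - placed) > mlen + 20L)) { ok <- TRUE; break }
      }
      if (!ok) {
        abort(sprintf(
          "site placement failed in %s after 200 retries; lower `sites_per_gene`/`n_sites` or raise `gene_length_range`",
          genes$gene_id[g]))
      }
      placed <- c(placed, a)
    }
    rows[[g]] <- tibble(gene_id = genes$gene_id[g], chrom = genes$chrom[g],
                        start = as.integer(sort(placed)),
                        strand = genes$strand[g], occupancy = occ[g])
  }
  bind_rows(rows) %>%
    mutate(end = .data$start + mlen,
           site_id = sprintf("site%03d", row_number())) %>%
    select("site_id", "gene_id", "chrom", "start", "end", "strand",
           "occupancy")
}

# Re-draw the sequence composition around each site towards C/T on the sense
# strand (pyrimidine-rich binding context).
bias_site_windows <- function(chrom_seq, sites, config) {
  b <- config$site_ct_bias
  halfwin <- 40L
  for (i in seq_len(nrow(sites))) {
    w0 <- max(0L, sites$start[i] - halfwin)
    w1 <- min(nchar(chrom_seq), sites$end[i] + halfwin)
    n <- w1 - w0
    probs <- if (sites$strand[i] == "+") {
      c(A = (1 - b) / 2, C = b / 2, G = (1 - b) / 2, T = b / 2)
    } else {
      c(A = b / 2, C = (1 - b) / 2, G = b / 2, T = (1 - b) / 2)
    }
    repl <- paste(sample(names(probs), n, replace = TRUE, prob = probs),
                  collapse = "")
    stringi::stri_sub(chrom_seq, w0 + 1L, w1) <- repl
  }
  chrom_seq
}
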