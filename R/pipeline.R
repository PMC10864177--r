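#' Validate a pipeline configuration
#'
#' Fills defaults and checks every cross-field constraint, reporting all
#' violations at once rather than failing on the first.
#'
#' @param config a YAML file path or a nested list. Recognised top-level
#'   fields: `out_dir` (required), `seed`, `strandedness`, `stages`,
#'   `simulate` (passed to [sim_config()], plus `ip_replicates`,
#'   `input_replicates`), `peaks` (`qcut`, `extsize`, `min_len`), `enrich`
#'   (`pairing`), `dynamics` (`enabled`, `time_points`, `clusters`,
#'   `min_sum`, `fc_min`, `p_max`, `select_fraction`).
#' @return A validated config list of class `artr_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  defaults <- list(
    seed = 1L, strandedness = "reverse",
    stages = c("simulate", "readprep", "peaks", "annotate", "enrich"),
    simulate = list(ip_replicates = 2L, input_replicates = 2L),
    peaks = list(qcut = 0.05, extsize = 30L, min_len = 30L),
    enrich = list(pairing = "cross"),
    dynamics = list(enabled = FALSE, time_points = 4L, clusters = 3L,
                    min_sum = 10L, fc_min = 2, p_max = 0.05,
                    select_fraction = 0.5)
  )
  cfg <- utils::modifyList(defaults, config)
  for (sub in c("simulate", "peaks", "enrich", "dynamics")) {
    cfg[[sub]] <- utils::modifyList(defaults[[sub]],
                                    as.list(config[[sub]] %||% list()))
  }

  if (is.null(cfg$out_dir)) note("out_dir: required but missing")
  if (!cfg$strandedness %in% c("forward", "reverse")) {
    note(sprintf("strandedness: '%s' is not one of forward, reverse",
                 cfg$strandedness))
  }
  known <- c("simulate", "readprep", "peaks", "annotate", "enrich", "dynamics")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) note(sprintf("stages: unknown stage(s) %s",
                                paste(bad, collapse = ", ")))
  chk_range <- function(val, field, lo, hi) {
    if (!is.numeric(val) || is.na(val) || val < lo || val > hi) {
      note(sprintf("%s: %s is outside [%s, %s]", field,
                   format(val), format(lo), format(hi)))
    }
  }
  chk_range(cfg$peaks$qcut, "peaks.qcut", 1e-12, 1)
  chk_range(cfg$peaks$extsize, "peaks.extsize", 1, 1e4)
  chk_range(cfg$dynamics$p_max, "dynamics.p_max", 1e-12, 1)
  chk_range(cfg$dynamics$select_fraction, "dynamics.select_fraction", 0, 1)
  if (cfg$dynamics$enabled && cfg$dynamics$time_points < 2) {
    note("dynamics.time_points: need at least 2 time points")
  }
  for (f in c("reference", "annotation", "fastq_r1", "fastq_r2")) {
    p <- cfg$inputs[[f]]
    if (!is.null(p) && !file.exists(p)) {
      note(sprintf("inputs.%s: file not found: %s", f, p))
    }
  }
  if (length(errors)) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", errors, collapse = "\n")))
  }
  structure(cfg, class = "artr_config")
}

#' Run the full analysis pipeline on a configuration
#'
#' Executes the enabled stages in order: simulate -> readprep (demultiplex,
#' trim, align, decoy filter, dedup) -> peaks (strand-separated calling
#' against input) -> annotate -> enrich -> dynamics. Every stage writes its
#' artifacts under `out_dir` and later stages reload what they need from
#' there, so a subset of stages can be re-run against existing outputs. A
#' serialised copy of the config, a plain-text run log (no timestamps, so
#' reruns are byte-identical) and a JSON manifest with MD5 checksums are
#' always written.
#'
#' @param config an [validate_config()] result (or anything it accepts).
#' @return Tibble `file`, `md5` (the manifest), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "artr_config")) config else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("artrkit pipeline run",
                 paste0("seed: ", cfg$seed),
                 paste0("stages: ", paste(cfg$stages, collapse = ", ")))
  logmsg <- function(...) log_lines <<- c(log_lines, sprintf(...))
  yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))

  sim_args <- cfg$simulate[setdiff(names(cfg$simulate),
                                   c("ip_replicates", "input_replicates"))]
  scfg <- do.call(sim_config, c(sim_args, list(seed = cfg$seed)))
  n_ip <- cfg$simulate$ip_replicates
  n_in <- cfg$simulate$input_replicates
  roles <- c(rep("IP", n_ip), rep("input", n_in))
  samples <- names(scfg$barcode_table)[seq_along(roles)]

  truth <- NULL
  load_truth <- function() {
    if (is.null(truth)) {
      truth <<- build_reference(scfg)
    }
    truth
  }

  if ("simulate" %in% cfg$stages) {
    tr <- load_truth()
    write_genome(tr$genome, file.path(out, "reference.fa"),
                 file.path(out, "annotation.gtf"))
    write_truth(tr, out)
    libs <- purrr::map2(roles, seq_along(roles), function(role, i) {
      simulate_library(tr, role, scfg, seed = sub_seed(cfg$seed, paste0("lib", i)),
                       sample = samples[i])
    })
    pool <- pool_libraries(libs)
    write_fastq(pool$reads, file.path(out, "pooled_R1.fastq"),
                file.path(out, "pooled_R2.fastq"))
    readr::write_tsv(pool$manifest, file.path(out, "read_manifest.tsv"))
    logmsg("simulate: %d libraries, %d read pairs", length(libs),
           nrow(pool$reads))
  }

  usable <- list()
  if ("readprep" %in% cfg$stages) {
    pairs <- read_fastq_pairs(file.path(out, "pooled_R1.fastq"),
                              file.path(out, "pooled_R2.fastq"))
    dmx <- demultiplex(pairs, scfg$barcode_table, max_mismatch = 1L)
    tr <- load_truth()
    for (i in seq_along(samples)) {
      s <- samples[i]
      rd <- dmx %>% filter(.data$sample == s)
      trm <- trim_reads(rd, scfg$adapter_seq, umi_length = scfg$umi_length)
      aln <- align_exact(trm, tr$genome,
                         max_mismatch = if (scfg$error_rate > 0) 1L else 0L,
                         strandedness = cfg$strandedness)
      aln <- filter_decoy(aln, tr$genome$decoy_contigs)
      ded <- deduplicate(aln)
      usable[[s]] <- ded
      write_sam(ded, tr$genome, file.path(out, sprintf("usable_%s.sam", s)))
      logmsg("readprep %s (%s): %d pairs -> %d trimmed -> %d usable",
             s, roles[i], nrow(rd), nrow(trm), nrow(ded))
    }
  }

  load_usable <- function() {
    if (length(usable) == 0L) {
      for (s in samples) {
        usable[[s]] <<- read_sam(file.path(out, sprintf("usable_%s.sam", s)),
                                 strandedness = cfg$strandedness)
      }
    }
    usable
  }

  peaks <- NULL
  if ("peaks" %in% cfg$stages) {
    u <- load_usable()
    tr <- load_truth()
    ip_all <- bind_rows(u[samples[roles == "IP"]])
    in_all <- bind_rows(u[samples[roles == "input"]])
    pk <- list()
    for (s in c("+", "-")) {
      cov_t <- build_coverage(ip_all, tr$genome, s,
                              extsize = cfg$peaks$extsize)
      cov_c <- build_coverage(in_all, tr$genome, s,
                              extsize = cfg$peaks$extsize)
      write_bedgraph(normalize_track(cov_t),
                     file.path(out, sprintf("ip_%s.bedgraph",
                                            if (s == "+") "plus" else "minus")))
      write_bedgraph(normalize_track(cov_c),
                     file.path(out, sprintf("input_%s.bedgraph",
                                            if (s == "+") "plus" else "minus")))
      pk[[s]] <- call_peaks(cov_t, cov_c, qcut = cfg$peaks$qcut,
                            min_len = cfg$peaks$min_len)
    }
    peaks <- combine_strands(pk[["+"]], pk[["-"]])
    write_narrowpeak(peaks, file.path(out, "peaks.narrowPeak"))
    write_bed(peaks %>% mutate(name = sprintf("peak_%d", row_number()),
                               score = 0),
              file.path(out, "peaks.bed"))
    logmsg("peaks: %d peaks (%d plus, %d minus)", nrow(peaks),
           nrow(pk[["+"]]), nrow(pk[["-"]]))
  }

  if ("annotate" %in% cfg$stages) {
    tr <- load_truth()
    if (is.null(peaks)) peaks <- read_narrowpeak(file.path(out,
                                                           "peaks.narrowPeak"))
    idx <- feature_index(tr$genome)
    ann <- assign_peaks(peaks, idx)
    readr::write_tsv(ann, file.path(out, "peaks_annotated.tsv"))
    u <- load_usable()
    fr <- assign_reads(bind_rows(u[samples[roles == "IP"]]), idx)
    readr::write_tsv(fr, file.path(out, "read_fractions.tsv"))
    md <- motif_distance(peaks, tr$genome$motif, tr$genome)
    readr::write_tsv(summarize_motif_distance(md),
                     file.path(out, "motif_distance.tsv"))
    logmsg("annotate: %d peaks annotated", nrow(ann))
  }

  if ("enrich" %in% cfg$stages) {
    tr <- load_truth()
    u <- load_usable()
    idx <- feature_index(tr$genome)
    cnt <- lapply(u, count_gene_reads, index = idx)
    strata <- build_strata(cnt[samples[roles == "IP"]],
                           cnt[samples[roles == "input"]],
                           pairing = cfg$enrich$pairing)
    enr <- gene_enrichment(strata)
    readr::write_tsv(enr, file.path(out, "enrichment.tsv"))
    logmsg("enrich: %d genes, %d High", nrow(enr),
           sum(enr$group == "High", na.rm = TRUE))
  }

  if ("dynamics" %in% cfg$stages && cfg$dynamics$enabled) {
    run_dynamics_stage(cfg, scfg, load_truth(), out, logmsg)
  }

  writeLines(log_lines, file.path(out, "run_log.txt"))
  files <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(out, files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}

# Time-course binding dynamics on alignment-level simulated libraries: gene
# occupancies follow three planted trajectory shapes (rising, falling,
# transient), one IP + one input library per time point.
run_dynamics_stage <- function(cfg, scfg, truth, out, logmsg) {
  tp <- cfg$dynamics$time_points
  shapes <- rbind(
    rising = seq(0.2, 2, length.out = tp),
    falling = seq(2, 0.2, length.out = tp),
    transient = 0.2 + 1.8 * exp(-(seq_len(tp) - ceiling(tp / 2))^2)
  )
  genes <- truth$genome$genes$gene_id
  assign <- rep_len(seq_len(nrow(shapes)), length(genes))
  idx <- feature_index(truth$genome)
  mats <- list()
  for (t in seq_len(tp)) {
    tr_t <- truth
    mult <- shapes[assign[match(tr_t$sites$gene_id, genes)], t]
    tr_t$sites$occupancy <- tr_t$sites$occupancy * mult
    ip <- simulate_library(tr_t, "IP", scfg,
                           seed = sub_seed(cfg$seed, paste0("dyn_ip", t)))
    inp <- simulate_library(tr_t, "input", scfg,
                            seed = sub_seed(cfg$seed, paste0("dyn_in", t)))
    cnt_ip <- count_gene_reads(deduplicate(manifest_alignments(ip)), idx)
    cnt_in <- count_gene_reads(deduplicate(manifest_alignments(inp)), idx)
    bs <- binding_strength(cnt_ip, cnt_in, min_sum = cfg$dynamics$min_sum)
    mats[[t]] <- bs %>% select("gene_id", "log2fc") %>%
      rename(!!paste0("t", t) := "log2fc")
  }
  wide <- purrr::reduce(mats, function(a, b) dplyr::inner_join(a, b,
                                                               by = "gene_id"))
  readr::write_tsv(wide, file.path(out, "binding_strength.tsv"))
  sel <- select_variable(wide, fraction = cfg$dynamics$select_fraction)
  fit <- cmeans_fuzzy(sel, centers = cfg$dynamics$clusters,
                      seed = sub_seed(cfg$seed, "cmeans"))
  readr::write_tsv(tidy(fit), file.path(out, "membership.tsv"))
  readr::write_tsv(as_tibble(fit$centroids, rownames = "cluster"),
                   file.path(out, "centroids.tsv"))
  dm <- dmin_curve(sel, c_range = 2:min(8, nrow(sel) - 1),
                   seed = sub_seed(cfg$seed, "dmin"))
  readr::write_tsv(dm, file.path(out, "dmin.tsv"))
  logmsg("dynamics: %d genes clustered into %d clusters", nrow(sel),
         cfg$dynamics$clusters)
}

#' Read a narrowPeak file back into a peak tibble
#'
#' @param path a [write_narrowpeak()] output.
#' @return Peak tibble with `chrom`, `start`, `end`, `strand`, `summit`,
#'   `fold_enrichment`, `p_value`, `q_value`.
#' @export
read_narrowpeak <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                            "score", "strand", "signalValue",
                                            "pValue", "qValue", "peak"),
                        show_col_types = FALSE)
  tibble(chrom = df$chrom, start = df$start, end = df$end,
         strand = df$strand, summit = df$start + df$peak,
         pileup = NA_real_, fold_enrichment = df$signalValue,
         p_value = 10^(-df$pValue), q_value = 10^(-df$qValue))
}
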