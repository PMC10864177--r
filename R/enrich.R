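#' Stratified 2x2 tables of in-gene vs out-of-gene reads
#'
#' For every gene, builds one 2x2 table per (IP replicate, input replicate)
#' pair: `a` = IP reads inside the gene, `b` = IP reads outside, `c`/`d` the
#' same for the input library. With R IP and S input replicates the default
#' `"cross"` pairing yields R x S strata per gene; `"paired"` pairs
#' replicates by index.
#'
#' @param ip_counts,input_counts lists of per-gene count tibbles from
#'   [count_gene_reads()] (each carrying a `"depth"` attribute), one per
#'   replicate.
#' @param pairing `"cross"` (all combinations, default) or `"paired"`.
#' @return Tibble `gene_id`, `stratum`, `ip_rep`, `input_rep`, `a`, `b`,
#'   `c`, `d`.
#' @export
build_strata <- function(ip_counts, input_counts,
                         pairing = c("cross", "paired")) {
  pairing <- match.arg(pairing)
  if (!is.data.frame(ip_counts[[1]])) abort("`ip_counts` must be a list of count tibbles")
  depths <- function(lst) vapply(lst, function(x) {
    d <- attr(x, "depth") %||% sum(x$n)
    if (d == 0L) abort("empty library: zero usable reads")
    d
  }, numeric(1))
  d_ip <- depths(ip_counts)
  d_in <- depths(input_counts)
  pairs <- if (pairing == "cross") {
    expand.grid(ip_rep = seq_along(ip_counts),
                input_rep = seq_along(input_counts))
  } else {
    if (length(ip_counts) != length(input_counts)) {
      abort("paired pairing needs equal numbers of IP and input replicates")
    }
    data.frame(ip_rep = seq_along(ip_counts),
               input_rep = seq_along(input_counts))
  }
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$ip_rep[k]; j <- pairs$input_rep[k]
    ip <- ip_counts[[i]]; inp <- input_counts[[j]]
    stopifnot(identical(ip$gene_id, inp$gene_id))
    tibble(gene_id = ip$gene_id,
           stratum = sprintf("ip%d_in%d", i, j),
           ip_rep = i, input_rep = j,
           a = ip$n, b = as.integer(d_ip[i]) - ip$n,
           c = inp$n, d = as.integer(d_in[j]) - inp$n)
  })
  bind_rows(out) %>% arrange(.data$gene_id, .data$stratum)
}

#' Mantel-Haenszel common odds ratio of stratified 2x2 tables
#'
#' `OR_MH = sum_i(a_i d_i / n_i) / sum_i(b_i c_i / n_i)` with
#' `n_i = a_i + b_i + c_i + d_i`; a single stratum reduces to the plain
#' cross-product ratio `ad / bc`. When a whole margin is zero (the estimator
#' undefined), the Haldane-Anscombe 0.5 correction is applied once to every
#' cell and the result flagged; if still undefined, `NA` is returned.
#'
#' @param a,b,c,d integer vectors, one element per stratum.
#' @return The common odds ratio (scalar); attribute `"correction"` is one
#'   of `"none"`, `"haldane"`, `"undefined"`.
#' @export
mh_common_or <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (sum(a, b, c, d) == 0) {
    out <- NA_real_
    attr(out, "correction") <- "undefined"
    return(out)
  }
  or_of <- function(a, b, c, d) {
    if (length(a) == 1L) {
      num <- a * d
      den <- b * c
    } else {
      n <- a + b + c + d
      num <- sum(a * d / n)
      den <- sum(b * c / n)
    }
    if (den > 0 && num >= 0) num / den else NA_real_
  }
  est <- or_of(a, b, c, d)
  corr <- "none"
  if (!is.na(est) && est > 0) {
    attr(est, "correction") <- corr
    return(est)
  }
  # zero margin somewhere: num == 0 or den == 0
  est2 <- or_of(a + 0.5, b + 0.5, c + 0.5, d + 0.5)
  if (!is.na(est2)) {
    est2 <- as.numeric(est2)
    attr(est2, "correction") <- "haldane"
    return(est2)
  }
  out <- NA_real_
  attr(out, "correction") <- "undefined"
  out
}

#' Cochran-Mantel-Haenszel chi-squared test for stratified 2x2 tables
#'
#' `chi2 = (|sum a_i - sum E(a_i)| - cc)^2 / sum Var(a_i)` with
#' `E(a_i) = (a_i + b_i)(a_i + c_i) / n_i` and
#' `Var(a_i) = (a_i + b_i)(c_i + d_i)(a_i + c_i)(b_i + d_i) /
#' (n_i^2 (n_i - 1))`; `cc = 0.5` when `continuity = TRUE`, else 0. The
#' p-value is the upper tail of chi-squared with 1 degree of freedom.
#' Strata with `n_i <= 1` carry no information and are dropped (flagged).
#'
#' @param a,b,c,d integer vectors, one element per stratum.
#' @param continuity apply the continuity correction.
#' @return List with `chi2`, `p`, `df`, `n_dropped`.
#' @export
cmh_test <- function(a, b, c, d, continuity = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  keep <- n > 1
  n_dropped <- sum(!keep)
  a <- a[keep]; b <- b[keep]; c <- c[keep]; d <- d[keep]; n <- n[keep]
  if (length(n) == 0L) {
    return(list(chi2 = NA_real_, p = NA_real_, df = 1L,
                n_dropped = n_dropped))
  }
  e_a <- (a + b) * (a + c) / n
  v_a <- (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
  v <- sum(v_a)
  if (v == 0) {
    return(list(chi2 = NA_real_, p = NA_real_, df = 1L,
                n_dropped = n_dropped))
  }
  cc <- if (continuity) 0.5 else 0
  dev <- max(abs(sum(a) - sum(e_a)) - cc, 0)
  chi2 <- dev^2 / v
  list(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE), df = 1L,
       n_dropped = n_dropped)
}

#' Enrichment grouping by common odds ratio
#'
#' No enrichment: `0 <= OR <= 1`; low: `1 < OR <= 2`; high: `OR > 2`
#' (boundaries inclusive on the left group). Undefined ORs give `NA`.
#'
#' @param or numeric vector of common odds ratios.
#' @return Factor with levels `No`, `Low`, `High`.
#' @export
classify_enrichment <- function(or) {
  out <- ifelse(is.na(or), NA_character_,
                ifelse(or <= 1, "No", ifelse(or <= 2, "Low", "High")))
  factor(out, levels = c("No", "Low", "High"))
}

#' Gene-level enrichment table: MH common OR, CMH test, grouping
#'
#' Runs [mh_common_or()] and [cmh_test()] per gene over its replicate
#' strata, BH-adjusts the CMH p-values across genes, and assigns the
#' No/Low/High enrichment group from the common odds ratio.
#'
#' @param strata a [build_strata()] tibble.
#' @param continuity continuity correction for the CMH statistic.
#' @return Tibble `gene_id`, `n_strata`, `or_mh`, `or_correction`, `chi2`,
#'   `p`, `q`, `group`.
#' @export
gene_enrichment <- function(strata, continuity = FALSE) {
  out <- strata %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_strata = n(),
      or_mh = {
        x <- mh_common_or(.data$a, .data$b, .data$c, .data$d)
        as.numeric(x)
      },
      or_correction = attr(mh_common_or(.data$a, .data$b, .data$c, .data$d),
                           "correction"),
      chi2 = cmh_test(.data$a, .data$b, .data$c, .data$d, continuity)$chi2,
      p = cmh_test(.data$a, .data$b, .data$c, .data$d, continuity)$p,
      .groups = "drop"
    ) %>%
    mutate(q = p.adjust(.data$p, method = "BH"),
           group = classify_enrichment(.data$or_mh))
  out
}
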