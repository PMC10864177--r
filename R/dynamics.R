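#' Per-gene binding strength: log2 fold change of IP over input
#'
#' Counts are normalised by median-of-ratios size factors (geometric-mean
#' reference over genes with nonzero counts in both libraries), the log2
#' fold change is computed with a pseudocount, and a two-sided binomial test
#' of the IP count against the depth-ratio expectation gives the per-gene
#' p-value. Genes whose summed raw count is below `min_sum` are dropped.
#'
#' @param ip_counts,input_counts per-gene count tibbles from
#'   [count_gene_reads()] (same gene order).
#' @param min_sum minimum `ip + input` raw read sum (genes below are
#'   dropped).
#' @param pseudocount added to both normalised counts inside the ratio.
#' @return Tibble `gene_id`, `ip`, `input`, `log2fc`, `fc`, `p`; attribute
#'   `"size_factors"` carries the two factors.
#' @export
binding_strength <- function(ip_counts, input_counts, min_sum = 10L,
                             pseudocount = 1) {
  stopifnot(identical(ip_counts$gene_id, input_counts$gene_id))
  ip <- as.numeric(ip_counts$n)
  inp <- as.numeric(input_counts$n)
  if (sum(ip) == 0 || sum(inp) == 0) abort("a library has zero depth")
  both <- ip > 0 & inp > 0
  sf <- c(1, 1)
  if (any(both)) {
    ref <- sqrt(ip[both] * inp[both])
    sf <- c(median(ip[both] / ref), median(inp[both] / ref))
  }
  keep <- (ip + inp) >= min_sum
  if (!any(keep)) abort("no gene passes the read-sum filter")
  ipk <- ip[keep]; ink <- inp[keep]
  log2fc <- log2((ipk / sf[1] + pseudocount) / (ink / sf[2] + pseudocount))
  p0 <- sum(ip) / (sum(ip) + sum(inp))
  p <- vapply(seq_along(ipk), function(i) {
    binom.test(ipk[i], ipk[i] + ink[i], p = p0)$p.value
  }, numeric(1))
  out <- tibble(gene_id = ip_counts$gene_id[keep],
                ip = as.integer(ipk), input = as.integer(ink),
                log2fc = log2fc, fc = 2^log2fc, p = p)
  attr(out, "size_factors") <- setNames(sf, c("ip", "input"))
  out
}

#' Call RNA targets from a binding-strength table
#'
#' Targets satisfy `fc >= fc_min` (inclusive bound) and `p < p_max`
#' (exclusive). By default the raw p-value is used; `adjust = TRUE`
#' BH-adjusts across the table first.
#'
#' @param tbl a [binding_strength()] tibble.
#' @param fc_min fold-change threshold (2 means log2FC >= 1).
#' @param p_max p-value threshold.
#' @param adjust use BH-adjusted p-values.
#' @return The target rows of `tbl`.
#' @export
call_targets <- function(tbl, fc_min = 2, p_max = 0.05, adjust = FALSE) {
  p <- if (adjust) p.adjust(tbl$p, "BH") else tbl$p
  tbl[tbl$fc >= fc_min & p < p_max, ]
}

#' Select high-variance genes and z-score their trajectories
#'
#' Ranks genes by the standard deviation of their trajectory (ties broken by
#' gene id), keeps the top `ceiling(fraction * n)`, and centres/scales each
#' kept row to mean 0, sd 1. Constant rows inside the selection cannot be
#' scaled and are dropped with a flag.
#'
#' @param mat wide tibble: `gene_id` plus one numeric column per time point.
#' @param fraction fraction of genes to keep (by greatest sd).
#' @return Z-scored tibble of the selected genes; attribute `"dropped"`
#'   lists constant-row gene ids.
#' @export
select_variable <- function(mat, fraction = 0.5) {
  vals <- as.matrix(mat[, setdiff(names(mat), "gene_id")])
  if (ncol(vals) < 2L) abort("need at least 2 time points")
  sds <- apply(vals, 1L, sd)
  ord <- order(-sds, mat$gene_id)
  keep <- ord[seq_len(ceiling(fraction * nrow(mat)))]
  sel <- vals[keep, , drop = FALSE]
  const <- apply(sel, 1L, sd) == 0
  z <- t(scale(t(sel[!const, , drop = FALSE])))
  out <- bind_cols(tibble(gene_id = mat$gene_id[keep][!const]),
                   as_tibble(z))
  attr(out, "dropped") <- mat$gene_id[keep][const]
  out
}

#' Fuzzy c-means clustering of binding trajectories
#'
#' Standard fuzzy c-means with Euclidean distance: memberships
#' `u_ij = 1 / sum_k (d_ij / d_ik)^(2 / (m - 1))` and centroids
#' `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`, iterated until the largest
#' centroid shift falls below `tol` or `max_iter` is reached. The objective
#' `sum_ij u_ij^m d_ij^2` is non-increasing at every step; a gene exactly on
#' a centroid gets membership 1 there. If a cluster ends up empty
#' (no gene with largest membership), the run is re-seeded once and flagged.
#'
#' @param mat z-scored tibble from [select_variable()] (or a numeric matrix
#'   with rownames).
#' @param centers number of clusters `c >= 2`.
#' @param m fuzzifier (> 1); 2 is the usual default.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the maximum centroid shift.
#' @param seed integer seed for centroid initialisation.
#' @return Object of class `artr_cmeans`: `centroids` (c x T), `membership`
#'   (gene x c), `cluster` (argmax membership), `objective` (per-iteration
#'   trace), `iterations`, `converged`, `reseeded`, plus `m`, `centers`,
#'   `seed`.
#' @export
cmeans_fuzzy <- function(mat, centers, m = 2, max_iter = 10000L, tol = 1e-9,
                         seed = 1L) {
  x <- as_trajectory_matrix(mat)
  if (centers < 2L) abort("`centers` must be at least 2")
  if (centers >= nrow(x)) abort("`centers` must be smaller than the number of genes")
  if (m <= 1) abort("fuzzifier `m` must exceed 1")
  fit <- with_seed(seed, cmeans_run(x, centers, m, max_iter, tol))
  if (fit$empty) {
    fit <- with_seed(sub_seed(seed, "reseed"), cmeans_run(x, centers, m,
                                                          max_iter, tol))
    fit$reseeded <- TRUE
    if (fit$empty) warn("a cluster is empty after re-seeding")
  } else {
    fit$reseeded <- FALSE
  }
  structure(c(fit[c("centroids", "membership", "objective", "iterations",
                    "converged", "reseeded")],
              list(cluster = apply(fit$membership, 1L, which.max),
                   centers = centers, m = m, seed = seed,
                   data = x)),
            class = "artr_cmeans")
}

as_trajectory_matrix <- function(mat) {
  if (is.matrix(mat)) return(mat)
  x <- as.matrix(mat[, setdiff(names(mat), "gene_id")])
  rownames(x) <- if ("gene_id" %in% names(mat)) mat$gene_id else NULL
  x
}

cmeans_run <- function(x, centers, m, max_iter, tol) {
  n <- nrow(x)
  cent <- x[sample.int(n, centers), , drop = FALSE]
  obj <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist(x, cent)
    u <- memberships_from_d2(d2, m)
    um <- u^m
    obj <- c(obj, sum(um * d2))
    new_cent <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(new_cent - cent))
    cent <- new_cent
    iterations <- it
    if (shift < tol) { converged <- TRUE; break }
  }
  # final membership against the converged centroids
  d2 <- sq_dist(x, cent)
  u <- memberships_from_d2(d2, m)
  obj <- c(obj, sum(u^m * d2))
  rownames(cent) <- paste0("cluster", seq_len(centers))
  colnames(u) <- rownames(cent)
  hard <- apply(u, 1L, which.max)
  list(centroids = cent, membership = u, objective = obj,
       iterations = iterations, converged = converged,
       empty = length(unique(hard)) < centers)
}

# squared Euclidean distances gene x centroid
sq_dist <- function(x, cent) {
  xx <- rowSums(x^2)
  cc <- rowSums(cent^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(cent)
  pmax(d2, 0)
}

memberships_from_d2 <- function(d2, m) {
  pow <- 1 / (m - 1)
  inv <- (1 / pmax(d2, .Machine$double.xmin))^pow
  u <- inv / rowSums(inv)
  zero <- d2 <= 0
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Minimum centroid distance across candidate cluster numbers
#'
#' Runs [cmeans_fuzzy()] for each `c` in `c_range` and reports the minimum
#' pairwise Euclidean distance between centroids -- the diagnostic curve
#' used to pick the cluster number by its elbow. `c < 2` gives `NA`
#' (undefined), `c >= n` is skipped with a flag.
#'
#' @param mat z-scored tibble or matrix.
#' @param c_range integer vector of candidate cluster numbers.
#' @param m fuzzifier.
#' @param seed integer seed; each `c` uses a derived sub-seed.
#' @return Tibble `c`, `dmin`, `skipped`.
#' @export
dmin_curve <- function(mat, c_range = 2:8, m = 2, seed = 1L) {
  x <- as_trajectory_matrix(mat)
  rows <- lapply(c_range, function(cc) {
    if (cc < 2L) return(tibble(c = cc, dmin = NA_real_, skipped = FALSE))
    if (cc >= nrow(x)) return(tibble(c = cc, dmin = NA_real_, skipped = TRUE))
    fit <- cmeans_fuzzy(x, cc, m = m, seed = sub_seed(seed, paste0("c", cc)))
    tibble(c = cc, dmin = min(dist(fit$centroids)), skipped = FALSE)
  })
  bind_rows(rows)
}

#' @export
print.artr_cmeans <- function(x, ...) {
  cat(sprintf(
    "<artr_cmeans> %d genes, c = %d, m = %g, %d iteration(s)%s%s\n",
    nrow(x$membership), x$centers, x$m, x$iterations,
    if (x$converged) ", converged" else ", iteration cap reached",
    if (x$reseeded) ", re-seeded" else ""))
  print(round(x$centroids, 3))
  invisible(x)
}

#' @describeIn cmeans_fuzzy one row per gene-cluster pair: `gene_id`,
#'   `cluster`, `membership`, `hard` (argmax flag).
#' @param x an `artr_cmeans` object.
#' @param ... unused.
#' @export
tidy.artr_cmeans <- function(x, ...) {
  u <- x$membership
  tibble(
    gene_id = rep(rownames(u) %||% as.character(seq_len(nrow(u))),
                  times = ncol(u)),
    cluster = rep(seq_len(ncol(u)), each = nrow(u)),
    membership = as.vector(u)
  ) %>%
    group_by(.data$gene_id) %>%
    mutate(hard = .data$membership == max(.data$membership)) %>%
    ungroup()
}

#' @describeIn cmeans_fuzzy one-row model summary: cluster count, fuzzifier,
#'   iterations, final objective, convergence, minimum centroid distance.
#' @export
glance.artr_cmeans <- function(x, ...) {
  tibble(centers = x$centers, m = x$m, iterations = x$iterations,
         objective = tail(x$objective, 1L), converged = x$converged,
         reseeded = x$reseeded, dmin = min(dist(x$centroids)))
}
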