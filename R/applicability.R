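# Score a candidate panel's cost/benefit on an expression resource: tau
# tissue specificity, panel expression fraction, variance/mean binning,
# preranked gene-set enrichment, and marker-overlap reporting.

#' Tau tissue-specificity profile
#'
#' For each gene, expression is log transformed (`log(x + 1)` in base
#' `log_base`) and tau computed as `sum(1 - x / max(x)) / (n - 1)` over the
#' `n` tissues: 0 for uniform expression, 1 for single-tissue expression.
#' Genes whose maximum raw expression falls below `floor` are reported as
#' missing (tau undefined at noise level).
#'
#' @param expr Gene x tissue expression matrix (e.g. TPM), >= 2 tissues.
#' @param floor Expression floor in the units of `expr` (default 1).
#' @param log_base Base of the log transform (default 2).
#' @param threshold Tau at or above which a gene is flagged tissue-specific
#'   (default 0.8).
#' @return Object of class `TauProfile`: list with `tau` (named numeric,
#'   NA where undefined), `flagged_specific`, and the parameters used.
#' @export
tau_specificity <- function(expr, floor = 1, log_base = 2, threshold = 0.8) {
  assert_that(is.matrix(expr) && ncol(expr) >= 2,
              "need a gene x tissue matrix with at least 2 tissues")
  assert_that(!is.null(rownames(expr)), "expression matrix needs gene ids")
  lx <- log(expr + 1, base = log_base)
  n <- ncol(expr)
  tau <- vapply(seq_len(nrow(expr)), function(i) {
    if (max(expr[i, ]) < floor) return(NA_real_)
    v <- lx[i, ]
    sum(1 - v / max(v)) / (n - 1)
  }, numeric(1))
  names(tau) <- rownames(expr)
  structure(list(tau = tau,
                 flagged_specific = names(tau)[!is.na(tau) & tau >= threshold],
                 floor = floor, log_base = log_base, threshold = threshold),
            class = "TauProfile")
}

#' @export
print.TauProfile <- function(x, ...) {
  cat(sprintf("TauProfile: %d genes (%d undefined), %d flagged specific at tau >= %.2f\n",
              length(x$tau), sum(is.na(x$tau)), length(x$flagged_specific),
              x$threshold))
  invisible(x)
}

#' Fraction of total expression contributed by a panel, per group
#'
#' @param expr Gene x group expression matrix (e.g. gene x tissue TPM).
#' @param panel A `TargetPanel` or character vector of gene ids; panel
#'   genes missing from `expr` contribute zero (with a warning).
#' @return Named numeric vector of fractions in `[0, 1]` per group (NA for
#'   groups with zero total).
#' @export
panel_expression_fraction <- function(expr, panel) {
  pg <- if (inherits(panel, "TargetPanel")) panel_genes(panel) else panel
  missing <- setdiff(pg, rownames(expr))
  if (length(missing) > 0) {
    warning(sprintf("%d panel gene(s) absent from the expression table", length(missing)))
  }
  pg <- intersect(pg, rownames(expr))
  tot <- colSums(expr)
  part <- if (length(pg) > 0) colSums(expr[pg, , drop = FALSE]) else rep(0, ncol(expr))
  out <- ifelse(tot > 0, part / tot, NA_real_)
  setNames(out, colnames(expr))
}

#' Equal-interval binning of a per-gene statistic with panel proportions
#'
#' Bin edges span `[min, max]` of the statistic in `n_bins` equal
#' intervals; a value falling exactly on an interior edge is resolved to
#' the lower bin. Each bin reports the proportion of its genes that are
#' panel members.
#'
#' @param statistic Named numeric vector (one value per gene).
#' @param panel A `TargetPanel` or character vector of gene ids.
#' @param n_bins Number of bins (default 7).
#' @return Object of class `BinReport`: list with `edges`, `n_genes`,
#'   `n_panel`, `panel_proportion` per bin.
#' @export
bin_genes <- function(statistic, panel, n_bins = 7L) {
  assert_that(!is.null(names(statistic)), "statistic needs gene names")
  rng <- range(statistic)
  assert_that(rng[1] < rng[2], "statistic is constant; cannot bin")
  assert_that(length(unique(statistic)) >= n_bins,
              "fewer distinct values (%d) than bins (%d)",
              length(unique(statistic)), n_bins)
  pg <- if (inherits(panel, "TargetPanel")) panel_genes(panel) else panel
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  w <- (rng[2] - rng[1]) / n_bins
  bin <- pmax(1L, pmin(n_bins, as.integer(ceiling((statistic - rng[1]) / w))))
  is_panel <- names(statistic) %in% pg
  n_genes <- tabulate(bin, nbins = n_bins)
  n_panel <- tabulate(bin[is_panel], nbins = n_bins)
  structure(list(edges = edges, n_genes = n_genes, n_panel = n_panel,
                 panel_proportion = ifelse(n_genes > 0, n_panel / n_genes, NA_real_)),
            class = "BinReport")
}

#' @export
print.BinReport <- function(x, ...) {
  cat(sprintf("BinReport: %d bins, panel proportions %s\n",
              length(x$n_genes),
              paste(sprintf("%.2f", x$panel_proportion), collapse = ", ")))
  invisible(x)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score of a gene set
# within a ranked list. `stat` must be ordered descending.
running_es <- function(stat, is_hit, weight_exponent) {
  n <- length(stat)
  nh <- sum(is_hit)
  w <- abs(stat)^weight_exponent
  hit_w <- ifelse(is_hit, w, 0)
  denom <- sum(hit_w)
  if (denom == 0) hit_w <- ifelse(is_hit, 1 / nh, 0) else hit_w <- hit_w / denom
  miss_w <- ifelse(is_hit, 0, 1 / (n - nh))
  run <- cumsum(hit_w - miss_w)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment of a panel
#'
#' Classic weighted Kolmogorov-Smirnov running-sum statistic: walking down
#' the ranked list, hits increment by `|statistic|^weight_exponent`
#' (normalised over hits) and misses decrement uniformly; the enrichment
#' score (ES) is the extremum of the running sum. The null is built from
#' `n_perm` random gene sets of the same size; NES is the ES divided by
#' the mean absolute null ES of the same sign, and the p value is the
#' fraction of same-sign null ES at least as extreme (add-one smoothed).
#' With a single gene set the FDR reduces to the p value.
#'
#' @param ranked Named numeric vector of the ranking statistic; sorted
#'   descending internally (highest statistic at the top of the list).
#' @param panel A `TargetPanel` or character vector of gene ids; must
#'   overlap the ranked list.
#' @param n_perm Number of gene-set permutations (default 1000).
#' @param weight_exponent KS weighting exponent (default 1; 0 gives the
#'   classical unweighted statistic).
#' @param seed Integer seed for the permutation null.
#' @return Object of class `EnrichmentResult`: list with `es`, `nes`,
#'   `p_value`, `fdr`, `n_perm`, `seed`, `n_hits`.
#' @export
preranked_enrichment <- function(ranked, panel, n_perm = 1000L,
                                 weight_exponent = 1, seed = 1L) {
  assert_that(!is.null(names(ranked)), "ranked statistic needs gene names")
  pg <- if (inherits(panel, "TargetPanel")) panel_genes(panel) else panel
  ord <- order(-ranked, names(ranked))
  stat <- ranked[ord]
  is_hit <- names(stat) %in% pg
  nh <- sum(is_hit)
  assert_that(nh > 0, "panel does not overlap the ranked list")
  assert_that(nh < length(stat), "panel covers the whole ranked list")
  es <- running_es(stat, is_hit, weight_exponent)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    hits <- logical(length(stat))
    hits[sample.int(length(stat), nh)] <- TRUE
    running_es(stat, hits, weight_exponent)
  }, numeric(1)))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  structure(list(es = es, nes = nes, p_value = p, fdr = p,
                 n_perm = as.integer(n_perm), seed = seed, n_hits = nh,
                 weight_exponent = weight_exponent),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: ES %.3f, NES %.2f, p %.3g (FDR %.3g), %d hits, %d permutations\n",
              x$es, x$nes, x$p_value, x$fdr, x$n_hits, x$n_perm))
  invisible(x)
}

#' Marker-gene overlap between a panel and a cell-type marker database
#'
#' Per cell type: the number of markers, the number falling in the panel,
#' and the percentage of markers retained after depletion. Globally: the
#' number and percentage of cell types with at least one panel marker.
#' Cell types with zero markers are skipped with a warning.
#'
#' @param marker_table Named list: cell type to character vector of marker
#'   gene ids.
#' @param panel A `TargetPanel` or character vector of gene ids.
#' @return Object of class `MarkerOverlapReport`: list with `per_type`
#'   (data frame), `n_cell_types`, `n_with_panel_marker`,
#'   `pct_with_panel_marker`.
#' @export
marker_overlap_report <- function(marker_table, panel) {
  assert_that(length(marker_table) > 0 && !is.null(names(marker_table)),
              "marker table must be a non-empty named list")
  pg <- if (inherits(panel, "TargetPanel")) panel_genes(panel) else panel
  sizes <- vapply(marker_table, length, integer(1))
  if (any(sizes == 0)) {
    warning(sprintf("skipping %d cell type(s) with no markers", sum(sizes == 0)))
    marker_table <- marker_table[sizes > 0]
  }
  assert_that(length(marker_table) > 0, "no cell type has markers")
  n_in <- vapply(marker_table, function(mk) length(intersect(mk, pg)), integer(1))
  n_mk <- vapply(marker_table, length, integer(1))
  per_type <- data.frame(cell_type = names(marker_table),
                         n_markers = n_mk, n_in_panel = n_in,
                         pct_retained = 100 * (1 - n_in / n_mk),
                         row.names = NULL)
  structure(list(per_type = per_type,
                 n_cell_types = nrow(per_type),
                 n_with_panel_marker = sum(n_in > 0),
                 pct_with_panel_marker = 100 * sum(n_in > 0) / nrow(per_type)),
            class = "MarkerOverlapReport")
}

#' @export
print.MarkerOverlapReport <- function(x, ...) {
  cat(sprintf("MarkerOverlapReport: %d cell types, %d (%.2f%%) with a panel marker\n",
              x$n_cell_types, x$n_with_panel_marker, x$pct_with_panel_marker))
  invisible(x)
}
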