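# Quantify library recomposition: read-bucket fractions, top-N gene UMI
# fraction, per-cell complexity, and the Marchenko-Pastur signal-component
# count.

#' Partition reads into genomic / targeted / informative buckets
#'
#' Targeted: all `targeted_*` labels from the classification. Among
#' retained reads, those originating from a (non-panel) transcript are
#' informative; retained reads with no transcript of origin are genomic.
#' Origin comes from the synthetic generator's truth table or any external
#' read-to-gene table.
#'
#' @param classification A `ReadClassification`.
#' @param read_origin Data frame with columns `read_id` and `gene` (gene id
#'   for transcript-derived reads, NA otherwise), e.g. the `truth` element
#'   of [simulate_reads()].
#' @return Object of class `BucketFractions`: list with `genomic`,
#'   `targeted`, `informative` percentages summing to 100.
#' @export
bucket_fractions <- function(classification, read_origin) {
  lab <- classification$labels
  gene <- read_origin$gene[match(names(lab), read_origin$read_id)]
  assert_that(all(names(lab) %in% read_origin$read_id),
              "read(s) missing from the origin table")
  targeted <- lab != "retained"
  informative <- !targeted & !is.na(gene)
  genomic <- !targeted & is.na(gene)
  n <- length(lab)
  assert_that(n > 0, "no reads to bucket")
  structure(list(genomic = 100 * sum(genomic) / n,
                 targeted = 100 * sum(targeted) / n,
                 informative = 100 * sum(informative) / n),
            class = "BucketFractions")
}

#' @export
print.BucketFractions <- function(x, ...) {
  cat(sprintf("BucketFractions: genomic %.1f%%, targeted %.1f%%, informative %.1f%%\n",
              x$genomic, x$targeted, x$informative))
  invisible(x)
}

#' Per-cell fraction of UMIs in the top-N expressed genes
#'
#' Genes are ranked library-wide by total UMIs across all cells (ties by
#' gene id); for each cell the fraction of its UMIs falling in the top-N
#' gene set is reported, along with the median over cells. A per-cell
#' ranking mode is provided as an alternative reading.
#'
#' @param matrix Gene x cell count matrix with positive per-cell totals.
#' @param n_list Vector of N values (default 50, 100, 200, 500); values
#'   above the gene count are clamped with a warning.
#' @param ranking `"library"` (default) or `"cell"` (per-cell ranking).
#' @return List with `per_cell` (cells x N matrix of fractions) and
#'   `medians` (named by N).
#' @export
top_n_umi_fraction <- function(matrix, n_list = c(50L, 100L, 200L, 500L),
                               ranking = c("library", "cell")) {
  matrix <- validate_counts(matrix)
  ranking <- match.arg(ranking)
  totals <- colSums(matrix)
  assert_that(all(totals > 0), "every cell must have at least one UMI")
  if (any(n_list > nrow(matrix))) {
    warning(sprintf("clamping N to the gene count (%d)", nrow(matrix)))
    n_list <- pmin(n_list, nrow(matrix))
  }
  per_cell <- sapply(n_list, function(n) {
    if (ranking == "library") {
      gene_tot <- rowSums(matrix)
      top <- rownames(matrix)[order(-gene_tot, rownames(matrix))][seq_len(n)]
      colSums(matrix[top, , drop = FALSE]) / totals
    } else {
      apply(matrix, 2, function(v) sum(sort(v, decreasing = TRUE)[seq_len(n)])) / totals
    }
  })
  per_cell <- matrix(per_cell, ncol = length(n_list),
                     dimnames = list(colnames(matrix), as.character(n_list)))
  list(per_cell = per_cell,
       medians = setNames(apply(per_cell, 2, median), as.character(n_list)))
}

#' Per-cell library complexity profile
#'
#' Genes detected (>= 1 UMI) and total UMIs per cell; the complexity ratio
#' is the ratio of the median genes detected to the median UMIs per cell,
#' and `genes_per_1000_umis` rescales each cell's ratio to 1000 UMIs.
#' Medians use the midpoint convention for even counts.
#'
#' @param matrix Gene x cell count matrix with at least one non-zero cell.
#' @return Object of class `ComplexityProfile`: list with `per_cell`
#'   (data frame: cell, genes_detected, total_umis, genes_per_1000_umis),
#'   `complexity_ratio`, `median_genes_per_1000_umis`.
#' @export
complexity_profile <- function(matrix) {
  matrix <- validate_counts(matrix)
  assert_that(sum(matrix) > 0, "all-zero count matrix")
  genes <- colSums(matrix > 0)
  umis <- colSums(matrix)
  keep <- umis > 0
  genes <- genes[keep]; umis <- umis[keep]
  per_cell <- data.frame(cell = colnames(matrix)[keep],
                         genes_detected = as.integer(genes),
                         total_umis = as.integer(umis),
                         genes_per_1000_umis = 1000 * genes / umis)
  structure(list(per_cell = per_cell,
                 complexity_ratio = median(genes) / median(umis),
                 median_genes_per_1000_umis = median(per_cell$genes_per_1000_umis)),
            class = "ComplexityProfile")
}

#' @export
print.ComplexityProfile <- function(x, ...) {
  cat(sprintf("ComplexityProfile: %d cells, complexity ratio %.3f, median %.0f genes / 1000 UMIs\n",
              nrow(x$per_cell), x$complexity_ratio, x$median_genes_per_1000_umis))
  invisible(x)
}

#' Signal-component count via the Marchenko-Pastur law
#'
#' Counts are normalised per cell to 10,000, log1p transformed, and each
#' gene standardised to mean 0 / variance 1 (zero-variance genes dropped).
#' The eigenvalues of the gene-gene correlation matrix (estimated across
#' cells) are compared against the upper Marchenko-Pastur edge
#' `(1 + sqrt(gamma))^2` with `gamma = n_genes / n_cells`; eigenvalues
#' above the edge are counted as signal components, the rest are
#' indistinguishable from i.i.d. noise.
#'
#' @param matrix Gene x cell count matrix (>= 2 cells, >= 2 genes).
#' @return Object of class `MPModel`: list with `n_cells`, `n_genes`
#'   (after dropping zero-variance genes), `gamma`, `mp_upper_edge`,
#'   `n_signal_components`, `eigenvalues`.
#' @export
signal_components <- function(matrix) {
  matrix <- validate_counts(matrix)
  assert_that(ncol(matrix) >= 2 && nrow(matrix) >= 2,
              "need at least 2 cells and 2 genes")
  totals <- colSums(matrix)
  assert_that(all(totals > 0), "every cell must have at least one UMI")
  norm <- log1p(t(t(matrix) / totals) * 1e4)
  x <- t(norm)                          # cells x genes
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  assert_that(ncol(x) >= 2, "fewer than 2 genes with non-zero variance")
  x <- scale(x)
  n <- nrow(x); p <- ncol(x)
  gamma <- p / n
  lambda <- svd(x, nu = 0, nv = 0)$d^2 / (n - 1)
  edge <- (1 + sqrt(gamma))^2
  structure(list(n_cells = n, n_genes = p, gamma = gamma,
                 mp_upper_edge = edge,
                 n_signal_components = sum(lambda > edge),
                 eigenvalues = lambda),
            class = "MPModel")
}

#' @export
print.MPModel <- function(x, ...) {
  cat(sprintf("MPModel: %d cells x %d genes (gamma %.2f), MP edge %.2f, %d signal component(s)\n",
              x$n_cells, x$n_genes, x$gamma, x$mp_upper_edge,
              x$n_signal_components))
  invisible(x)
}
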