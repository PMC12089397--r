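# Detect unintended depletion by depth-matched pseudobulk comparison between
# a control and a depleted library, separating coordinate-overlap effects
# from sequence-similarity off-target candidates.
#
# Deliberately naive by design: size-factor normalisation (as in DESeq2-style
# DE tools) would interpret the global re-allocation as a depth change and
# mask both the benefit and the off-targets, so none is offered here.

#' Pseudobulk per-gene totals
#'
#' @param matrix Gene x cell count matrix.
#' @return Named numeric vector of per-gene totals (row sums).
#' @export
pseudobulk <- function(matrix) {
  matrix <- validate_counts(matrix)
  rowSums(matrix)
}

#' Depth-matched pseudobulk log2 fold changes
#'
#' Both libraries are reduced to pseudobulk and downsampled (multinomial,
#' seeded) to the smaller total before comparison; a library already at the
#' target depth is left untouched. Log2 fold change uses a pseudocount;
#' the r-squared is from the least-squares fit of `log2(treated + c)` on
#' `log2(control + c)` over non-panel genes.
#'
#' @param control,treated Gene x cell count matrices sharing (part of) a
#'   gene namespace.
#' @param panel Optional `TargetPanel` or gene-id vector: panel genes are
#'   excluded from the regression and from flagging.
#' @param pseudocount Pseudocount for log fold changes (default 1).
#' @param seed Integer seed for the downsampling.
#' @return Object of class `PseudobulkComparison`: list with `table`
#'   (gene, control, treated, log2fc), `r_squared`, `depth`, `pseudocount`,
#'   `panel_genes`.
#' @export
depth_matched_log2fc <- function(control, treated, panel = NULL,
                                 pseudocount = 1, seed = 1L) {
  pb_c <- pseudobulk(control)
  pb_t <- pseudobulk(treated)
  shared <- intersect(names(pb_c), names(pb_t))
  assert_that(length(shared) > 0, "control and treated share no genes")
  pb_c <- pb_c[shared]; pb_t <- pb_t[shared]
  target <- min(sum(pb_c), sum(pb_t))
  resample <- function(pb, s) {
    if (sum(pb) == target) return(pb)
    with_seed(s, setNames(as.numeric(rmultinom(1, target, pb)), names(pb)))
  }
  pb_c <- resample(pb_c, seed)
  pb_t <- resample(pb_t, seed + 1L)
  log2fc <- log2((pb_t + pseudocount) / (pb_c + pseudocount))
  pg <- if (is.null(panel)) character(0)
        else if (inherits(panel, "TargetPanel")) panel_genes(panel)
        else panel
  non_panel <- setdiff(shared, pg)
  r2 <- {
    x <- log2(pb_c[non_panel] + pseudocount)
    y <- log2(pb_t[non_panel] + pseudocount)
    # squared Pearson correlation = r-squared of the simple linear fit,
    # without lm()'s perfect-fit warning on identical inputs
    if (var(x) == 0 || var(y) == 0) 1 else cor(x, y)^2
  }
  structure(list(table = data.frame(gene = shared, control = as.numeric(pb_c),
                                    treated = as.numeric(pb_t),
                                    log2fc = as.numeric(log2fc),
                                    row.names = NULL),
                 r_squared = r2, depth = target, pseudocount = pseudocount,
                 panel_genes = pg, seed = seed),
            class = "PseudobulkComparison")
}

#' @export
print.PseudobulkComparison <- function(x, ...) {
  cat(sprintf("PseudobulkComparison: %d genes at depth %s, r^2 (non-panel, log scale) %.3f\n",
              nrow(x$table), format(x$depth, big.mark = ","), x$r_squared))
  invisible(x)
}

#' Flag putative off-target genes
#'
#' Non-panel genes with log2 fold change below `threshold`, sorted
#' ascending (most depleted first). Raising the threshold can only add
#' flags, never remove them.
#'
#' @param comparison A `PseudobulkComparison`.
#' @param panel A `TargetPanel` or gene-id vector (defaults to the panel
#'   recorded in the comparison).
#' @param threshold Log2 fold-change threshold; -0.5 suits experimental
#'   comparisons, -0.1 the tighter in silico model.
#' @return Data frame (gene, log2fc) sorted ascending by log2fc.
#' @export
flag_offtargets <- function(comparison, panel = NULL, threshold = -0.5) {
  pg <- if (is.null(panel)) comparison$panel_genes
        else if (inherits(panel, "TargetPanel")) panel_genes(panel)
        else panel
  tab <- comparison$table
  tab <- tab[!(tab$gene %in% pg) & tab$log2fc < threshold, c("gene", "log2fc")]
  tab <- tab[order(tab$log2fc, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Non-panel genes overlapping panel footprints in genome coordinates
#'
#' Lists non-panel genes whose genomic span intersects any panel gene span
#' (extended by the depletion flank actually cut) or any panel interval.
#' Genes depleted for this reason are coordinate-overlap casualties, not
#' sequence-similarity off-targets.
#'
#' @param panel A `TargetPanel`.
#' @param annotation A `GeneAnnotation`.
#' @param flank Flank width used when building the depletion reference
#'   (default 100 nt).
#' @return Character vector of gene ids.
#' @export
coordinate_overlap_genes <- function(panel, annotation, flank = 100L) {
  pg <- panel_genes(panel)
  g <- annotation$genes
  pan <- g[g$gene_id %in% pg, , drop = FALSE]
  foot <- GenomicRanges::GRanges(character(0), IRanges::IRanges())
  if (nrow(pan) > 0) {
    foot <- GenomicRanges::GRanges(
      pan$contig, IRanges::IRanges(pmax(1L, pan$start - flank), pan$end + flank))
  }
  if (nrow(panel$intervals) > 0) {
    iv <- panel$intervals
    foot <- c(foot, GenomicRanges::GRanges(
      iv$contig, IRanges::IRanges(iv$start, iv$end)))
  }
  other <- g[!(g$gene_id %in% pg), , drop = FALSE]
  if (nrow(other) == 0 || length(foot) == 0) return(character(0))
  ogr <- GenomicRanges::GRanges(other$contig,
                                IRanges::IRanges(other$start, other$end))
  sort(other$gene_id[IRanges::overlapsAny(ogr, foot)])
}

#' Off-target QC report partitioning flags by mechanism
#'
#' Combines [flag_offtargets()] and [coordinate_overlap_genes()]: flagged
#' genes that overlap a panel footprint are explained by coordinate
#' overlap; the remainder are sequence-similarity candidates deserving
#' guide-level review.
#'
#' @inheritParams flag_offtargets
#' @param annotation A `GeneAnnotation`.
#' @param flank Depletion flank width (default 100 nt).
#' @return List with `flagged`, `coordinate_overlap`,
#'   `sequence_similarity_candidates`, `r_squared`, `threshold`.
#' @export
offtarget_report <- function(comparison, panel, annotation, threshold = -0.5,
                             flank = 100L) {
  flagged <- flag_offtargets(comparison, panel, threshold)
  overlap <- coordinate_overlap_genes(panel, annotation, flank)
  list(flagged = flagged,
       coordinate_overlap = intersect(flagged$gene, overlap),
       sequence_similarity_candidates = setdiff(flagged$gene, overlap),
       r_squared = comparison$r_squared,
       threshold = threshold)
}
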