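# Curate the four removal-target categories (rRNA, Ribo/Mito, non-variable
# genes, intergenic hotspot intervals) and assemble them into a TargetPanel
# plus a depletion reference sequence set.

#' Select non-variable genes (NVGs) across datasets
#'
#' Per dataset: counts are normalised per cell to 10,000 and log1p
#' transformed; genes are ranked by normalised dispersion (variance/mean of
#' the normalised counts, z-scored within 20 equal-frequency mean bins);
#' the top `n_hvg` highly variable genes are dropped; the remainder is
#' ranked by mean expression (descending). Across datasets a gene's
#' aggregate rank is its worst (maximum) per-dataset rank — a gene must be
#' uniformly abundant and non-variable everywhere to score well — and genes
#' absent from any dataset are excluded. The `n_select` best aggregate
#' ranks are returned (ties broken lexicographically by gene id).
#'
#' @param datasets List of gene x cell count matrices sharing a gene
#'   namespace.
#' @param n_hvg Number of top highly variable genes to exclude per dataset.
#' @param n_select Number of NVGs to return (default 155).
#' @param n_bins Mean bins for dispersion normalisation (default 20, clamped
#'   so each bin holds at least ~5 genes on small inputs).
#' @return Character vector of selected gene ids.
#' @export
select_nvg <- function(datasets, n_hvg = 5000L, n_select = 155L, n_bins = 20L) {
  assert_that(length(datasets) >= 1, "need at least one dataset")
  datasets <- lapply(datasets, validate_counts)
  shared <- Reduce(intersect, lapply(datasets, rownames))
  assert_that(length(shared) > 0, "datasets share no genes")
  per_ds <- lapply(datasets, function(m) {
    m <- m[shared, , drop = FALSE]
    assert_that(n_hvg < nrow(m),
                "n_hvg (%d) leaves no genes to rank (dataset has %d shared genes)",
                n_hvg, nrow(m))
    totals <- colSums(m)
    norm <- t(t(m) / pmax(totals, 1)) * 1e4
    mu <- rowMeans(norm)
    v <- apply(norm, 1, var)
    disp <- ifelse(mu > 0, v / mu, 0)
    # normalised dispersion: z-score within equal-frequency mean bins
    k <- max(1L, min(n_bins, nrow(m) %/% 5L))
    bins <- cut(rank(mu, ties.method = "first"), breaks = k, labels = FALSE)
    zdisp <- disp
    for (b in unique(bins)) {
      idx <- bins == b
      s <- sd(disp[idx])
      zdisp[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
    }
    hvg <- names(sort(zdisp, decreasing = TRUE))[seq_len(n_hvg)]
    rest <- setdiff(shared, hvg)
    mu_rest <- sort(mu[rest], decreasing = TRUE)
    rank_of <- setNames(seq_along(mu_rest), names(mu_rest))
    list(hvg = hvg, rank = rank_of)
  })
  # worst (maximum) per-dataset rank; genes dropped as HVG anywhere get Inf
  agg <- vapply(shared, function(g) {
    r <- vapply(per_ds, function(d) {
      if (g %in% names(d$rank)) d$rank[[g]] else Inf
    }, numeric(1))
    max(r)
  }, numeric(1))
  agg <- agg[is.finite(agg)]
  assert_that(length(agg) > 0, "no gene survives HVG exclusion in all datasets")
  ord <- order(agg, names(agg))
  head(names(agg)[ord], n_select)
}

#' Windowed read-start coverage over a contig set
#'
#' Depth is the number of read starts falling in each fixed window
#' (read-start binning, not span overlap).
#'
#' @param reads Data frame with `contig`, `start`, `end` (1-based closed).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param window_size Window width in nt (default 500).
#' @return Object of class `CoverageTrack`: list of per-contig depth
#'   vectors plus `window_size`.
#' @export
coverage_track <- function(reads, contig_lengths, window_size = 500L) {
  assert_that(window_size > 0, "window_size must be positive")
  depths <- lapply(names(contig_lengths), function(ctg) {
    nw <- ceiling(contig_lengths[[ctg]] / window_size)
    d <- integer(nw)
    r <- reads[reads$contig == ctg, , drop = FALSE]
    if (nrow(r) > 0) {
      w <- pmin((r$start - 1L) %/% window_size + 1L, nw)
      tab <- table(w)
      d[as.integer(names(tab))] <- as.integer(tab)
    }
    d
  })
  structure(list(depth = setNames(depths, names(contig_lengths)),
                 window_size = as.integer(window_size)),
            class = "CoverageTrack")
}

gene_granges <- function(annotation, biotype = NULL, flank = 0L) {
  g <- annotation$genes
  if (!is.null(biotype)) g <- g[g$biotype %in% biotype, , drop = FALSE]
  GenomicRanges::GRanges(g$contig,
                         IRanges::IRanges(pmax(1L, g$start - flank), g$end + flank),
                         gene_id = g$gene_id)
}

#' Rank intergenic genomic windows by shared read coverage
#'
#' Reads overlapping any protein-coding gene span (>= 1 bp) are discarded;
#' the remainder are accumulated into fixed windows per dataset by read
#' start. The shared score of a window is its minimum depth across
#' datasets (strict sharing); the output is the top `n_shared` windows by
#' shared score plus, per dataset, its top `n_per_dataset` dataset-specific
#' windows not already chosen, merged and deduplicated. Windows that touch
#' a protein-coding gene span are never reported.
#'
#' @param read_intervals List (one per dataset) of data frames with
#'   `contig`, `start`, `end`.
#' @param annotation A `GeneAnnotation` on the same assembly.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param window_size Window width (default 500 nt).
#' @param n_shared Number of shared top windows (default 100).
#' @param n_per_dataset Number of extra dataset-specific windows per dataset
#'   (default 10).
#' @return Data frame of merged intervals (`contig`, `start`, `end`).
#' @export
rank_genomic_intervals <- function(read_intervals, annotation, contig_lengths,
                                   window_size = 500L, n_shared = 100L,
                                   n_per_dataset = 10L) {
  assert_that(window_size > 0, "window_size must be positive")
  pc <- gene_granges(annotation, biotype = "protein_coding")
  tracks <- lapply(read_intervals, function(reads) {
    if (nrow(reads) > 0) {
      gr <- GenomicRanges::GRanges(reads$contig,
                                   IRanges::IRanges(reads$start, reads$end))
      hit <- IRanges::overlapsAny(gr, pc)
      reads <- reads[!hit, , drop = FALSE]
    }
    coverage_track(reads, contig_lengths, window_size)
  })
  # window table: one row per (contig, window)
  win <- do.call(rbind, lapply(names(contig_lengths), function(ctg) {
    nw <- ceiling(contig_lengths[[ctg]] / window_size)
    data.frame(contig = ctg, window = seq_len(nw))
  }))
  depth_mat <- vapply(tracks, function(tr) {
    unlist(lapply(names(contig_lengths), function(ctg) tr$depth[[ctg]]),
           use.names = FALSE)
  }, numeric(nrow(win)))
  depth_mat <- matrix(depth_mat, nrow = nrow(win))
  # drop windows touching a protein-coding gene span
  wstart <- (win$window - 1L) * window_size + 1L
  wend <- pmin(win$window * window_size,
               unname(contig_lengths[win$contig]))
  wgr <- GenomicRanges::GRanges(win$contig, IRanges::IRanges(wstart, wend))
  clean <- !IRanges::overlapsAny(wgr, pc)
  shared <- apply(depth_mat, 1, min)
  shared[!clean] <- -Inf
  pick <- integer(0)
  ord <- order(-shared, win$contig, win$window)
  ord <- ord[shared[ord] > 0]
  pick <- head(ord, n_shared)
  for (j in seq_len(ncol(depth_mat))) {
    dj <- depth_mat[, j]
    dj[!clean] <- -Inf
    oj <- order(-dj, win$contig, win$window)
    oj <- oj[dj[oj] > 0]
    oj <- setdiff(oj, pick)
    pick <- c(pick, head(oj, n_per_dataset))
  }
  if (length(pick) == 0) {
    return(data.frame(contig = character(), start = integer(), end = integer()))
  }
  sel <- GenomicRanges::reduce(wgr[sort(unique(pick))])
  data.frame(contig = as.character(GenomicRanges::seqnames(sel)),
             start = GenomicRanges::start(sel),
             end = GenomicRanges::end(sel))
}

#' Assemble a removal-target panel
#'
#' Combines the four gene categories plus genomic intervals into a single
#' panel. A gene appearing in more than one category is kept in the first
#' category in precedence order rRNA > mito > ribo > nvg (with a warning);
#' intervals are merged to non-overlapping form. `panel_size` is the number
#' of unique genes across categories.
#'
#' @param ribo_genes,mito_genes,nvg_genes,rrna_genes Character vectors of
#'   gene ids (any may be empty).
#' @param intervals Optional data frame of genomic intervals (`contig`,
#'   `start`, `end`).
#' @return Object of class `TargetPanel` with elements `categories` (list
#'   rrna/mito/ribo/nvg), `intervals`, `panel_size`.
#' @export
assemble_panel <- function(ribo_genes = character(), mito_genes = character(),
                           nvg_genes = character(), rrna_genes = character(),
                           intervals = NULL) {
  cats <- list(rrna = unique(rrna_genes), mito = unique(mito_genes),
               ribo = unique(ribo_genes), nvg = unique(nvg_genes))
  seen <- character(0)
  for (nm in names(cats)) {
    dup <- intersect(cats[[nm]], seen)
    if (length(dup) > 0) {
      warning(sprintf("gene(s) %s already assigned to an earlier category; dropped from '%s'",
                      paste(dup, collapse = ", "), nm))
      cats[[nm]] <- setdiff(cats[[nm]], seen)
    }
    seen <- c(seen, cats[[nm]])
  }
  assert_that(length(seen) > 0, "panel has no genes")
  if (!is.null(intervals) && nrow(intervals) > 0) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      intervals$contig, IRanges::IRanges(intervals$start, intervals$end)))
    intervals <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr),
                            end = GenomicRanges::end(gr))
  } else {
    intervals <- data.frame(contig = character(), start = integer(),
                            end = integer())
  }
  structure(list(categories = cats, intervals = intervals,
                 panel_size = length(seen)),
            class = "TargetPanel")
}

#' @export
print.TargetPanel <- function(x, ...) {
  sizes <- vapply(x$categories, length, integer(1))
  cat(sprintf("TargetPanel: %d genes (%s), %d interval(s)\n", x$panel_size,
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
              nrow(x$intervals)))
  invisible(x)
}

#' All unique gene ids of a panel
#' @param panel A `TargetPanel`.
#' @export
panel_genes <- function(panel) unique(unlist(panel$categories, use.names = FALSE))

#' Panel share of the annotated transcriptome
#'
#' Percentage of the transcriptome represented by the panel's gene
#' categories: `100 * panel_size / (panel_size + n_nontargeted)`.
#'
#' @param panel A `TargetPanel` (or an integer panel size).
#' @param n_nontargeted Number of annotated non-targeted genes.
#' @return Percentage in `[0, 100]`.
#' @export
panel_transcriptome_share <- function(panel, n_nontargeted) {
  size <- if (inherits(panel, "TargetPanel")) panel$panel_size else as.integer(panel)
  100 * size / (size + n_nontargeted)
}

#' Serialize a panel to JSON
#' @param panel A `TargetPanel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(list(categories = panel$categories,
                            intervals = panel$intervals,
                            panel_size = panel$panel_size),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a panel from JSON
#' @param path Path written by [write_panel()].
#' @export
read_panel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- as.data.frame(x$intervals)
  if (nrow(iv) == 0) iv <- NULL
  assemble_panel(ribo_genes = unlist(x$categories$ribo) %||% character(),
                 mito_genes = unlist(x$categories$mito) %||% character(),
                 nvg_genes = unlist(x$categories$nvg) %||% character(),
                 rrna_genes = unlist(x$categories$rrna) %||% character(),
                 intervals = iv)
}

#' Build the depletion reference sequence set for a panel
#'
#' One record per panel gene: the unspliced genomic span plus `flank` nt on
#' each side, clipped at contig ends (strand ignored; the nuclease cuts
#' double-stranded cDNA). One record per genomic interval. rRNA entries are
#' resolved first against record ids in `genome` (taken as full sequences,
#' e.g. dedicated rRNA records) and otherwise against the annotation like
#' other genes.
#'
#' @param panel A `TargetPanel`.
#' @param genome Sequence set of contigs (and optional rRNA records).
#' @param annotation A `GeneAnnotation`.
#' @param flank Flanking width in nt (default 100).
#' @return Sequence set with ids `gene:<id>`, `interval:<contig>:<start>-<end>`,
#'   `rrna:<id>`.
#' @export
build_depletion_reference <- function(panel, genome, annotation, flank = 100L) {
  genome <- as_sequence_set(genome)
  g <- annotation$genes
  gene_ids <- c(panel$categories$mito, panel$categories$ribo,
                panel$categories$nvg)
  rrna_ids <- panel$categories$rrna
  rrna_as_seq <- rrna_ids[rrna_ids %in% names(genome)]
  rrna_as_gene <- setdiff(rrna_ids, rrna_as_seq)
  missing <- setdiff(c(gene_ids, rrna_as_gene), g$gene_id)
  assert_that(length(missing) == 0,
              "panel gene(s) missing from annotation: %s",
              paste(missing, collapse = ", "))
  span_record <- function(gid) {
    row <- g[g$gene_id == gid, ]
    ctg <- genome[[row$contig]]
    s <- max(1L, row$start - flank)
    e <- min(nchar(ctg), row$end + flank)
    substring(ctg, s, e)
  }
  recs <- character(0)
  for (gid in gene_ids) recs[paste0("gene:", gid)] <- span_record(gid)
  for (gid in rrna_as_gene) recs[paste0("rrna:", gid)] <- span_record(gid)
  for (gid in rrna_as_seq) recs[paste0("rrna:", gid)] <- genome[[gid]]
  iv <- panel$intervals
  for (i in seq_len(nrow(iv))) {
    ctg <- genome[[iv$contig[i]]]
    assert_that(!is.null(ctg), "interval contig '%s' missing from genome",
                iv$contig[i])
    assert_that(iv$end[i] <= nchar(ctg), "interval beyond contig '%s' end",
                iv$contig[i])
    recs[sprintf("interval:%s:%d-%d", iv$contig[i], iv$start[i], iv$end[i])] <-
      substring(ctg, iv$start[i], iv$end[i])
  }
  as_sequence_set(recs)
}
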