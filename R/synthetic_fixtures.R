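# Generate genomes, annotations, count matrices and barcoded read sets with
# planted structure (abundant panel-like genes, housekeeping and
# highly-variable genes, intergenic hotspot windows, rRNA-like records) so
# every other module is testable without downloads. All generators are pure
# functions of (spec, seed); truth labels are emitted for every read so
# downstream recovery checks compare against exact references.

#' Specification for a synthetic single-cell library
#'
#' Defaults emulate a modest droplet scRNA-seq experiment dominated by a
#' compact set of highly abundant genes: the planted "panel" genes jointly
#' hold an expected `panel_share` of every cell's UMIs, mirroring the
#' situation where ribosomal/mitochondrial/housekeeping material crowds out
#' informative molecules. Baseline abundances are log-normal; per-cell
#' depth is fixed at `depth`.
#'
#' @param n_cells,n_genes Library dimensions (defaults 1000 x 2000).
#' @param depth UMIs per cell (default 2000, degenerate distribution).
#' @param abundance_sigma Log-normal sigma of baseline gene abundances
#'   (default 1; 0 gives uniform expected abundance).
#' @param n_panel Number of planted abundant panel genes (default 100).
#' @param panel_share Expected fraction of UMIs held by the panel genes
#'   (default 0.5).
#' @param n_housekeeping Planted high-mean, low-variance genes (default 0).
#' @param n_hvg Planted high-variance genes (default 0).
#' @param hvg_sigma Extra per-cell log-normal sigma for HVG-like genes
#'   (default 2).
#' @param n_hotspots Intergenic hotspot windows in the genome (default 2).
#' @param n_rrna rRNA-like records in the genome (default 1).
#' @param hotspot_frac,rrna_frac Fractions of the final read set drawn from
#'   hotspot windows / rRNA-like records when simulating reads (default 0).
#' @param read_length cDNA read length (default 90).
#' @param gene_length,intergenic_gap Gene span and gap widths in the
#'   synthetic genome (defaults 600 / 400 nt).
#' @param barcode_len,umi_len Barcode geometry (defaults 16 / 12).
#' @param overlap_pair Plant one extra non-panel gene nested inside the
#'   first panel gene (default FALSE).
#' @return List of class `LibrarySpec`.
#' @export
library_spec <- function(n_cells = 1000L, n_genes = 2000L, depth = 2000L,
                         abundance_sigma = 1, n_panel = 100L,
                         panel_share = 0.5, n_housekeeping = 0L, n_hvg = 0L,
                         hvg_sigma = 2, n_hotspots = 2L, n_rrna = 1L,
                         hotspot_frac = 0, rrna_frac = 0, read_length = 90L,
                         gene_length = 600L, intergenic_gap = 400L,
                         barcode_len = 16L, umi_len = 12L,
                         overlap_pair = FALSE) {
  assert_that(n_panel + n_housekeeping + n_hvg <= n_genes,
              "planted gene sets exceed n_genes")
  assert_that(panel_share > 0 && panel_share < 1,
              "panel_share must be in (0, 1)")
  assert_that(hotspot_frac >= 0 && rrna_frac >= 0 &&
                hotspot_frac + rrna_frac < 1,
              "hotspot_frac + rrna_frac must be in [0, 1)")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    depth = as.integer(depth), abundance_sigma = abundance_sigma,
    gene_ids = gene_ids,
    panel_genes = if (n_panel > 0) gene_ids[seq_len(n_panel)] else character(0),
    housekeeping_genes = if (n_housekeeping > 0)
      gene_ids[n_panel + seq_len(n_housekeeping)] else character(0),
    hvg_genes = if (n_hvg > 0)
      gene_ids[n_panel + n_housekeeping + seq_len(n_hvg)] else character(0),
    panel_share = panel_share, hvg_sigma = hvg_sigma,
    n_hotspots = as.integer(n_hotspots), n_rrna = as.integer(n_rrna),
    hotspot_frac = hotspot_frac, rrna_frac = rrna_frac,
    read_length = as.integer(read_length),
    gene_length = as.integer(gene_length),
    intergenic_gap = as.integer(intergenic_gap),
    barcode_len = as.integer(barcode_len), umi_len = as.integer(umi_len),
    overlap_pair = isTRUE(overlap_pair)),
    class = "LibrarySpec")
}

#' Generate a synthetic genome and annotation
#'
#' Genes are laid head-to-tail on one contig separated by intergenic gaps;
#' hotspot windows (500 nt, aligned to the 500-nt window grid) are placed
#' in intergenic space downstream of the genes; rRNA-like sequences are
#' separate records outside the annotation. Reproducible per seed.
#'
#' @param spec A `LibrarySpec`.
#' @param seed Integer seed.
#' @return List with `genome` (sequence set), `annotation`
#'   (`GeneAnnotation`), `hotspots` (data frame contig/start/end),
#'   `rrna_ids`.
#' @export
make_genome <- function(spec, seed = 1L) {
  with_seed(seed, {
    pitch <- spec$gene_length + spec$intergenic_gap
    gene_start <- (seq_len(spec$n_genes) - 1L) * pitch + spec$intergenic_gap %/% 2L + 1L
    gene_end <- gene_start + spec$gene_length - 1L
    gene_region_end <- spec$n_genes * pitch
    # hotspots on the 500-nt window grid, past the gene region
    first_w <- ceiling(gene_region_end / 500) + 2L
    hs_start <- (first_w + 2L * (seq_len(spec$n_hotspots) - 1L)) * 500L + 1L
    contig_len <- max(gene_region_end,
                      if (spec$n_hotspots > 0) max(hs_start) + 999L else 0L) + 500L
    chr1 <- paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
                  collapse = "")
    genes <- data.frame(gene_id = spec$gene_ids, contig = "chr1",
                        start = gene_start, end = gene_end,
                        strand = rep_len(c("+", "-"), spec$n_genes),
                        biotype = "protein_coding")
    if (spec$overlap_pair) {
      assert_that(length(spec$panel_genes) > 0,
                  "overlap_pair requires at least one panel gene")
      host <- genes[genes$gene_id == spec$panel_genes[1], ]
      genes <- rbind(genes, data.frame(
        gene_id = "g_overlap", contig = "chr1",
        start = host$start + 50L, end = host$end - 50L,
        strand = "+", biotype = "protein_coding"))
    }
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end)
    seqs <- c(chr1 = chr1)
    rrna_ids <- character(0)
    if (spec$n_rrna > 0) {
      rrna_ids <- sprintf("rRNA%d", seq_len(spec$n_rrna))
      seqs[rrna_ids] <- random_dna(spec$n_rrna, 1500L)
    }
    hotspots <- if (spec$n_hotspots > 0) {
      data.frame(contig = "chr1", start = hs_start, end = hs_start + 499L)
    } else {
      data.frame(contig = character(), start = integer(), end = integer())
    }
    list(genome = as_sequence_set(seqs),
         annotation = gene_annotation(genes, exons),
         hotspots = hotspots, rrna_ids = rrna_ids)
  })
}

# Baseline gene weights with planted structure; panel genes are rescaled so
# their expected UMI share equals spec$panel_share.
base_weights <- function(spec) {
  w <- rlnorm(spec$n_genes, meanlog = 0, sdlog = spec$abundance_sigma)
  names(w) <- spec$gene_ids
  if (length(spec$housekeeping_genes) > 0) {
    w[spec$housekeeping_genes] <- 3 * max(w)
  }
  if (length(spec$panel_genes) > 0) {
    f <- spec$panel_share
    wp <- sum(w[spec$panel_genes])
    wn <- sum(w) - wp
    w[spec$panel_genes] <- w[spec$panel_genes] * (f * wn) / ((1 - f) * wp)
  }
  w
}

#' Simulate a gene x cell UMI count matrix
#'
#' Per-cell totals are fixed at `spec$depth`; each cell's counts are a
#' multinomial draw over cell-specific abundances (baseline log-normal
#' weights, panel genes rescaled to the planted UMI share, HVG-like genes
#' jittered per cell by an extra log-normal factor).
#'
#' @param spec A `LibrarySpec`.
#' @param seed Integer seed.
#' @return Integer gene x cell matrix with gene ids and generated cell
#'   barcodes.
#' @export
simulate_counts <- function(spec, seed = 1L) {
  with_seed(seed, {
    w <- base_weights(spec)
    barcodes <- unique(random_dna(spec$n_cells * 2L, spec$barcode_len))
    assert_that(length(barcodes) >= spec$n_cells, "barcode collision overflow")
    barcodes <- barcodes[seq_len(spec$n_cells)]
    m <- matrix(0L, nrow = spec$n_genes, ncol = spec$n_cells,
                dimnames = list(spec$gene_ids, barcodes))
    for (j in seq_len(spec$n_cells)) {
      wc <- w
      if (length(spec$hvg_genes) > 0) {
        wc[spec$hvg_genes] <- wc[spec$hvg_genes] *
          rlnorm(length(spec$hvg_genes), 0, spec$hvg_sigma)
      }
      m[, j] <- as.integer(rmultinom(1, spec$depth, wc))
    }
    m
  })
}

#' Simulate a barcoded read set from a count matrix
#'
#' One read pair per UMI: R1 is cell barcode + random UMI, R2 a random
#' substring of the gene's unspliced genomic span (matching the depletion
#' reference's unspliced convention). Additional reads are drawn from
#' hotspot windows and rRNA-like records so that they constitute
#' `spec$hotspot_frac` and `spec$rrna_frac` of the final read set. Truth
#' labels (origin and gene) are emitted for every read.
#'
#' @param matrix Gene x cell count matrix (genes must exist in the
#'   annotation).
#' @param genome_fx Output of [make_genome()] (genome, annotation,
#'   hotspots, rrna_ids).
#' @param spec A `LibrarySpec`.
#' @param seed Integer seed.
#' @return List with `reads` (a `BarcodedReadSet`) and `truth` (data frame:
#'   read_id, origin in gene/hotspot/rrna, gene id or NA).
#' @export
simulate_reads <- function(matrix, genome_fx, spec, seed = 1L) {
  ann <- genome_fx$annotation$genes
  missing <- setdiff(rownames(matrix), ann$gene_id)
  assert_that(length(missing) == 0, "matrix gene(s) missing from annotation: %s",
              paste(head(missing, 5), collapse = ", "))
  with_seed(seed, {
    idx <- which(matrix > 0, arr.ind = TRUE)
    gene_idx <- rep(idx[, 1], matrix[idx])
    cell_idx <- rep(idx[, 2], matrix[idx])
    n_tx <- length(gene_idx)
    gids <- rownames(matrix)[gene_idx]
    row <- match(gids, ann$gene_id)
    contig_seq <- genome_fx$genome[[ann$contig[1]]]
    span_len <- ann$end[row] - ann$start[row] + 1L
    rl <- pmin(spec$read_length, span_len)
    if (any(rl < spec$read_length)) {
      warning("read length clamped to gene length for some genes")
    }
    off <- floor(runif(n_tx) * (span_len - rl + 1L))
    cdna <- substring(contig_seq, ann$start[row] + off, ann$start[row] + off + rl - 1L)
    barcode <- colnames(matrix)[cell_idx]
    origin <- rep("gene", n_tx)
    gene_lab <- gids
    # extra reads realising the requested bucket fractions
    p_hs <- spec$hotspot_frac; p_rr <- spec$rrna_frac
    denom <- 1 - p_hs - p_rr
    n_hs <- if (p_hs > 0) round(n_tx * p_hs / denom) else 0L
    n_rr <- if (p_rr > 0) round(n_tx * p_rr / denom) else 0L
    if (n_hs > 0) {
      assert_that(nrow(genome_fx$hotspots) > 0, "spec requests hotspot reads but genome has no hotspots")
      hs <- genome_fx$hotspots[sample.int(nrow(genome_fx$hotspots), n_hs, replace = TRUE), ]
      o <- floor(runif(n_hs) * (hs$end - hs$start - spec$read_length + 2L))
      cdna <- c(cdna, substring(contig_seq, hs$start + o,
                                hs$start + o + spec$read_length - 1L))
      barcode <- c(barcode, sample(colnames(matrix), n_hs, replace = TRUE))
      origin <- c(origin, rep("hotspot", n_hs))
      gene_lab <- c(gene_lab, rep(NA_character_, n_hs))
    }
    if (n_rr > 0) {
      assert_that(length(genome_fx$rrna_ids) > 0, "spec requests rRNA reads but genome has no rRNA records")
      rid <- sample(genome_fx$rrna_ids, n_rr, replace = TRUE)
      rseq <- unname(genome_fx$genome[rid])
      o <- floor(runif(n_rr) * (nchar(rseq) - spec$read_length + 1L))
      cdna <- c(cdna, substring(rseq, 1L + o, o + spec$read_length))
      barcode <- c(barcode, sample(colnames(matrix), n_rr, replace = TRUE))
      origin <- c(origin, rep("rrna", n_rr))
      gene_lab <- c(gene_lab, rep(NA_character_, n_rr))
    }
    n <- length(cdna)
    reads <- data.frame(
      read_id = sprintf("r%07d", seq_len(n)),
      barcode = barcode,
      umi = random_dna(n, spec$umi_len),
      cdna = cdna)
    list(reads = barcoded_read_set(reads, spec$barcode_len, spec$umi_len),
         truth = data.frame(read_id = reads$read_id, origin = origin,
                            gene = gene_lab))
  })
}
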