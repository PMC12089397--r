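# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Random DNA string under the current RNG state.
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Minimal GTF text for a set of genes (single exon spanning the gene).
gtf_text <- function(genes) {
  unlist(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    attr <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
    c(sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\t%s",
              g$contig, g$start, g$end, g$strand, attr),
      sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
              g$contig, g$start, g$end, g$strand, attr))
  }))
}

# Small count matrix with named dims.
toy_counts <- function(n_genes, n_cells, lambda = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("cell%03d", seq_len(n_cells))))
    storage.mode(m) <- "integer"
    m
  })
}

# A compact library spec for read-level tests.
small_read_spec <- function(depth = 120L, panel_share = 0.4, ...) {
  library_spec(n_cells = 30L, n_genes = 40L, depth = depth, n_panel = 10L,
               panel_share = panel_share, n_hotspots = 2L, n_rrna = 1L,
               gene_length = 400L, intergenic_gap = 300L, ...)
}
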