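# Hand-built multi-dataset count fixtures with planted housekeeping (high
# mean, low variance) and variable genes let the NVG ranking be checked
# against its definition.
nvg_fixture <- function(seed) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", 1:30)
    mk <- function(bimodal_gene = NULL) {
      m <- matrix(rpois(30 * 40, 5), nrow = 30,
                  dimnames = list(genes, sprintf("c%02d", 1:40)))
      m["g01", ] <- rpois(40, 60)              # housekeeping: uniform, abundant
      m["g02", ] <- rpois(40, 40)              # second abundant gene
      m["g03", ] <- rpois(40, 30) * rbinom(40, 1, 0.5)  # variable
      if (!is.null(bimodal_gene)) {
        m[bimodal_gene, ] <- rpois(40, 100) * rbinom(40, 1, 0.5)
      }
      storage.mode(m) <- "integer"
      m
    }
    list(d1 = mk(), d2 = mk(), d3 = mk("g04"))
  })
}

test_that("NVG selection keeps planted housekeeping genes and drops HVGs", {
  ds <- nvg_fixture(2)
  sel <- select_nvg(ds, n_hvg = 3, n_select = 10)
  expect_true("g01" %in% sel)
  expect_true("g02" %in% sel)
  # g03 is variable in every dataset, g04 bursts only in d3; both must be
  # excluded because HVG membership anywhere disqualifies
  expect_false("g03" %in% sel)
  expect_false("g04" %in% sel)
  expect_length(sel, 10)
})

test_that("a top-mean gene planted as HVG in one dataset is excluded", {
  ds <- nvg_fixture(6)
  # make g05 the most abundant gene everywhere but wildly variable in d1
  for (n in names(ds)) ds[[n]]["g05", ] <- 80L
  withr::with_seed(8, {
    ds$d1["g05", ] <- as.integer(rpois(40, 160) * rbinom(40, 1, 0.5))
  })
  sel <- select_nvg(ds, n_hvg = 2, n_select = 10)
  expect_false("g05" %in% sel)
})

test_that("single-dataset NVG selection is the mean ranking of the non-HVG set", {
  ds <- nvg_fixture(3)[1]
  m <- ds[[1]]
  n_hvg <- 3
  all_rest <- select_nvg(ds, n_hvg = n_hvg, n_select = 30 - n_hvg)
  # recompute: normalise, dispersion z-score in mean bins, drop top 3,
  # rank remainder by mean
  norm <- t(t(m) / colSums(m)) * 1e4
  mu <- rowMeans(norm)
  disp <- apply(norm, 1, var) / mu
  bins <- cut(rank(mu, ties.method = "first"), min(20, nrow(m) %/% 5), labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    z[i] <- if (sd(disp[i]) > 0) (disp[i] - mean(disp[i])) / sd(disp[i]) else 0
  }
  hvg <- names(sort(z, decreasing = TRUE))[1:n_hvg]
  want <- names(sort(mu[setdiff(rownames(m), hvg)], decreasing = TRUE))
  expect_identical(all_rest, want)
  expect_error(select_nvg(ds, n_hvg = 30), "leaves no genes")
})

interval_fixture <- function() {
  genes <- data.frame(gene_id = c("pcA", "pcB"), contig = "chr1",
                      start = c(1001L, 3001L), end = c(1800L, 3900L),
                      strand = "+", biotype = "protein_coding")
  ann <- gene_annotation(genes)
  lens <- c(chr1 = 10000L)
  # shared intergenic hotspot in window 15 (7001-7500); dataset-specific
  # hotspot in window 18 (8501-9000) for d1 only; reads inside pcA ignored
  mk_reads <- function(shared_n, specific_n, genic_n) {
    data.frame(
      contig = "chr1",
      start = c(rep(7100L, shared_n), rep(8600L, specific_n), rep(1100L, genic_n)),
      end = c(rep(7190L, shared_n), rep(8690L, specific_n), rep(1190L, genic_n)))
  }
  list(ann = ann, lens = lens,
       reads = list(d1 = mk_reads(30, 20, 50),
                    d2 = mk_reads(25, 0, 50),
                    d3 = mk_reads(20, 0, 50)))
}

test_that("interval ranking finds the shared intergenic hotspot first", {
  fx <- interval_fixture()
  got <- rank_genomic_intervals(fx$reads, fx$ann, fx$lens,
                                n_shared = 1, n_per_dataset = 0)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 7001L)
  expect_equal(got$end, 7500L)

  # dataset-specific windows are appended after the shared ones
  got2 <- rank_genomic_intervals(fx$reads, fx$ann, fx$lens,
                                 n_shared = 1, n_per_dataset = 1)
  expect_true(any(got2$start == 8501L))
})

test_that("reads inside protein-coding genes contribute nothing", {
  fx <- interval_fixture()
  genic_only <- lapply(fx$reads, function(r) r[r$start == 1100L, , drop = FALSE])
  got <- rank_genomic_intervals(genic_only, fx$ann, fx$lens,
                                n_shared = 10, n_per_dataset = 10)
  expect_equal(nrow(got), 0L)

  empty <- lapply(fx$reads, function(r) r[0, , drop = FALSE])
  expect_equal(nrow(rank_genomic_intervals(empty, fx$ann, fx$lens)), 0L)
})

test_that("selected windows never overlap protein-coding genes", {
  fx <- interval_fixture()
  withr::with_seed(4, {
    rand_reads <- lapply(1:3, function(i) {
      st <- sample.int(9900, 400)
      data.frame(contig = "chr1", start = st, end = st + 90L)
    })
  })
  got <- rank_genomic_intervals(rand_reads, fx$ann, fx$lens,
                                n_shared = 5, n_per_dataset = 3)
  if (nrow(got) > 0) {
    gr <- GenomicRanges::GRanges(got$contig, IRanges::IRanges(got$start, got$end))
    pc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1001, 3001), c(1800, 3900)))
    expect_false(any(IRanges::overlapsAny(gr, pc)))
  }
})

test_that("panel assembly reproduces the 90+10+155 composition", {
  ribo <- sprintf("RP%02d", 1:90)
  mito <- sprintf("MT-%02d", 1:10)
  nvg <- sprintf("NVG%03d", 1:155)
  panel <- assemble_panel(ribo_genes = ribo, mito_genes = mito, nvg_genes = nvg)
  expect_equal(panel$panel_size, 255L)
  expect_setequal(panel_genes(panel), c(ribo, mito, nvg))

  # duplicate between ribo and nvg is deduplicated with a warning
  expect_warning(
    dup <- assemble_panel(ribo_genes = ribo, mito_genes = mito,
                          nvg_genes = c(nvg, ribo[1])),
    "already assigned")
  expect_equal(dup$panel_size, 255L)

  expect_error(assemble_panel(intervals = data.frame(contig = "chr1",
                                                     start = 1L, end = 500L)),
               "no genes")
})

test_that("panel assembly is permutation invariant and round-trips JSON", {
  a <- assemble_panel(ribo_genes = c("r2", "r1"), mito_genes = c("m1"),
                      nvg_genes = c("n3", "n1"),
                      intervals = data.frame(contig = "chr1",
                                             start = c(1L, 600L),
                                             end = c(500L, 900L)))
  b <- assemble_panel(ribo_genes = c("r1", "r2"), mito_genes = "m1",
                      nvg_genes = c("n1", "n3"),
                      intervals = data.frame(contig = "chr1",
                                             start = c(600L, 1L),
                                             end = c(900L, 500L)))
  expect_equal(a$panel_size, b$panel_size)
  expect_setequal(panel_genes(a), panel_genes(b))
  expect_equal(a$intervals, b$intervals)

  f <- withr::local_tempfile(fileext = ".json")
  write_panel(a, f)
  back <- read_panel(f)
  expect_equal(back$panel_size, a$panel_size)
  expect_setequal(panel_genes(back), panel_genes(a))
  expect_equal(back$intervals, a$intervals)
})

test_that("depletion reference takes unspliced spans with clipped flanks", {
  withr::with_seed(21, {
    genome <- c(chr1 = rand_seq(1000), rRNA1 = rand_seq(300))
  })
  genes <- data.frame(gene_id = c("gMid", "gEdge"), contig = "chr1",
                      start = c(201L, 1L), end = c(500L, 50L),
                      strand = "+", biotype = "protein_coding")
  ann <- gene_annotation(genes)
  panel <- assemble_panel(ribo_genes = "gMid", nvg_genes = "gEdge",
                          rrna_genes = "rRNA1",
                          intervals = data.frame(contig = "chr1",
                                                 start = 601L, end = 700L))
  ref <- build_depletion_reference(panel, genome, ann, flank = 100)
  expect_equal(nchar(ref[["gene:gMid"]]), 500L)   # 300 + 2 x 100
  expect_equal(nchar(ref[["gene:gEdge"]]), 150L)  # left clip at contig start
  expect_equal(unname(ref[["rrna:rRNA1"]]), unname(genome[["rRNA1"]]))
  expect_equal(nchar(ref[["interval:chr1:601-700"]]), 100L)
  expect_identical(unname(ref[["gene:gMid"]]), substring(genome[["chr1"]], 101, 600))

  # total reference length equals the independent clipped-span arithmetic
  expected_total <- 500 + 150 + 300 + 100
  expect_equal(sum(nchar(ref)), expected_total)

  bad <- assemble_panel(ribo_genes = "missing_gene")
  expect_error(build_depletion_reference(bad, genome, ann), "missing from annotation")
})
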