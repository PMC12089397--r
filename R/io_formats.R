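# Readers/writers for the standard formats the toolkit touches, plus the
# light-weight containers shared by all modules.
#
# Containers are deliberately simple R structures:
#   * sequence set   -- named character vector (A/C/G/T/N, upper case)
#   * gene annotation-- S3 list with `genes` and `exons` data frames,
#                       1-based closed coordinates (the GTF/GRanges convention)
#   * barcoded reads -- S3 list wrapping a data frame of (read_id, barcode,
#                       umi, cdna) plus the barcode/UMI geometry
#   * count matrix   -- integer matrix, genes x cells, with dimnames
#
# Heavy-format parsing is delegated to Biostrings (FASTA/FASTQ), rtracklayer
# (GTF/BED) and Matrix (MatrixMarket); this module only validates and converts.

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a validated sequence set
#'
#' A sequence set is a named character vector of upper-case nucleotide
#' sequences restricted to the alphabet A/C/G/T/N. Lower-case input is
#' upcased and IUPAC ambiguity codes (or any other letter) are mapped to N.
#'
#' @param x Named character vector of sequences.
#' @return Named character vector with unique names, upper case, alphabet
#'   restricted to A/C/G/T/N.
#' @export
as_sequence_set <- function(x) {
  assert_that(is.character(x) && length(x) > 0, "sequence set is empty")
  ids <- names(x)
  assert_that(!is.null(ids) && all(nzchar(ids)), "sequence set requires names")
  assert_that(!anyDuplicated(ids), "duplicate sequence ids: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  x <- toupper(x)
  x <- gsub("[^ACGTN]", "N", x)
  assert_that(all(nchar(x) > 0), "empty sequence in set")
  x
}

#' Read a FASTA file into a sequence set
#'
#' @param path Path to a FASTA file (gzip transparent).
#' @return A sequence set (see [as_sequence_set()]).
#' @export
load_sequences <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  dna <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop_fmt("malformed FASTA '%s': %s", path, conditionMessage(e))
  )
  assert_that(length(dna) > 0, "FASTA '%s' contains no records", path)
  ids <- sub("\\s.*$", "", names(dna))
  as_sequence_set(setNames(as.character(dna), ids))
}

#' Write a sequence set to FASTA
#'
#' @param seqs A sequence set.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_sequences <- function(seqs, path, width = 70L) {
  seqs <- as_sequence_set(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

#' Construct a gene annotation
#'
#' Coordinates are 1-based closed (GTF convention) throughout the package;
#' BED input/output is converted at the boundary by rtracklayer.
#'
#' @param genes Data frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `biotype`.
#' @param exons Data frame with columns `gene_id`, `start`, `end` (may be
#'   empty).
#' @return An object of class `GeneAnnotation`.
#' @export
gene_annotation <- function(genes, exons = NULL) {
  need <- c("gene_id", "contig", "start", "end", "strand", "biotype")
  assert_that(all(need %in% names(genes)), "genes table missing columns: %s",
              paste(setdiff(need, names(genes)), collapse = ", "))
  assert_that(!anyDuplicated(genes$gene_id), "duplicate gene ids")
  assert_that(all(genes$start >= 1 & genes$start <= genes$end),
              "invalid gene coordinates (need 1 <= start <= end)")
  if (is.null(exons) || nrow(exons) == 0) {
    exons <- data.frame(gene_id = character(), start = integer(), end = integer())
  } else {
    idx <- match(exons$gene_id, genes$gene_id)
    assert_that(!anyNA(idx), "exon references unknown gene")
    ok <- exons$start >= genes$start[idx] & exons$end <= genes$end[idx]
    assert_that(all(ok), "exon outside gene span for gene(s): %s",
                paste(unique(exons$gene_id[!ok]), collapse = ", "))
  }
  structure(list(genes = as.data.frame(genes), exons = as.data.frame(exons)),
            class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat(sprintf("GeneAnnotation: %d genes (%d protein_coding), %d exons on %d contig(s)\n",
              nrow(x$genes), sum(x$genes$biotype == "protein_coding"),
              nrow(x$exons), length(unique(x$genes$contig))))
  invisible(x)
}

#' Read a GTF file into a gene annotation
#'
#' Gene and exon features are retained; coordinates stay 1-based closed.
#' The gene biotype is taken from the `gene_biotype` (Ensembl) or
#' `gene_type` (GENCODE) attribute, defaulting to `"protein_coding"` when
#' absent.
#'
#' @param path Path to a GTF file.
#' @return A `GeneAnnotation`.
#' @export
load_annotation <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  assert_that("gene_id" %in% names(md) && !anyNA(md$gene_id),
              "GTF '%s' lacks gene_id attributes", path)
  is_gene <- md$type == "gene"
  assert_that(any(is_gene), "GTF '%s' has no gene features", path)
  bio <- if ("gene_biotype" %in% names(md)) md$gene_biotype
         else if ("gene_type" %in% names(md)) md$gene_type
         else rep("protein_coding", length(gr))
  bio[is.na(bio)] <- "protein_coding"
  genes <- data.frame(
    gene_id = md$gene_id[is_gene],
    contig  = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start   = GenomicRanges::start(gr)[is_gene],
    end     = GenomicRanges::end(gr)[is_gene],
    strand  = as.character(GenomicRanges::strand(gr)[is_gene]),
    biotype = bio[is_gene]
  )
  is_exon <- md$type == "exon"
  exons <- data.frame(
    gene_id = md$gene_id[is_exon],
    start   = GenomicRanges::start(gr)[is_exon],
    end     = GenomicRanges::end(gr)[is_exon]
  )
  gene_annotation(genes, exons)
}

#' Write a gene annotation to GTF
#'
#' @param annotation A `GeneAnnotation`.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @export
write_annotation <- function(annotation, path, source = "scdeplete") {
  g <- annotation$genes
  attr_of <- function(gid, bt) sprintf('gene_id "%s"; gene_biotype "%s";', gid, bt)
  lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   g$contig, source, g$start, g$end, g$strand,
                   attr_of(g$gene_id, g$biotype))
  e <- annotation$exons
  if (nrow(e) > 0) {
    idx <- match(e$gene_id, g$gene_id)
    lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                              g$contig[idx], source, e$start, e$end,
                              g$strand[idx], attr_of(e$gene_id, g$biotype[idx])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read BED intervals
#'
#' BED's 0-based half-open coordinates are converted to the package's
#' 1-based closed convention (rtracklayer performs the conversion).
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `contig`, `start`, `end` (1-based closed).
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr))
}

#' Write intervals to BED
#'
#' @param intervals Data frame with `contig`, `start`, `end` (1-based closed).
#' @param path Output path.
#' @export
write_intervals_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(intervals$contig,
                               IRanges::IRanges(intervals$start, intervals$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a gene x cell UMI count matrix
#'
#' Reads the CellRanger-style triplet of MatrixMarket matrix plus gene and
#' barcode label files.
#'
#' @param matrix_path Path to the `.mtx` file (genes as rows).
#' @param genes_path Path to a one-column gene id file.
#' @param barcodes_path Path to a one-column cell barcode file.
#' @return Integer matrix, genes x cells, with dimnames.
#' @export
load_counts <- function(matrix_path, genes_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  assert_that(nrow(m) == length(genes),
              "gene labels (%d) do not match matrix rows (%d)", length(genes), nrow(m))
  assert_that(ncol(m) == length(barcodes),
              "cell barcodes (%d) do not match matrix columns (%d)",
              length(barcodes), ncol(m))
  m <- as.matrix(m)
  assert_that(all(m >= 0), "negative entries in count matrix")
  assert_that(all(m == round(m)), "non-integer entries in count matrix")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, barcodes)
  validate_counts(m)
}

#' Write a count matrix as MatrixMarket triplet
#'
#' Round-trips bit-exactly with [load_counts()].
#'
#' @param counts Integer genes x cells matrix with dimnames.
#' @param matrix_path,genes_path,barcodes_path Output paths.
#' @export
write_counts <- function(counts, matrix_path, genes_path, barcodes_path) {
  counts <- validate_counts(counts)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), matrix_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), barcodes_path)
  invisible(matrix_path)
}

# Validate the count-matrix contract used across modules.
validate_counts <- function(counts) {
  assert_that(is.matrix(counts), "counts must be a matrix")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must carry gene and cell dimnames")
  assert_that(!anyDuplicated(rownames(counts)), "duplicate gene ids in counts")
  assert_that(!anyDuplicated(colnames(counts)), "duplicate cell barcodes in counts")
  assert_that(all(counts >= 0), "negative counts")
  counts
}

#' Construct a barcoded read set
#'
#' @param reads Data frame with columns `read_id`, `barcode`, `umi`, `cdna`
#'   (optionally `r1_qual`, `r2_qual`, preserved verbatim, never interpreted).
#' @param barcode_len,umi_len Barcode/UMI geometry (defaults: 10x 3' v3.1,
#'   16 + 12 nt).
#' @return Object of class `BarcodedReadSet`.
#' @export
barcoded_read_set <- function(reads, barcode_len = 16L, umi_len = 12L) {
  need <- c("read_id", "barcode", "umi", "cdna")
  assert_that(all(need %in% names(reads)), "reads table missing columns: %s",
              paste(setdiff(need, names(reads)), collapse = ", "))
  assert_that(!anyDuplicated(reads$read_id), "duplicate read ids")
  if (nrow(reads) > 0) {
    assert_that(all(nchar(reads$barcode) == barcode_len),
                "barcode length mismatch (expected %d)", barcode_len)
    assert_that(all(nchar(reads$umi) == umi_len),
                "UMI length mismatch (expected %d)", umi_len)
  }
  structure(list(reads = as.data.frame(reads),
                 barcode_len = as.integer(barcode_len),
                 umi_len = as.integer(umi_len)),
            class = "BarcodedReadSet")
}

#' @export
print.BarcodedReadSet <- function(x, ...) {
  cat(sprintf("BarcodedReadSet: %d read pairs (barcode %d nt + UMI %d nt)\n",
              nrow(x$reads), x$barcode_len, x$umi_len))
  invisible(x)
}

#' Number of read pairs in a barcoded read set
#' @param x A `BarcodedReadSet`.
#' @export
n_reads <- function(x) nrow(x$reads)

#' Read a paired barcoded FASTQ library
#'
#' R1 carries cell barcode + UMI as its prefix; R2 carries the cDNA. Record
#' ids must match pairwise in order (a trailing `/1`, `/2` or comment after
#' whitespace is ignored). Qualities are kept verbatim but never interpreted.
#'
#' @param r1_path,r2_path FASTQ paths (gzip transparent).
#' @param barcode_len,umi_len Barcode/UMI geometry.
#' @return A `BarcodedReadSet`.
#' @export
load_read_pairs <- function(r1_path, r2_path, barcode_len = 16L, umi_len = 12L) {
  # Biostrings warns about dropping its own metadata columns here; benign
  read_fq <- function(p) withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(p),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  r1 <- read_fq(r1_path)
  r2 <- read_fq(r2_path)
  assert_that(length(r1) == length(r2),
              "R1 has %d records but R2 has %d", length(r1), length(r2))
  clean_id <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  id1 <- clean_id(names(r1)); id2 <- clean_id(names(r2))
  bad <- which(id1 != id2)
  assert_that(length(bad) == 0, "read id mismatch at record %d: '%s' vs '%s'",
              if (length(bad)) bad[1] else 0L,
              if (length(bad)) id1[bad[1]] else "", if (length(bad)) id2[bad[1]] else "")
  if (length(r1) == 0) return(barcoded_read_set(
    data.frame(read_id = character(), barcode = character(),
               umi = character(), cdna = character()),
    barcode_len, umi_len))
  s1 <- as.character(r1)
  assert_that(all(nchar(s1) >= barcode_len + umi_len),
              "R1 shorter than barcode+UMI (%d nt)", barcode_len + umi_len)
  reads <- data.frame(
    read_id = id1,
    barcode = substr(s1, 1L, barcode_len),
    umi = substr(s1, barcode_len + 1L, barcode_len + umi_len),
    cdna = as.character(r2),
    r1_qual = as.character(Biostrings::quality(r1)),
    r2_qual = as.character(Biostrings::quality(r2))
  )
  barcoded_read_set(reads, barcode_len, umi_len)
}

#' Write a barcoded read set as a FASTQ pair
#'
#' R1 is reconstructed as barcode + UMI; stored qualities are emitted
#' verbatim when present, otherwise a constant high quality is written.
#'
#' @param reads A `BarcodedReadSet`.
#' @param r1_path,r2_path Output FASTQ paths.
#' @export
write_read_pairs <- function(reads, r1_path, r2_path) {
  df <- reads$reads
  r1_seq <- paste0(df$barcode, df$umi)
  q1 <- df$r1_qual %||% strrep("I", nchar(r1_seq))
  q2 <- df$r2_qual %||% strrep("I", nchar(df$cdna))
  if (is.null(df$r1_qual)) q1 <- strrep("I", nchar(r1_seq))
  if (is.null(df$r2_qual)) q2 <- strrep("I", nchar(df$cdna))
  fq <- function(id, seq, qual) as.vector(rbind(paste0("@", id), seq, "+", qual))
  writeLines(fq(df$read_id, r1_seq, q1), r1_path)
  writeLines(fq(df$read_id, df$cdna, q2), r2_path)
  invisible(r1_path)
}
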