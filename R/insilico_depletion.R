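# Simulate depletion at read level (k-mer classification against a depletion
# reference, 100%-efficiency removal, pair-preserving downsampling) and at
# count level (panel zeroing with multinomial re-allocation proportional to
# each cell's relative non-panel abundance).

# Canonical k-mers (lexicographic min of k-mer and its reverse complement)
# of one sequence.
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  pmin(km, revcomp(km))
}

# Canonical k-mer set of a collection of sequences.
kmer_set <- function(seqs, k) {
  unique(unlist(lapply(seqs, canonical_kmers, k = k), use.names = FALSE))
}

#' Classify reads against a categorised depletion reference
#'
#' A read is labelled with the first category (in the order of
#' `names(reference)`) whose reference shares at least `theta` of the
#' read's canonical k-mers (strand-insensitive); otherwise it is labelled
#' `"retained"`. This mimics alignment-based removal with 100% efficiency
#' at desk scale; result-equivalence with a spliced aligner is not claimed,
#' and an externally produced read-to-label table can be passed anywhere a
#' classification is consumed.
#'
#' @param reads A `BarcodedReadSet`.
#' @param reference Named list of category to sequence-set (character
#'   vector); category priority is list order (e.g. gene > interval >
#'   rrna). The combined output of [build_depletion_reference()] can be
#'   split with [split_reference()].
#' @param k K-mer size (default 21).
#' @param theta Containment threshold in `(0, 1]` (default 0.5).
#' @return Object of class `ReadClassification`: list with `labels` (named
#'   character per read, values `targeted_<category>` or `"retained"`),
#'   `k`, `theta`.
#' @export
classify_reads <- function(reads, reference, k = 21L, theta = 0.5) {
  df <- reads$reads
  assert_that(length(reference) > 0 && !is.null(names(reference)),
              "reference must be a named list of category sequence sets")
  if (nrow(df) > 0) {
    assert_that(all(nchar(df$cdna) >= k),
                "k (%d) exceeds the length of at least one read", k)
  }
  sets <- lapply(reference, kmer_set, k = k)
  labels <- rep("retained", nrow(df))
  undecided <- seq_len(nrow(df))
  read_kmers <- lapply(df$cdna, canonical_kmers, k = k)
  for (cat in names(sets)) {
    if (length(undecided) == 0) break
    hit <- vapply(read_kmers[undecided], function(km) {
      mean(km %in% sets[[cat]]) >= theta
    }, logical(1))
    labels[undecided[hit]] <- paste0("targeted_", cat)
    undecided <- undecided[!hit]
  }
  structure(list(labels = setNames(labels, df$read_id),
                 k = as.integer(k), theta = theta),
            class = "ReadClassification")
}

#' Split a combined depletion reference by record category
#'
#' Records produced by [build_depletion_reference()] carry `gene:`,
#' `interval:` and `rrna:` id prefixes; this splits them into the named
#' list [classify_reads()] expects, in gene > interval > rrna priority
#' order.
#'
#' @param reference Sequence set from [build_depletion_reference()].
#' @export
split_reference <- function(reference) {
  pref <- sub(":.*$", "", names(reference))
  out <- lapply(c(gene = "gene", interval = "interval", rrna = "rrna"),
                function(p) reference[pref == p])
  out[vapply(out, length, integer(1)) > 0]
}

#' Remove targeted reads (100% removal efficiency)
#'
#' @param reads A `BarcodedReadSet`.
#' @param classification A `ReadClassification` covering every read.
#' @return The retained reads, unchanged and in original order.
#' @export
deplete_reads <- function(reads, classification) {
  df <- reads$reads
  lab <- classification$labels[df$read_id]
  assert_that(!anyNA(lab), "classification does not cover all reads")
  barcoded_read_set(df[lab == "retained", , drop = FALSE],
                    reads$barcode_len, reads$umi_len)
}

#' Downsample read pairs uniformly without replacement
#'
#' Pairs are kept intact (barcode, UMI and cDNA travel together);
#' reproducible under a fixed seed; input order is preserved.
#'
#' @param reads A `BarcodedReadSet`.
#' @param n Number of pairs to keep.
#' @param seed Integer seed.
#' @return A `BarcodedReadSet` of `n` pairs.
#' @export
downsample_pairs <- function(reads, n, seed = 1L) {
  total <- n_reads(reads)
  assert_that(n <= total, "cannot sample %d pairs from %d", n, total)
  keep <- with_seed(seed, sort(sample.int(total, n)))
  barcoded_read_set(reads$reads[keep, , drop = FALSE],
                    reads$barcode_len, reads$umi_len)
}

#' Count-level in silico depletion with relative-abundance re-allocation
#'
#' For each cell, counts of panel genes are set to zero and a fresh
#' multinomial draw of size `per_cell_depth` (or the cell's original total
#' when `"match"`) is taken over the non-panel genes with probabilities
#' proportional to that cell's original non-panel counts. This models
#' removed molecules being replaced by other molecules of the library
#' according to their relative abundance. Cells left with no non-panel
#' counts are dropped with a warning.
#'
#' @param matrix Gene x cell integer count matrix.
#' @param panel A `TargetPanel` or character vector of panel gene ids.
#' @param per_cell_depth `"match"` (default) to resample each cell to its
#'   original total, or a positive integer depth.
#' @param seed Integer seed.
#' @return List with `matrix` (depleted counts) and `summary`
#'   (a `DepletionSummary`).
#' @export
deplete_counts <- function(matrix, panel, per_cell_depth = "match", seed = 1L) {
  matrix <- validate_counts(matrix)
  pg <- if (inherits(panel, "TargetPanel")) panel_genes(panel) else panel
  missing <- setdiff(pg, rownames(matrix))
  if (length(missing) > 0) {
    warning(sprintf("%d panel gene(s) absent from the count matrix", length(missing)))
  }
  pg <- intersect(pg, rownames(matrix))
  match_depth <- identical(per_cell_depth, "match")
  if (!match_depth) {
    assert_that(is.numeric(per_cell_depth) && per_cell_depth > 0,
                "per_cell_depth must be 'match' or a positive integer")
  }
  is_panel <- rownames(matrix) %in% pg
  nonpanel_tot <- colSums(matrix[!is_panel, , drop = FALSE])
  drop <- nonpanel_tot == 0
  if (any(drop)) {
    warning(sprintf("dropping %d cell(s) with no non-panel counts", sum(drop)))
  }
  keep_cells <- which(!drop)
  out <- matrix(0L, nrow = nrow(matrix), ncol = length(keep_cells),
                dimnames = list(rownames(matrix), colnames(matrix)[keep_cells]))
  with_seed(seed, {
    for (j in seq_along(keep_cells)) {
      cell <- keep_cells[j]
      probs <- matrix[!is_panel, cell]
      depth <- if (match_depth) sum(matrix[, cell]) else as.integer(per_cell_depth)
      out[!is_panel, j] <- as.integer(rmultinom(1, depth, probs))
    }
  })
  before_total <- sum(matrix[, keep_cells])
  before_informative <- sum(nonpanel_tot[keep_cells])
  f <- 1 - before_informative / before_total
  per_cat <- panel_category_fractions(matrix[, keep_cells, drop = FALSE], panel)
  summary <- depletion_summary(
    reads_before = before_total,
    reads_after = before_total - (before_total - before_informative),
    fraction_removed = f,
    category_fractions = per_cat,
    informative_fold_change = sum(out) / before_informative,
    per_cell_depth = if (match_depth) "match" else as.integer(per_cell_depth),
    seed = seed,
    cells_dropped = sum(drop))
  list(matrix = out, summary = summary)
}

# Fraction of total UMIs held by each panel category.
panel_category_fractions <- function(matrix, panel) {
  tot <- sum(matrix)
  if (!inherits(panel, "TargetPanel")) {
    return(c(panel = sum(matrix[intersect(panel, rownames(matrix)), ]) / tot))
  }
  vapply(panel$categories, function(gg) {
    gg <- intersect(gg, rownames(matrix))
    if (length(gg) == 0) return(0)
    sum(matrix[gg, , drop = FALSE]) / tot
  }, numeric(1))
}

depletion_summary <- function(reads_before, reads_after, fraction_removed,
                              category_fractions, informative_fold_change,
                              per_cell_depth, seed = NULL, cells_dropped = 0L) {
  structure(list(reads_before = reads_before, reads_after = reads_after,
                 fraction_removed = fraction_removed,
                 category_fractions = category_fractions,
                 informative_fold_change = informative_fold_change,
                 per_cell_depth = per_cell_depth, seed = seed,
                 cells_dropped = cells_dropped),
            class = "DepletionSummary")
}

#' @export
print.DepletionSummary <- function(x, ...) {
  cat(sprintf("DepletionSummary: %.1f%% removed, informative fold change %.2fx\n",
              100 * x$fraction_removed, x$informative_fold_change))
  if (length(x$category_fractions)) {
    cat("  per category:",
        paste(sprintf("%s=%.1f%%", names(x$category_fractions),
                      100 * x$category_fractions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarise a read-level depletion
#'
#' Category fractions are taken from the classification of the original
#' library; the informative fold change is the depth-normalised ratio of
#' retained-read fractions after vs before, which at matched sequencing
#' depth equals the fold increase of reads available to non-targeted
#' transcripts (expectation `1 / (1 - f)` for removed fraction `f`).
#'
#' @param before,after `BarcodedReadSet`s before and after depletion (after
#'   may also be downsampled).
#' @param classification `ReadClassification` of `before`.
#' @return A `DepletionSummary`.
#' @export
summarize_depletion <- function(before, after, classification) {
  lab <- classification$labels[before$reads$read_id]
  assert_that(!anyNA(lab), "classification does not cover the 'before' reads")
  assert_that(n_reads(after) <= n_reads(before),
              "'after' has more reads than 'before'")
  after_lab <- classification$labels[after$reads$read_id]
  assert_that(!anyNA(after_lab), "'after' contains reads not present before")
  n_before <- n_reads(before)
  cat_tab <- table(lab[lab != "retained"])
  cat_frac <- setNames(as.numeric(cat_tab) / n_before, names(cat_tab))
  f <- sum(cat_frac)
  frac_informative_before <- 1 - f
  frac_informative_after <- mean(after_lab == "retained")
  depletion_summary(
    reads_before = n_before, reads_after = n_reads(after),
    fraction_removed = f, category_fractions = cat_frac,
    informative_fold_change = frac_informative_after / frac_informative_before,
    per_cell_depth = "match")
}
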