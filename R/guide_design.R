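# Enumerate, filter, score and select 20-nt sgRNA protospacers adjacent to
# NGG PAM sites, with a Hamming-distance off-target screen against exonic
# exclusion sequences and greedy density-aware selection.
#
# Guide candidates are carried as a data frame (one row per candidate) with
# columns: target_id, start, strand, protospacer, pam, gc_fraction,
# max_homopolymer, max_dinucleotide_units, on_target_score, offtarget_hits.
# `start` is the 1-based position of the protospacer's first base on the
# plus strand of the target sequence (for minus-strand candidates this is
# the plus-strand start of the 20-nt span; the protospacer column holds the
# reverse complement, i.e. the sequence the guide will base-pair to).

empty_candidates <- function() {
  data.frame(target_id = character(), start = integer(), strand = character(),
             protospacer = character(), pam = character(),
             gc_fraction = numeric(), max_homopolymer = integer(),
             max_dinucleotide_units = integer(),
             on_target_score = numeric(), offtarget_hits = integer())
}

# Longest single-base run in each sequence.
longest_homopolymer <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    if (length(ch) == 0) return(0L)
    max(rle(ch)$lengths)
  }, integer(1))
}

# Longest perfect tandem repeat of any dinucleotide unit, in repeat units.
# Both phases are scanned; a homopolymer of length 2r counts as r units of
# an XX dinucleotide (e.g. AAAA = 2 units of AA).
longest_dinucleotide_run <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    best <- if (n >= 2) 1L else 0L
    for (phase in 0:1) {
      if (n - phase < 2) next
      starts <- seq(1 + phase, n - 1, by = 2)
      units <- substring(s, starts, starts + 1)
      r <- rle(units)
      best <- max(best, r$lengths)
    }
    as.integer(best)
  }, integer(1), USE.NAMES = FALSE)
}

# Scan one strand of one sequence for 20-mers immediately 5' of NGG.
scan_pam_strand <- function(seq) {
  n <- nchar(seq)
  if (n < 23) return(integer(0))
  # GG at positions (p+1, p+2) where p is the PAM start; protospacer needs
  # 20 nt upstream of p, so p >= 21.
  gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1]]
  if (gg[1] == -1) return(integer(0))
  p <- gg - 1L                      # PAM start (N of NGG)
  p[p >= 21L & p + 2L <= n]
}

#' Enumerate candidate protospacers adjacent to NGG PAM sites
#'
#' Scans both strands of each target sequence for 20-mers immediately 5' of
#' an NGG PAM. Minus-strand candidates are reported with the plus-strand
#' coordinates of their protospacer span and the protospacer given as the
#' reverse complement. Candidates containing N are excluded.
#'
#' @param targets A sequence set (named character vector).
#' @return Candidate data frame (see module header for columns), sorted by
#'   target, start, strand.
#' @export
enumerate_protospacers <- function(targets) {
  targets <- as_sequence_set(targets)
  out <- list()
  for (tid in names(targets)) {
    s <- targets[[tid]]
    n <- nchar(s)
    rows <- list()
    p_plus <- scan_pam_strand(s)
    if (length(p_plus)) {
      rows$plus <- data.frame(
        target_id = tid,
        start = p_plus - 20L,
        strand = "+",
        protospacer = substring(s, p_plus - 20L, p_plus - 1L),
        pam = substring(s, p_plus, p_plus + 2L)
      )
    }
    rc <- revcomp(s)
    p_minus <- scan_pam_strand(rc)
    if (length(p_minus)) {
      # position q on the reverse complement maps to plus-strand n - q + 1;
      # the protospacer occupies rc[q-20 .. q-1] = plus strand
      # [n - q + 2 .. n - q + 21].
      rows$minus <- data.frame(
        target_id = tid,
        start = n - p_minus + 2L,
        strand = "-",
        protospacer = substring(rc, p_minus - 20L, p_minus - 1L),
        pam = substring(rc, p_minus, p_minus + 2L)
      )
    }
    out[[tid]] <- do.call(rbind, rows)
  }
  cand <- do.call(rbind, c(out, list(empty_candidates()[, 1:5])))
  rownames(cand) <- NULL
  if (nrow(cand) > 0) {
    cand <- cand[!grepl("N", cand$protospacer, fixed = TRUE), , drop = FALSE]
    cand <- cand[order(cand$target_id, cand$start, cand$strand), , drop = FALSE]
    rownames(cand) <- NULL
  }
  cand$gc_fraction <- if (nrow(cand)) {
    (nchar(gsub("[^GC]", "", cand$protospacer))) / 20
  } else numeric(0)
  cand$max_homopolymer <- longest_homopolymer(cand$protospacer)
  cand$max_dinucleotide_units <- longest_dinucleotide_run(cand$protospacer)
  cand$on_target_score <- rep(NA_real_, nrow(cand))
  cand$offtarget_hits <- rep(NA_integer_, nrow(cand))
  cand
}

#' Filter candidates on sequence composition
#'
#' Retains candidates with GC fraction within `[gc_min, gc_max]`, longest
#' homopolymer run shorter than `max_homopolymer` and longest perfect
#' dinucleotide tandem shorter than `max_dinucleotide_units` repeat units.
#' Defaults follow common IVT guide-pool QC practice.
#'
#' @param candidates Candidate data frame from [enumerate_protospacers()].
#' @param gc_min,gc_max GC-fraction bounds (inclusive).
#' @param max_homopolymer Candidates with a run of this length or longer are
#'   removed (default 4: no AAAA/CCCC/GGGG/TTTT).
#' @param max_dinucleotide_units Candidates with a tandem of this many
#'   dinucleotide units or more are removed (default 4: no ATATATAT).
#' @return Filtered candidate data frame.
#' @export
filter_composition <- function(candidates, gc_min = 0.25, gc_max = 0.75,
                               max_homopolymer = 4L, max_dinucleotide_units = 4L) {
  assert_that(gc_min >= 0 && gc_min < gc_max && gc_max <= 1,
              "invalid GC bounds (need 0 <= gc_min < gc_max <= 1)")
  keep <- candidates$gc_fraction >= gc_min &
    candidates$gc_fraction <= gc_max &
    candidates$max_homopolymer < max_homopolymer &
    candidates$max_dinucleotide_units < max_dinucleotide_units
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count off-target sites of a protospacer in an exclusion sequence set
#'
#' Counts positions (both strands of every exclusion sequence) where the
#' 20-mer aligns with Hamming distance at most `max_mismatches` and, when
#' `require_pam`, an NGG is immediately 3'. Matching is literal (an N in
#' the exclusion sequence matches nothing but N). A candidate with a
#' non-zero count is disqualified from panels.
#'
#' @param protospacer A 20-nt character string (or a one-row candidate data
#'   frame).
#' @param exclusion Sequence set of regions that must not be cut (e.g.
#'   exonic sequence of non-panel protein-coding genes).
#' @param max_mismatches Maximum Hamming distance (default 3).
#' @param require_pam Require NGG immediately 3' of the match (default TRUE).
#' @return Integer hit count.
#' @export
count_offtargets <- function(protospacer, exclusion, max_mismatches = 3L,
                             require_pam = TRUE) {
  if (is.data.frame(protospacer)) protospacer <- protospacer$protospacer
  assert_that(length(protospacer) == 1 && nchar(protospacer) == 20,
              "protospacer must be a single 20-nt string")
  exclusion <- as_sequence_set(exclusion)
  pat <- Biostrings::DNAString(protospacer)
  total <- 0L
  for (s in exclusion) {
    for (subject_chr in c(s, revcomp(s))) {
      subject <- Biostrings::DNAString(subject_chr)
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatches,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0) next
      if (require_pam) {
        e <- Biostrings::end(m)
        n <- nchar(subject_chr)
        ok <- e + 3L <= n &
          substring(subject_chr, e + 2L, e + 2L) == "G" &
          substring(subject_chr, e + 3L, e + 3L) == "G"
        total <- total + sum(ok)
      } else {
        total <- total + length(m)
      }
    }
  }
  total
}

#' Annotate candidates with off-target hit counts
#'
#' @param candidates Candidate data frame.
#' @inheritParams count_offtargets
#' @return Candidates with the `offtarget_hits` column filled.
#' @export
annotate_offtargets <- function(candidates, exclusion, max_mismatches = 3L,
                                require_pam = TRUE) {
  candidates$offtarget_hits <- vapply(
    candidates$protospacer, count_offtargets, integer(1),
    exclusion = exclusion, max_mismatches = max_mismatches,
    require_pam = require_pam, USE.NAMES = FALSE)
  candidates
}

#' Positional-nucleotide weight table of the default on-target scorer
#'
#' A fixed 4 x 20 weight matrix (rows A/C/G/T, columns protospacer positions
#' 1-20, position 20 adjacent to the PAM). Values encode well-established
#' qualitative preferences of SpCas9 activity models (G favoured and T
#' disfavoured at the PAM-proximal end, C disfavoured immediately 5' of the
#' PAM, mild seed-region base preferences). The table is a deterministic,
#' documented stand-in for proprietary scorers such as CRISPick;
#' equivalence with any external scorer is not claimed.
#'
#' @return Numeric 4 x 20 matrix.
#' @export
position_weight_table <- function() {
  w <- matrix(0, nrow = 4, ncol = 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  w["G", 20] <- 0.80; w["C", 20] <- -0.50; w["T", 20] <- -0.60
  w["G", 19] <- 0.30; w["T", 19] <- -0.30
  w["C", 18] <- -0.20; w["G", 18] <- 0.20
  w["A", 17] <- 0.15; w["T", 17] <- -0.25
  w["G", 16] <- 0.25; w["T", 16] <- -0.35
  w["A", 15] <- 0.10
  w["C", 14] <- 0.10; w["T", 14] <- -0.10
  w["A", 13] <- -0.10; w["G", 13] <- 0.15
  w["T", 12] <- -0.20
  w["G", 11] <- 0.10
  w["T", 10] <- -0.15; w["G", 10] <- 0.10
  w["A", 9] <- 0.05
  w["T", 8] <- -0.10
  w["C", 7] <- 0.05
  w["G", 6] <- 0.05; w["T", 6] <- -0.10
  w["A", 5] <- 0.05
  w["C", 4] <- -0.05
  w["T", 3] <- -0.05
  w["G", 2] <- 0.05
  w["A", 1] <- 0.05; w["T", 1] <- -0.05
  w
}

score_schemes <- function() {
  list(
    uniform = function(protospacers) rep(0.5, length(protospacers)),
    position_weight = function(protospacers) {
      w <- position_weight_table()
      x <- vapply(protospacers, function(p) {
        nts <- strsplit(p, "")[[1]]
        sum(w[cbind(match(nts, rownames(w)), seq_len(20))])
      }, numeric(1), USE.NAMES = FALSE)
      1 / (1 + exp(-x))
    }
  )
}

#' Score protospacers for predicted on-target activity
#'
#' Deterministic scoring in `[0, 1]`. The default `"position_weight"`
#' scheme sums a fixed positional-nucleotide weight table over the 20-nt
#' protospacer and maps the sum through a logistic link; the `"uniform"`
#' scheme returns 0.5 for every candidate.
#'
#' @param protospacers Character vector of 20-nt protospacers (or a
#'   candidate data frame, in which case the annotated frame is returned).
#' @param scheme Scoring scheme name.
#' @return Numeric scores (or the candidate data frame with
#'   `on_target_score` filled).
#' @export
score_on_target <- function(protospacers, scheme = "position_weight") {
  schemes <- score_schemes()
  assert_that(scheme %in% names(schemes),
              "unknown scoring scheme '%s' (available: %s)", scheme,
              paste(names(schemes), collapse = ", "))
  if (is.data.frame(protospacers)) {
    protospacers$on_target_score <- schemes[[scheme]](protospacers$protospacer)
    return(protospacers)
  }
  schemes[[scheme]](protospacers)
}

#' Select a maximum-density guide panel with minimum inter-guide spacing
#'
#' Greedy selection per target sequence in descending on-target score (ties
#' broken by ascending coordinate, then lexicographically by protospacer);
#' a candidate is taken only if its start differs by at least `min_spacing`
#' from every already-selected start on that target. Candidates with
#' off-target hits are refused.
#'
#' @param candidates Composition- and off-target-filtered candidate data
#'   frame with scores.
#' @param min_spacing Minimum distance between selected protospacer starts
#'   on the same target (nt).
#' @param max_per_target Cap on guides per target (default unlimited).
#' @return Object of class `GuidePanel` with elements `guides`,
#'   `min_spacing`, `max_per_target`.
#' @export
select_spaced_guides <- function(candidates, min_spacing = 30L,
                                 max_per_target = Inf) {
  if (nrow(candidates) > 0 && any(candidates$offtarget_hits > 0, na.rm = TRUE)) {
    n_bad <- sum(candidates$offtarget_hits > 0, na.rm = TRUE)
    warning(sprintf("dropping %d candidate(s) with off-target hits", n_bad))
    candidates <- candidates[is.na(candidates$offtarget_hits) |
                               candidates$offtarget_hits == 0, , drop = FALSE]
  }
  sel <- list()
  for (tid in unique(candidates$target_id)) {
    cc <- candidates[candidates$target_id == tid, , drop = FALSE]
    score <- ifelse(is.na(cc$on_target_score), 0, cc$on_target_score)
    cc <- cc[order(-score, cc$start, cc$protospacer), , drop = FALSE]
    taken <- integer(0)
    rows <- integer(0)
    for (i in seq_len(nrow(cc))) {
      if (length(rows) >= max_per_target) break
      st <- cc$start[i]
      if (all(abs(st - taken) >= min_spacing)) {
        taken <- c(taken, st)
        rows <- c(rows, i)
      }
    }
    sel[[tid]] <- cc[rows, , drop = FALSE]
  }
  guides <- do.call(rbind, c(sel, list(empty_candidates())))
  rownames(guides) <- NULL
  structure(list(guides = guides, min_spacing = as.integer(min_spacing),
                 max_per_target = max_per_target),
            class = "GuidePanel")
}

#' @export
print.GuidePanel <- function(x, ...) {
  cat(sprintf("GuidePanel: %d guides over %d target(s), min spacing %d nt\n",
              nrow(x$guides), length(unique(x$guides$target_id)), x$min_spacing))
  invisible(x)
}

#' Run the full guide-design funnel
#'
#' Enumerate, composition-filter, off-target-screen, score and select
#' spaced guides for each target sequence.
#'
#' @param targets Sequence set of targets to cut.
#' @param exclusion Optional sequence set that must not be cut (off-target
#'   screen skipped when NULL).
#' @inheritParams filter_composition
#' @inheritParams count_offtargets
#' @inheritParams select_spaced_guides
#' @param scheme On-target scoring scheme.
#' @return A `GuidePanel`.
#' @export
design_guides <- function(targets, exclusion = NULL, gc_min = 0.25,
                          gc_max = 0.75, max_homopolymer = 4L,
                          max_dinucleotide_units = 4L, max_mismatches = 3L,
                          require_pam = TRUE, scheme = "position_weight",
                          min_spacing = 30L, max_per_target = Inf) {
  cand <- enumerate_protospacers(targets)
  cand <- filter_composition(cand, gc_min, gc_max, max_homopolymer,
                             max_dinucleotide_units)
  if (!is.null(exclusion)) {
    cand <- annotate_offtargets(cand, exclusion, max_mismatches, require_pam)
    cand <- cand[cand$offtarget_hits == 0, , drop = FALSE]
  } else {
    cand$offtarget_hits <- rep(0L, nrow(cand))
  }
  cand <- score_on_target(cand, scheme)
  select_spaced_guides(cand, min_spacing, max_per_target)
}
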