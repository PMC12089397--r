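# Brute-force enumeration of protospacer sites, independent of the package
# implementation: scan every 23-mer on both strands for a GG at positions
# 22-23.
brute_enumerate <- function(seq) {
  scan1 <- function(s) {
    n <- nchar(s)
    hits <- data.frame(start = integer(), protospacer = character(),
                       pam = character())
    for (i in seq_len(max(0, n - 22))) {
      win <- substr(s, i, i + 22)
      if (substr(win, 22, 22) == "G" && substr(win, 23, 23) == "G") {
        hits <- rbind(hits, data.frame(start = i,
                                       protospacer = substr(win, 1, 20),
                                       pam = substr(win, 21, 23)))
      }
    }
    hits
  }
  plus <- scan1(seq)
  minus <- scan1(rc_chr(seq))
  n <- nchar(seq)
  if (nrow(minus) > 0) minus$start <- n - (minus$start + 19L) + 1L
  list(plus = plus, minus = minus)
}

test_that("protospacer enumeration finds single and absent PAM sites", {
  one <- c(t1 = paste0(strrep("AT", 10), "AGG"))
  cand <- enumerate_protospacers(one)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pam, "AGG")
  expect_equal(cand$strand, "+")
  expect_equal(cand$start, 1L)
  expect_equal(cand$protospacer, strrep("AT", 10))

  expect_equal(nrow(enumerate_protospacers(c(a = strrep("A", 30)))), 0L)
  # candidates containing N inside the protospacer are excluded
  withN <- one
  substr(withN[["t1"]], 3, 3) <- "N"
  names(withN) <- "t1"
  expect_equal(nrow(enumerate_protospacers(withN)), 0L)
})

test_that("enumeration matches an exhaustive 23-mer scan on random sequence", {
  withr::with_seed(7, {
    s <- rand_seq(300)
    cand <- enumerate_protospacers(c(t = s))
    oracle <- brute_enumerate(s)
    expect_equal(sum(cand$strand == "+"), nrow(oracle$plus))
    expect_equal(sum(cand$strand == "-"), nrow(oracle$minus))
    got_plus <- cand[cand$strand == "+", ]
    expect_setequal(paste(got_plus$start, got_plus$protospacer),
                    paste(oracle$plus$start, oracle$plus$protospacer))
    got_minus <- cand[cand$strand == "-", ]
    expect_setequal(paste(got_minus$start, got_minus$protospacer),
                    paste(oracle$minus$start, oracle$minus$protospacer))
  })
})

test_that("enumeration is strand-symmetric", {
  withr::with_seed(41, {
    for (i in 1:5) {
      s <- rand_seq(200)
      fwd <- enumerate_protospacers(c(t = s))
      rev <- enumerate_protospacers(c(t = rc_chr(s)))
      expect_identical(sort(fwd$protospacer), sort(rev$protospacer))
    }
  })
})

test_that("composition filter applies GC, homopolymer and dinucleotide rules", {
  base <- enumerate_protospacers(c(t = paste0(strrep("AT", 10), "AGG")))
  allG <- base; allG$protospacer <- strrep("G", 20); allG$gc_fraction <- 1
  allG$max_homopolymer <- 20L; allG$max_dinucleotide_units <- 10L
  expect_equal(nrow(filter_composition(allG)), 0L)

  run4 <- base
  run4$protospacer <- paste0("TTTT", strrep("AC", 8))
  run4$gc_fraction <- 8 / 20
  run4$max_homopolymer <- 4L
  run4$max_dinucleotide_units <- 8L
  expect_equal(nrow(filter_composition(run4, max_homopolymer = 4)), 0L)
  expect_error(filter_composition(base, gc_min = 0.8, gc_max = 0.5), "invalid GC")
})

test_that("composition filter matches a per-rule brute-force oracle", {
  withr::with_seed(3, {
    cand <- enumerate_protospacers(setNames(
      vapply(1:8, function(i) rand_seq(250), character(1)),
      paste0("t", 1:8)))
    expect_gt(nrow(cand), 50)
    got <- filter_composition(cand, 0.25, 0.75, 4, 4)
    keep <- vapply(cand$protospacer, function(p) {
      ch <- strsplit(p, "")[[1]]
      gc <- mean(ch %in% c("G", "C"))
      hp <- max(rle(ch)$lengths)
      dn <- 1L
      for (phase in 0:1) {
        units <- substring(p, seq(1 + phase, 19, 2), seq(2 + phase, 20, 2))
        dn <- max(dn, rle(units)$lengths)
      }
      gc >= 0.25 && gc <= 0.75 && hp < 4 && dn < 4
    }, logical(1), USE.NAMES = FALSE)
    expect_identical(got$protospacer, cand$protospacer[keep])
  })
})

# Position-by-position Hamming scan, independent of Biostrings.
brute_offtargets <- function(p, exclusion, max_mm = 3, require_pam = TRUE) {
  total <- 0L
  for (s in exclusion) {
    for (subj in c(s, rc_chr(s))) {
      n <- nchar(subj)
      if (n < 20) next
      starts <- 1:(n - 19)
      windows <- substring(subj, starts, starts + 19)
      mm <- rep(0L, length(windows))
      for (j in 1:20) {
        mm <- mm + (substr(windows, j, j) != substr(p, j, j))
      }
      hit <- mm <= max_mm
      if (require_pam) {
        e <- starts + 19L
        pam_ok <- e + 3L <= n &
          substring(subj, e + 2L, e + 2L) == "G" &
          substring(subj, e + 3L, e + 3L) == "G"
        hit <- hit & pam_ok
      }
      total <- total + sum(hit)
    }
  }
  total
}

test_that("off-target counting handles exact hits and a 4-mismatch miss", {
  withr::with_seed(13, {
    p <- rand_seq(20)
    excl <- c(e1 = paste0(rand_seq(30), p, "AGG", rand_seq(30)))
    expect_gte(count_offtargets(p, excl), 1L)

    p4 <- p
    for (pos in c(2, 7, 12, 18)) {
      old <- substr(p4, pos, pos)
      substr(p4, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    excl4 <- c(e1 = paste0(strrep("A", 25), p4, "AGG", strrep("A", 25)))
    expect_equal(count_offtargets(p, excl4, max_mismatches = 3), 0L)
    expect_gte(count_offtargets(p, excl4, max_mismatches = 4), 1L)
  })
})

test_that("off-target counts equal the brute-force Hamming oracle", {
  withr::with_seed(11, {
    excl <- setNames(vapply(1:5, function(i) rand_seq(1000), character(1)),
                     paste0("e", 1:5))
    protos <- vapply(1:50, function(i) rand_seq(20), character(1))
    for (variant in list(c(3, TRUE), c(3, FALSE), c(2, TRUE))) {
      got <- vapply(protos, count_offtargets, integer(1), exclusion = excl,
                    max_mismatches = variant[1], require_pam = as.logical(variant[2]),
                    USE.NAMES = FALSE)
      want <- vapply(protos, brute_offtargets, numeric(1), exclusion = excl,
                     max_mm = variant[1], require_pam = as.logical(variant[2]),
                     USE.NAMES = FALSE)
      expect_equal(got, as.integer(want))
    }
  })
})

test_that("on-target scoring is deterministic and matches the weight table", {
  withr::with_seed(5, {
    protos <- vapply(1:20, function(i) rand_seq(20), character(1))
    expect_equal(score_on_target(protos, "uniform"), rep(0.5, 20))
    s1 <- score_on_target(protos)
    expect_identical(s1, score_on_target(protos))
    expect_true(all(s1 >= 0 & s1 <= 1))
    expect_error(score_on_target(protos, "nope"), "unknown scoring scheme")

    # independent recomputation of the logistic table sum
    w <- position_weight_table()
    manual <- vapply(protos, function(p) {
      x <- 0
      for (j in 1:20) x <- x + w[substr(p, j, j), j]
      1 / (1 + exp(-x))
    }, numeric(1), USE.NAMES = FALSE)
    expect_equal(s1, manual)
    expect_identical(order(s1), order(manual))
  })
})

test_that("spacing selection is greedy with documented tie-breaks", {
  cand <- data.frame(target_id = "t", start = c(1L, 11L), strand = "+",
                     protospacer = c(strrep("AC", 10), strrep("AG", 10)),
                     pam = "AGG", gc_fraction = 0.5, max_homopolymer = 1L,
                     max_dinucleotide_units = 3L, on_target_score = 0.5,
                     offtarget_hits = 0L)
  panel <- select_spaced_guides(cand, min_spacing = 50)
  expect_equal(nrow(panel$guides), 1L)
  expect_equal(panel$guides$start, 1L)  # coordinate tie-break

  cand3 <- cand[c(1, 1, 1), ]
  cand3$start <- c(1L, 61L, 121L)
  panel3 <- select_spaced_guides(cand3, min_spacing = 50)
  expect_equal(sort(panel3$guides$start), c(1L, 61L, 121L))
})

test_that("greedy spacing is at least half the exhaustive optimum", {
  # exhaustive search over subsets of candidate starts
  optimum <- function(starts, min_spacing) {
    best <- 0L
    n <- length(starts)
    for (mask in 0:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(idx) <= best) next
      ss <- starts[idx]
      if (all(abs(outer(ss, ss, "-"))[lower.tri(diag(length(ss)))] >= min_spacing)) {
        best <- length(idx)
      }
    }
    best
  }
  withr::with_seed(5, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      starts <- sort(sample.int(300, n))
      cand <- data.frame(target_id = "t", start = as.integer(starts),
                         strand = "+", protospacer = strrep("AC", 10),
                         pam = "AGG", gc_fraction = 0.5, max_homopolymer = 1L,
                         max_dinucleotide_units = 3L,
                         on_target_score = 0.5, offtarget_hits = 0L)
      got <- nrow(select_spaced_guides(cand, min_spacing = 60)$guides)
      opt <- optimum(starts, 60)
      expect_gte(got, ceiling(opt / 2))
      # with uniform scores the coordinate-ordered greedy is optimal for
      # interval scheduling on a line
      expect_equal(got, opt)
    }
  })
})

test_that("the design funnel is monotone and panels are off-target free", {
  withr::with_seed(17, {
    targets <- setNames(vapply(1:3, function(i) rand_seq(400), character(1)),
                        paste0("t", 1:3))
    excl <- c(x = rand_seq(2000))
    cand <- enumerate_protospacers(targets)
    comp <- filter_composition(cand)
    comp <- annotate_offtargets(comp, excl)
    clean <- comp[comp$offtarget_hits == 0, ]
    panel <- design_guides(targets, excl)
    expect_gte(nrow(cand), nrow(comp))
    expect_gte(nrow(comp), nrow(clean))
    expect_gte(nrow(clean), nrow(panel$guides))
    expect_true(all(panel$guides$offtarget_hits == 0))
    # spacing invariant holds within every target
    for (tid in unique(panel$guides$target_id)) {
      st <- panel$guides$start[panel$guides$target_id == tid]
      if (length(st) > 1) {
        expect_true(all(abs(outer(st, st, "-"))[lower.tri(diag(length(st)))] >= 30))
      }
    }
  })
})
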