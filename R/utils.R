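# Internal helpers shared across modules.

#' @importFrom stats median rmultinom rnorm runif rlnorm sd var setNames cor
#' @importFrom utils head
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# All stochastic operations in the package take an explicit `seed` argument and
# go through this helper; nothing relies on the global random state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Reverse-complement for plain character vectors of A/C/G/T/N.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_fmt(fmt, ...)
  invisible(TRUE)
}

# Random DNA string(s); uses the current RNG state (callers wrap in with_seed).
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
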