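# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded simulations never perturb surrounding
#' randomness.
#'
#' @param seed Single non-missing number.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA string of length n at the given GC fraction.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T (case-insensitive) sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1L]])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# A base different from every base in `avoid` (used when engineering
# microhomology stop positions).
other_base <- function(avoid) {
  pool <- setdiff(DNA_BASES, avoid)
  if (length(pool) == 0L) stop("no base left to choose from")
  if (length(pool) == 1L) pool else sample(pool, 1L)
}

is_dna_string <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) &&
    !grepl("[^ACGT]", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
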