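#' Construct a switch-region-like reference sequence
#'
#' Switch (S) regions of the immunoglobulin heavy-chain locus are GC-rich
#' tandem arrays of short motifs. This builds a synthetic stand-in with the
#' same two properties: tandem copies of `repeat_unit` interleaved with short
#' random spacers drawn at `gc_bias`. The construction guarantees at least
#' `length / (4 * nchar(repeat_unit))` copies of the motif.
#'
#' @param name Short identifier (e.g. `"Smu"`).
#' @param role `"donor"` or `"acceptor"`.
#' @param length Target sequence length in nt; must be at least 200 so that
#'   junction reads fit inside the reference.
#' @param repeat_unit Short DNA motif used to build the tandem repetitiveness.
#' @param gc_bias GC fraction of the spacer bases, in (0, 1).
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return An object of class `switch_reference`: a list with elements
#'   `name`, `sequence`, `role` and `repeat_unit`.
#' @examples
#' smu <- make_switch_reference("Smu", "donor", 2000, "GAGCT", 0.6, seed = 1)
#' nchar(smu$sequence)
#' @export
make_switch_reference <- function(name, role = c("donor", "acceptor"),
                                  length = 2000, repeat_unit = "GAGCT",
                                  gc_bias = 0.6, seed = 1) {
  role <- match.arg(role)
  if (!is.numeric(length) || length < 200) {
    stop("`length` must be >= 200 nt", call. = FALSE)
  }
  if (!is_dna_string(repeat_unit) || nchar(repeat_unit) < 1) {
    stop("`repeat_unit` must be a non-empty A/C/G/T string", call. = FALSE)
  }
  if (!is.numeric(gc_bias) || gc_bias <= 0 || gc_bias >= 1) {
    stop("`gc_bias` must be strictly between 0 and 1", call. = FALSE)
  }
  length <- as.integer(length)
  u <- nchar(repeat_unit)
  seqn <- with_seed(seed, {
    pieces <- character(0)
    total <- 0L
    while (total < length) {
      spacer <- random_dna(sample.int(u + 1L, 1L) - 1L, gc = gc_bias)
      pieces <- c(pieces, repeat_unit, spacer)
      total <- total + u + nchar(spacer)
    }
    substr(paste(pieces, collapse = ""), 1L, length)
  })
  structure(
    list(name = name, sequence = seqn, role = role, repeat_unit = repeat_unit),
    class = "switch_reference"
  )
}

#' @export
print.switch_reference <- function(x, ...) {
  cat(sprintf("<switch_reference> %s (%s), %d nt, repeat unit %s\n",
              x$name, x$role, nchar(x$sequence), x$repeat_unit))
  invisible(x)
}

#' Extract the plain sequence from a reference
#'
#' Accepts either a [make_switch_reference()] object or a plain DNA string,
#' so downstream functions can take both.
#'
#' @param x A `switch_reference` or an A/C/G/T string.
#' @return The sequence as a character scalar.
#' @export
ref_sequence <- function(x) {
  if (inherits(x, "switch_reference")) x$sequence
  else if (is_dna_string(x)) x
  else stop("expected a switch_reference or an A/C/G/T string", call. = FALSE)
}

ref_name <- function(x, default = "ref") {
  if (inherits(x, "switch_reference")) x$name else default
}

#' Generate a random decoy genome
#'
#' A small multi-contig genome used as the source (and search space) for
#' ectopic sequence capture (ECS) insertions. Contigs are uniform random DNA.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in nt.
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @return Named character vector of contig sequences.
#' @export
make_decoy_genome <- function(n_contigs = 3, contig_length = 5000,
                              gc = 0.45, seed = 1) {
  stopifnot(n_contigs >= 1, contig_length >= 200)
  with_seed(seed, {
    out <- vapply(seq_len(n_contigs), function(i) random_dna(contig_length, gc),
                  character(1))
    names(out) <- paste0("decoy", seq_len(n_contigs))
    out
  })
}

#' Read and write FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that move between files and the named
#' character vectors used throughout this package.
#'
#' @param path File path.
#' @param x Named character vector of DNA sequences.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(x)
  names(ss) <- names(x) %||% paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Build a k-mer index over one or more sequences
#'
#' Exact k-mer positions used for seed-and-extend alignment (junction
#' calling) and ECS lookup. Positions are 1-based.
#'
#' @param seqs Named character vector of sequences (or a single string).
#' @param k K-mer length (default 12).
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(seqs, k = 12) {
  if (inherits(seqs, "switch_reference")) seqs <- ref_sequence(seqs)
  seqs <- vapply(seqs, as.character, character(1))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("contig", seq_along(seqs))
  }
  stopifnot(k >= 4)
  km <- character(0); contig <- integer(0); pos <- integer(0)
  for (ci in seq_along(seqs)) {
    n <- nchar(seqs[[ci]])
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    km <- c(km, substring(seqs[[ci]], starts, starts + k - 1L))
    contig <- c(contig, rep.int(ci, length(starts)))
    pos <- c(pos, starts)
  }
  u <- unique(km)
  grp <- match(km, u)
  groups <- split(seq_along(km), grp)
  structure(
    list(k = as.integer(k), contigs = names(seqs), seqs = seqs,
         kmers = u, groups = groups, contig = contig, pos = pos),
    class = "kmer_index"
  )
}

# Look up all (read position, contig, ref position) seed matches for a read.
# Returns a plain list of parallel vectors (kept off data.frame for speed in
# the per-read hot path).
kmer_hits <- function(index, read, stride = 1L) {
  k <- index$k
  L <- nchar(read)
  empty <- list(read_pos = integer(0), contig = integer(0),
                ref_pos = integer(0))
  if (L < k) return(empty)
  starts <- seq.int(1L, L - k + 1L, by = stride)
  rk <- substring(read, starts, starts + k - 1L)
  g <- match(rk, index$kmers)
  keep <- which(!is.na(g))
  if (length(keep) == 0L) return(empty)
  rows <- index$groups[g[keep]]
  ln <- lengths(rows)
  rows <- unlist(rows, use.names = FALSE)
  list(read_pos = rep.int(starts[keep], ln),
       contig = index$contig[rows],
       ref_pos = index$pos[rows])
}
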