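#' Options controlling junction calling
#'
#' @param min_anchor Minimum number of read bases that must be assigned to
#'   each reference (donor and acceptor) for a call to be accepted (nt).
#' @param min_identity Minimum identity within each anchor.
#' @param seed_k K-mer length used for seeding candidate alignment diagonals.
#' @param seed_stride Evaluate every `seed_stride`-th read k-mer when seeding;
#'   1 uses every k-mer.
#' @param max_diagonals Keep at most this many candidate diagonals per
#'   reference, ranked by seed support.
#' @param match Match reward.
#' @param mismatch Mismatch penalty (applied as a positive number).
#' @param try_reverse_complement Retry the reverse complement of a read whose
#'   forward call is unalignable (cloned PCR products can insert in either
#'   orientation).
#' @param exhaustive `TRUE` enumerates every alignment diagonal instead of
#'   seeding (exact but slow; only sensible for short references), `FALSE`
#'   always seeds, `NA` (default) decides automatically: references shorter
#'   than 200 nt or reads shorter than two seed lengths are handled
#'   exhaustively.
#' @return A list of options for [call_junction()] / [call_cohort()].
#' @export
junction_opts <- function(min_anchor = 20, min_identity = 0.9,
                          seed_k = 12, seed_stride = 3, max_diagonals = 12,
                          match = 1, mismatch = 3,
                          try_reverse_complement = TRUE, exhaustive = NA) {
  stopifnot(min_anchor >= 1, min_identity > 0, min_identity <= 1,
            seed_k >= 4, seed_stride >= 1, max_diagonals >= 1,
            match > 0, mismatch >= 0)
  list(min_anchor = as.integer(min_anchor), min_identity = min_identity,
       seed_k = as.integer(seed_k), seed_stride = as.integer(seed_stride),
       max_diagonals = as.integer(max_diagonals),
       match = match, mismatch = mismatch,
       try_reverse_complement = isTRUE(try_reverse_complement),
       exhaustive = exhaustive)
}

#' Score a single-breakpoint gapless split of a read
#'
#' The read prefix `read[1..b]` is aligned gaplessly to the donor ending at
#' donor position `d_cut`, and the suffix `read[(b+1)..L]` to the acceptor
#' starting at acceptor position `a_cut`. The score is
#' `match * (#matches) - mismatch * (#mismatches)` summed over both
#' alignments. An empty side contributes zero.
#'
#' @param read,donor,acceptor DNA strings (references may also be
#'   `switch_reference` objects).
#' @param d_cut Donor position aligned to read position `b`.
#' @param a_cut Acceptor position aligned to read position `b + 1`.
#' @param b Read breakpoint, `0 <= b <= nchar(read)`.
#' @param match,mismatch Scoring parameters.
#' @return Integer score.
#' @export
score_split <- function(read, donor, acceptor, d_cut, a_cut, b,
                        match = 1, mismatch = 3) {
  donor <- ref_sequence(donor); acceptor <- ref_sequence(acceptor)
  L <- nchar(read)
  if (b < 0 || b > L) stop("`b` must lie in [0, read length]", call. = FALSE)
  rc <- seq_chars(read)
  sc <- 0
  if (b > 0) {
    dstart <- d_cut - b + 1L
    if (dstart < 1 || d_cut > nchar(donor)) {
      stop("donor segment out of reference bounds", call. = FALSE)
    }
    dc <- seq_chars(substr(donor, dstart, d_cut))
    m <- rc[seq_len(b)] == dc
    sc <- sc + match * sum(m) - mismatch * sum(!m)
  }
  if (b < L) {
    aend <- a_cut + (L - b) - 1L
    if (a_cut < 1 || aend > nchar(acceptor)) {
      stop("acceptor segment out of reference bounds", call. = FALSE)
    }
    ac <- seq_chars(substr(acceptor, a_cut, aend))
    m <- rc[(b + 1L):L] == ac
    sc <- sc + match * sum(m) - mismatch * sum(!m)
  }
  sc
}

# Candidate alignment diagonals for one side, from seed support.
# Returns integer diagonals (ref_pos - read_pos), most-supported first.
candidate_diagonals <- function(index, read, opts, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  L <- nchar(read)
  ref_len <- nchar(index$seqs[[1L]])
  hits <- kmer_hits(index, read, stride = opts$seed_stride)
  if (length(hits$read_pos) == 0L) return(integer(0))
  d <- hits$ref_pos - hits$read_pos
  if (side == "donor") {
    d <- d[d >= 0L]                  # read must start inside the donor
  } else {
    d <- d[d <= ref_len - L]         # read must end inside the acceptor
  }
  if (length(d) == 0L) return(integer(0))
  ud <- unique(d)
  cnt <- tabulate(match(d, ud))
  ud[order(-cnt, ud)][seq_len(min(length(ud), opts$max_diagonals))]
}

all_diagonals <- function(ref_len, L, side) {
  if (side == "donor") 0:(ref_len - 1L) else (1L - L):(ref_len - L)
}

# Core split search for one read against one (donor, acceptor) pair.
#
# Objective: choose diagonals (dd = donor_pos - read_pos, da likewise) and
# breakpoints b1 <= b2 so that the donor scores read[1..b1], the acceptor
# scores read[(b2+1)..L], and the gap read[(b1+1)..b2] (the insertion) is
# unscored; maximise the summed match/mismatch score. Every read base is
# scored at most once, so no alternative split can tie a fully matching one
# unless it is itself fully matching.
#
# Microhomology is then annotated on the optimal split: from the breakpoint,
# the donor match is extended forwards and the acceptor match backwards while
# read bases equal the respective reference, and MH = the junction-spanning
# segment matching both references. For a blunt/MH junction all breakpoints
# inside the MH segment are score-equivalent and annotate identically; a call
# is ambiguous only when score-equivalent splits disagree on
# (mh_length, insertion_seq).
call_core <- function(readc, read, donc, accc, dds, das, opts) {
  L <- length(readc)
  don_len <- length(donc); acc_len <- length(accc)
  mt <- opts$match; mm <- opts$mismatch
  if (length(dds) == 0L || length(das) == 0L) return(NULL)

  # Per-diagonal prefix scores (donor side): Pfull[b + 1] = score of
  # read[1..b] on diagonal dd, -Inf where the donor cannot cover the prefix.
  dinfo <- lapply(dds, function(dd) {
    bmax <- min(L, don_len - dd)
    if (bmax < 1L) return(NULL)
    mD <- readc[1:bmax] == donc[(1:bmax) + dd]
    P <- c(0, cumsum((mt + mm) * mD - mm))
    Pfull <- c(P, rep(-Inf, L - bmax))
    list(dd = dd, bmax = bmax, Pfull = Pfull, cmP = cummax(Pfull))
  })
  dinfo <- Filter(Negate(is.null), dinfo)
  # Per-diagonal suffix scores (acceptor side): Sfull[b + 1] = score of
  # read[(b+1)..L] on diagonal da, -Inf where the suffix is not covered.
  ainfo <- lapply(das, function(da) {
    bmin <- max(0L, -da)
    if (bmin >= L) return(NULL)
    iA <- (bmin + 1L):L
    mA <- readc[iA] == accc[iA + da]
    S <- c(rev(cumsum(rev((mt + mm) * mA - mm))), 0)
    Sfull <- c(rep(-Inf, bmin), S)
    list(da = da, bmin = bmin, Sfull = Sfull)
  })
  ainfo <- Filter(Negate(is.null), ainfo)
  if (length(dinfo) == 0L || length(ainfo) == 0L) return(NULL)

  # Pass 1: best score per diagonal pair (b1 folded in through cummax).
  nd <- length(dinfo); na <- length(ainfo)
  pairmax <- matrix(-Inf, nd, na)
  for (i in seq_len(nd)) {
    cmP <- dinfo[[i]]$cmP
    for (j in seq_len(na)) {
      pairmax[i, j] <- max(cmP + ainfo[[j]]$Sfull)
    }
  }
  best <- max(pairmax)
  if (!is.finite(best)) return(NULL)

  # Pass 2: enumerate optimal (b1, b2) only for pairs achieving the optimum,
  # and annotate each with its MH flank extension.
  ann <- list()
  for (ij in which(pairmax == best)) {
    i <- (ij - 1L) %% nd + 1L; j <- (ij - 1L) %/% nd + 1L
    di <- dinfo[[i]]; ai <- ainfo[[j]]
    dd <- di$dd; da <- ai$da
    tot <- di$cmP + ai$Sfull
    b2s <- which(tot == best) - 1L
    if (length(b2s) > 24L) b2s <- b2s[1:24]
    for (b2 in b2s) {
      b1s <- which(di$Pfull[1:(b2 + 1L)] == di$cmP[b2 + 1L]) - 1L
      if (length(b1s) > 8L) b1s <- b1s[1:8]
      for (b1 in b1s) {
        if (b1 < b2) {                       # insertion, MH excluded
          dend_r <- b1; astart_r <- b2 + 1L
          mh <- 0L
          ins <- substr(read, b1 + 1L, b2)
        } else {                             # b1 == b2: extend the MH flank
          h <- 0L
          while (b1 + h + 1L <= di$bmax &&
                 readc[b1 + h + 1L] == donc[b1 + h + 1L + dd]) h <- h + 1L
          g <- 0L
          while (b1 - g >= ai$bmin + 1L &&
                 readc[b1 - g] == accc[b1 - g + da]) g <- g + 1L
          dend_r <- b1 + h; astart_r <- b1 - g + 1L
          mh <- g + h
          ins <- ""
        }
        ann[[length(ann) + 1L]] <- list(
          dd = dd, da = da, dend_r = dend_r, astart_r = astart_r,
          mh = mh, ins = ins)
      }
    }
  }
  key <- vapply(ann, function(a)
    paste(a$dend_r + a$dd, a$astart_r + a$da, a$mh, a$ins, sep = "\r"),
    character(1))
  ann <- ann[!duplicated(key)]
  # Tie-break: larger MH, then shorter insertion, then smallest donor end,
  # then deterministic coordinate order. Survivors of the first three keys
  # that still disagree on the insertion content make the call ambiguous.
  mhv <- vapply(ann, function(a) a$mh, numeric(1))
  insl <- vapply(ann, function(a) nchar(a$ins), numeric(1))
  dendv <- vapply(ann, function(a) a$dend_r + a$dd, numeric(1))
  ord <- order(-mhv, insl, dendv,
               vapply(ann, function(a) a$astart_r + a$da, numeric(1)),
               vapply(ann, function(a) a$dd, numeric(1)),
               vapply(ann, function(a) a$da, numeric(1)))
  ann <- ann[ord]
  first <- ann[[1L]]
  surv <- ann[mhv[ord] == first$mh & insl[ord] == nchar(first$ins) &
                dendv[ord] == first$dend_r + first$dd]
  ambiguous <- any(vapply(surv, function(a) a$ins != first$ins, logical(1)))

  dd <- first$dd; da <- first$da
  dend_r <- first$dend_r; astart_r <- first$astart_r
  # Anchor accounting (MH bases belong to both anchors).
  nD <- dend_r
  matchD <- if (nD >= 1L) sum(readc[1:nD] == donc[(1:nD) + dd]) else 0L
  nA <- L - astart_r + 1L
  matchA <- if (nA >= 1L)
    sum(readc[astart_r:L] == accc[(astart_r:L) + da]) else 0L
  list(status = if (ambiguous) "ambiguous" else "called",
       d_end = dend_r, a_start = astart_r,
       mh_length = first$mh, insertion_seq = first$ins,
       donor_ref_start = 1L + dd, donor_ref_end = dend_r + dd,
       acceptor_ref_start = astart_r + da, acceptor_ref_end = L + da,
       donor_anchor = nD, acceptor_anchor = nA,
       donor_mismatches = nD - matchD, acceptor_mismatches = nA - matchA,
       donor_identity = if (nD > 0) matchD / nD else NA_real_,
       acceptor_identity = if (nA > 0) matchA / nA else NA_real_,
       total_score = as.integer(best))
}

call_fields <- c("read_id", "status", "orientation", "d_end", "a_start",
                 "mh_length", "insertion_seq", "donor_ref_start",
                 "donor_ref_end", "acceptor_ref_start", "acceptor_ref_end",
                 "donor_mismatches", "acceptor_mismatches", "donor_identity",
                 "acceptor_identity", "total_score")

empty_call <- function(read_id, status) {
  list(read_id = read_id, status = status, orientation = NA_character_,
       d_end = NA_integer_, a_start = NA_integer_,
       mh_length = NA_integer_, insertion_seq = NA_character_,
       donor_ref_start = NA_integer_, donor_ref_end = NA_integer_,
       acceptor_ref_start = NA_integer_, acceptor_ref_end = NA_integer_,
       donor_mismatches = NA_integer_, acceptor_mismatches = NA_integer_,
       donor_identity = NA_real_, acceptor_identity = NA_real_,
       total_score = NA_integer_)
}

# Assemble one-call lists into the cohort call table.
calls_to_df <- function(calls) {
  cols <- lapply(call_fields, function(f)
    unlist(lapply(calls, `[[`, f), use.names = FALSE))
  names(cols) <- call_fields
  if (length(calls) == 0L) {
    proto <- empty_call(character(0), character(0))
    cols <- lapply(call_fields, function(f) proto[[f]][0])
    names(cols) <- call_fields
  }
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

call_one <- function(read, read_id, donc, accc, don_idx, acc_idx, opts,
                     orientation = "forward") {
  L <- nchar(read)
  use_exhaustive <- if (is.na(opts$exhaustive)) {
    length(donc) <= 200 || length(accc) <= 200 || L < 2L * opts$seed_k
  } else {
    isTRUE(opts$exhaustive)
  }
  if (use_exhaustive) {
    dds <- all_diagonals(length(donc), L, "donor")
    das <- all_diagonals(length(accc), L, "acceptor")
  } else {
    dds <- candidate_diagonals(don_idx, read, opts, "donor")
    das <- candidate_diagonals(acc_idx, read, opts, "acceptor")
  }
  readc <- seq_chars(read)
  res <- call_core(readc, read, donc, accc, dds, das, opts)
  fail <- is.null(res) ||
    (res$status == "called" &&
       (res$donor_anchor < opts$min_anchor ||
          res$acceptor_anchor < opts$min_anchor ||
          res$donor_identity < opts$min_identity ||
          res$acceptor_identity < opts$min_identity))
  if (fail) {
    if (orientation == "forward" && opts$try_reverse_complement) {
      return(call_one(revcomp(read), read_id, donc, accc,
                      don_idx, acc_idx, opts, orientation = "reverse"))
    }
    return(empty_call(read_id, "unalignable"))
  }
  out <- empty_call(read_id, res$status)
  out$orientation <- orientation
  keep <- setdiff(call_fields, c("read_id", "status", "orientation"))
  out[keep] <- res[keep]
  out
}

#' Call the donor/acceptor breakpoint of one junction read
#'
#' Finds the score-maximal gapless split of the read into a donor-aligned
#' prefix and an acceptor-aligned suffix over candidate diagonals obtained by
#' k-mer seeding, optionally leaving an unaligned (unscored) insertion
#' between the two; every read base is scored at most once. Microhomology
#' (MH) is annotated on the optimal split by extending the donor match
#' forwards and the acceptor match backwards from the breakpoint while read
#' bases match the respective reference; the MH segment is the
#' junction-spanning run matching both references, so `(d_end, a_start,
#' mh_length, insertion_seq)` is well defined whichever equivalent
#' breakpoint inside it the optimiser lands on.
#'
#' Reads are assumed to be in the sense orientation of the recombined allele;
#' the reverse complement is retried when the forward call is unalignable.
#' Coordinates in the result are 1-based inclusive and, for reverse calls,
#' refer to the reverse-complemented read.
#'
#' @param read DNA string (non-ACGT characters score as mismatches).
#' @param donor,acceptor References (`switch_reference` or DNA string).
#' @param opts See [junction_opts()].
#' @param read_id Identifier carried into the result.
#' @return One-row data frame; see [call_cohort()] for the columns.
#' @examples
#' call_junction("AAAATTTT", "AAAACCCC", "GGGGTTTT",
#'               junction_opts(min_anchor = 2))
#' @export
call_junction <- function(read, donor, acceptor, opts = junction_opts(),
                          read_id = "read") {
  don_seq <- ref_sequence(donor); acc_seq <- ref_sequence(acceptor)
  if (nchar(don_seq) < opts$min_anchor || nchar(acc_seq) < opts$min_anchor) {
    stop("references shorter than `min_anchor`", call. = FALSE)
  }
  need_idx <- !(if (is.na(opts$exhaustive)) {
    nchar(don_seq) <= 200 || nchar(acc_seq) <= 200 ||
      nchar(read) < 2L * opts$seed_k
  } else isTRUE(opts$exhaustive))
  don_idx <- if (need_idx) build_kmer_index(don_seq, opts$seed_k) else NULL
  acc_idx <- if (need_idx) build_kmer_index(acc_seq, opts$seed_k) else NULL
  calls_to_df(list(call_one(read, read_id, seq_chars(don_seq),
                            seq_chars(acc_seq), don_idx, acc_idx, opts)))
}

#' Call breakpoints for a whole cohort of junction reads
#'
#' @param reads Named character vector of reads, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param donor,acceptor References (`switch_reference` or DNA string).
#' @param opts See [junction_opts()].
#' @return A data frame with one row per read (input order preserved):
#'   `read_id`, `status` (`called` / `unalignable` / `ambiguous`),
#'   `orientation`, read-coordinate `d_end` and `a_start`, `mh_length`,
#'   `insertion_seq`, reference coordinates of both anchors, per-anchor
#'   mismatch counts and identities, and `total_score`.
#' @export
call_cohort <- function(reads, donor, acceptor, opts = junction_opts()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      !is_dna_string(reads)) {
    reads <- read_fasta(reads)
  }
  if (inherits(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (length(reads) == 0L) {
    warning("empty read set: returning an empty call table")
    return(calls_to_df(list()))
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  don_seq <- ref_sequence(donor); acc_seq <- ref_sequence(acceptor)
  don_idx <- build_kmer_index(don_seq, opts$seed_k)
  acc_idx <- build_kmer_index(acc_seq, opts$seed_k)
  donc <- seq_chars(don_seq); accc <- seq_chars(acc_seq)
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    out[[i]] <- call_one(reads[[i]], names(reads)[i], donc, accc,
                         don_idx, acc_idx, opts)
  }
  res <- calls_to_df(out)
  tab <- table(factor(res$status, levels = c("called", "ambiguous", "unalignable")))
  message(sprintf("call_cohort: %d called, %d ambiguous, %d unalignable",
                  tab[["called"]], tab[["ambiguous"]], tab[["unalignable"]]))
  res
}
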