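#' Classify a junction call into a repair pathway
#'
#' Junctions with at most `mh_cnhej_max` (default 3) nt of microhomology and
#' no insertion are attributed to classical non-homologous end joining
#' (C-NHEJ); junctions with longer microhomology or any nucleotide insertion
#' are attributed to alternative end joining (A-EJ). Insertions longer than
#' `ecs_min_len` nt form their own category (`ins_long`), the size class in
#' which ectopic sequence capture is sought.
#'
#' @param mh_length Microhomology length (nt).
#' @param insertion_seq Insertion sequence (`""` if none).
#' @param mh_cnhej_max Largest microhomology still counted as C-NHEJ.
#' @param ecs_min_len Insertions strictly longer than this are `ins_long`.
#' @return List with `pathway` (`"C-NHEJ"` or `"A-EJ"`) and `category`
#'   (`blunt`, `mh_1_3`, `mh_ge4`, `ins_small`, `ins_long`).
#' @export
classify_junction <- function(mh_length, insertion_seq = "",
                              mh_cnhej_max = 3, ecs_min_len = 30) {
  if (is.na(mh_length) || mh_length < 0) {
    stop("`mh_length` must be a non-negative integer", call. = FALSE)
  }
  ins_len <- if (is.na(insertion_seq)) 0L else nchar(insertion_seq)
  if (mh_length > 0 && ins_len > 0) {
    stop("a junction is MH-joined or insertion-joined, never both",
         call. = FALSE)
  }
  category <- if (ins_len > ecs_min_len) "ins_long"
    else if (ins_len > 0) "ins_small"
    else if (mh_length == 0) "blunt"
    else if (mh_length <= mh_cnhej_max) "mh_1_3"
    else "mh_ge4"
  pathway <- if (mh_length <= mh_cnhej_max && ins_len == 0) "C-NHEJ" else "A-EJ"
  list(pathway = pathway, category = category)
}

#' Search a genome index for the origin of a junction insertion
#'
#' Gapless seed-and-extend lookup of an insertion against a (decoy) genome
#' k-mer index, on both strands. A hit must cover at least
#' `min_coverage` of the insertion at identity at least `min_identity`.
#'
#' @param insertion_seq Insertion sequence.
#' @param genome_index A [build_kmer_index()] over the genome.
#' @param min_len Insertions of at most this length are not searched.
#' @param min_identity,min_coverage Acceptance thresholds.
#' @return `NULL`, or a list `(contig, start, end, strand, identity,
#'   coverage)` for the best hit (highest identity, then coverage; ties
#'   resolved by coordinate order).
#' @export
detect_ecs <- function(insertion_seq, genome_index, min_len = 30,
                       min_identity = 0.9, min_coverage = 0.9) {
  m <- nchar(insertion_seq)
  if (is.na(insertion_seq) || m <= min_len) return(NULL)
  best <- NULL
  for (strand in c("+", "-")) {
    qry <- if (strand == "+") insertion_seq else revcomp(insertion_seq)
    qc <- seq_chars(qry)
    hits <- kmer_hits(genome_index, qry)
    if (length(hits$read_pos) == 0L) next
    diag <- hits$ref_pos - hits$read_pos
    keep <- !duplicated(paste(hits$contig, diag))
    uu <- data.frame(contig = hits$contig[keep], diag = diag[keep])
    uu <- uu[order(uu$contig, uu$diag), , drop = FALSE]
    for (r in seq_len(nrow(uu))) {
      ci <- uu$contig[r]; dg <- uu$diag[r]
      cc <- seq_chars(genome_index$seqs[[ci]])
      clen <- length(cc)
      i1 <- max(1L, 1L - dg); i2 <- min(m, clen - dg)
      if (i2 < i1) next
      cov_len <- i2 - i1 + 1L
      if (cov_len < min_coverage * m) next
      ident <- mean(qc[i1:i2] == cc[(i1:i2) + dg])
      if (ident < min_identity) next
      cand <- list(contig = genome_index$contigs[ci],
                   start = i1 + dg, end = i2 + dg, strand = strand,
                   identity = ident, coverage = cov_len / m)
      if (is.null(best) || cand$identity > best$identity ||
          (cand$identity == best$identity && cand$coverage > best$coverage)) {
        best <- cand
      }
    }
  }
  best
}

#' Classify every called junction in a cohort
#'
#' Applies [classify_junction()] to each row of a call table and, when a
#' genome index is supplied, searches long insertions for their ectopic
#' origin with [detect_ecs()]. Without a genome, the ECS flag falls back to
#' the length-only criterion (`insertion > ecs_min_len`). Rows whose status
#' is not `called` are excluded and reported in the `"excluded"` attribute
#' (never silently dropped).
#'
#' @param calls Data frame from [call_cohort()] (typically after
#'   [unique_junctions()]).
#' @param genome_index Optional [build_kmer_index()] over a genome.
#' @param mh_cnhej_max,ecs_min_len See [classify_junction()].
#' @param min_identity,min_coverage See [detect_ecs()].
#' @return Data frame: `read_id`, `pathway`, `category`, `mh_length`,
#'   `insertion_len`, `ecs`, `ecs_contig`, `ecs_start`, `ecs_end`,
#'   `ecs_strand`, `ecs_identity`; attribute `excluded` holds the
#'   non-called rows' `read_id` and `status`.
#' @export
classify_cohort <- function(calls, genome_index = NULL,
                            mh_cnhej_max = 3, ecs_min_len = 30,
                            min_identity = 0.9, min_coverage = 0.9) {
  keep <- calls$status == "called"
  excluded <- calls[!keep, c("read_id", "status")]
  cc <- calls[keep, , drop = FALSE]
  n <- nrow(cc)
  out <- data.frame(
    read_id = cc$read_id,
    pathway = character(n), category = character(n),
    mh_length = cc$mh_length,
    insertion_len = ifelse(is.na(cc$insertion_seq), 0L, nchar(cc$insertion_seq)),
    ecs = logical(n),
    ecs_contig = NA_character_, ecs_start = NA_integer_,
    ecs_end = NA_integer_, ecs_strand = NA_character_,
    ecs_identity = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    cl <- classify_junction(cc$mh_length[i], cc$insertion_seq[i],
                            mh_cnhej_max, ecs_min_len)
    out$pathway[i] <- cl$pathway
    out$category[i] <- cl$category
    if (out$insertion_len[i] > ecs_min_len) {
      if (is.null(genome_index)) {
        out$ecs[i] <- TRUE                      # length-only fallback
      } else {
        hit <- detect_ecs(cc$insertion_seq[i], genome_index, ecs_min_len,
                          min_identity, min_coverage)
        if (!is.null(hit)) {
          out$ecs[i] <- TRUE
          out$ecs_contig[i] <- hit$contig
          out$ecs_start[i] <- hit$start
          out$ecs_end[i] <- hit$end
          out$ecs_strand[i] <- hit$strand
          out$ecs_identity[i] <- hit$identity
        }
      }
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' Collapse duplicate junctions to unique recombination events
#'
#' Two reads carry the same junction signature when they agree on
#' (donor reference end, acceptor reference start, microhomology length,
#' insertion sequence). Clones of one recombination event that differ only
#' by distal point mutations share a signature and collapse; the first
#' occurrence is kept. Non-called rows are passed through untouched.
#'
#' @param calls Data frame from [call_cohort()].
#' @return Filtered data frame; attributes `n_duplicates` (count removed)
#'   and `duplicate_read_ids`.
#' @export
unique_junctions <- function(calls) {
  called <- calls$status == "called"
  sig <- paste(calls$donor_ref_end, calls$acceptor_ref_start,
               calls$mh_length, calls$insertion_seq, sep = "\r")
  dup <- called & duplicated(ifelse(called, sig, paste0("uncalled\r", calls$read_id)))
  out <- calls[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(dup)
  attr(out, "duplicate_read_ids") <- calls$read_id[dup]
  out
}
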