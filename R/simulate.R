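#' Specification of a synthetic junction cohort
#'
#' Describes a cohort of switch-junction reads with known ground truth. The
#' repair-outcome mixture is given over five categories: `blunt` (direct
#' ligation), `mh_short` (1-3 nt microhomology), `mh_long` (4 nt up to
#' `mh_long_max`), `ins_small` (1-2 nt untemplated insertion) and `ecs`
#' (ectopic sequence capture: a >=31 nt insertion copied from a decoy
#' genome).
#'
#' @param n_junctions Number of distinct junctions to generate.
#' @param mix Named probability vector over the five categories; must sum
#'   to 1 (within 1e-9).
#' @param mh_long_max Largest microhomology length generated for `mh_long`.
#' @param mutation_rate Per-base substitution probability applied within
#'   `mutation_window` nt of the junction (outside a protected exact zone),
#'   emulating AID-induced point mutations near breakpoints.
#' @param mutation_window Half-width of the mutation halo in nt.
#' @param hotspot_wrc If `TRUE`, mutations are biased (2x weight) toward
#'   cytosines in WRC motifs (and G of GYW on the other strand).
#' @param read_length_range Two integers in \[200, 2000\]; junction reads
#'   emulate gel-extracted fragments of roughly 500-1000 nt by default.
#' @param duplication_rate Fraction of reads re-emitted verbatim under new
#'   IDs, to exercise unique-junction filtering.
#' @param ecs_len_range Length range of ECS insertions (nt).
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_junctions,
                        mix = control_mix(),
                        mh_long_max = 10,
                        mutation_rate = 0.01,
                        mutation_window = 50,
                        hotspot_wrc = FALSE,
                        read_length_range = c(500, 1000),
                        duplication_rate = 0,
                        ecs_len_range = c(31, 120),
                        seed = 1) {
  cats <- c("blunt", "mh_short", "mh_long", "ins_small", "ecs")
  if (!is.numeric(n_junctions) || n_junctions < 1) {
    stop("`n_junctions` must be >= 1", call. = FALSE)
  }
  if (is.null(names(mix)) || !all(names(mix) %in% cats)) {
    stop("`mix` must be named with categories among: ",
         paste(cats, collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(numeric(length(cats)), cats)
  full[names(mix)] <- mix
  if (any(full < 0) || abs(sum(full) - 1) > 1e-9) {
    stop("`mix` probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  rr <- as.integer(read_length_range)
  if (length(rr) != 2L || rr[1] > rr[2] || rr[1] < 200L || rr[2] > 2000L) {
    stop("`read_length_range` must lie within [200, 2000]", call. = FALSE)
  }
  stopifnot(mh_long_max >= 4, mutation_rate >= 0, mutation_rate < 1,
            mutation_window >= 0, duplication_rate >= 0, duplication_rate < 1,
            ecs_len_range[1] >= 31, ecs_len_range[1] <= ecs_len_range[2])
  structure(
    list(n_junctions = as.integer(n_junctions), mix = full,
         mh_long_max = as.integer(mh_long_max),
         mutation_rate = mutation_rate,
         mutation_window = as.integer(mutation_window),
         hotspot_wrc = isTRUE(hotspot_wrc),
         read_length_range = rr,
         duplication_rate = duplication_rate,
         ecs_len_range = as.integer(ecs_len_range),
         seed = seed),
    class = "cohort_spec"
  )
}

#' Repair-outcome mixtures emulating control and knockdown conditions
#'
#' `control_mix()` is blunt-dominant with mostly short microhomology
#' (C-NHEJ share 0.88), as in unperturbed B cells; `knockdown_mix()` shifts
#' 25 percentage points of the C-NHEJ share toward long microhomology and
#' insertions (C-NHEJ share 0.63), the signature of impaired classical end
#' joining.
#'
#' @return Named probability vector usable as the `mix` of [cohort_spec()].
#' @export
control_mix <- function() {
  c(blunt = 0.55, mh_short = 0.33, mh_long = 0.08, ins_small = 0.03,
    ecs = 0.01)
}

#' @rdname control_mix
#' @export
knockdown_mix <- function() {
  c(blunt = 0.32, mh_short = 0.31, mh_long = 0.24, ins_small = 0.08,
    ecs = 0.05)
}

#' Concatenate a junction read from explicit breakpoints
#'
#' `read = donor[donor_start..donor_break] + insertion +
#' acceptor[acceptor_break..acceptor_end]`. This is the low-level read
#' constructor used by the simulator; exposed for building toy cases.
#'
#' @param donor,acceptor DNA strings or `switch_reference` objects.
#' @param donor_break 1-based position of the last donor base used.
#' @param acceptor_break 1-based position of the first acceptor base used.
#' @param insertion Optional insertion sequence.
#' @param donor_start,acceptor_end Extent of the flanking segments.
#' @return DNA string.
#' @examples
#' build_junction_read("AAAACCCC", 4, "GGGGTTTT", 5)  # "AAAATTTT"
#' @export
build_junction_read <- function(donor, donor_break, acceptor, acceptor_break,
                                insertion = "", donor_start = 1,
                                acceptor_end = NULL) {
  donor <- ref_sequence(donor); acceptor <- ref_sequence(acceptor)
  if (is.null(acceptor_end)) acceptor_end <- nchar(acceptor)
  stopifnot(donor_start >= 1, donor_break <= nchar(donor),
            donor_start <= donor_break,
            acceptor_break >= 1, acceptor_end <= nchar(acceptor),
            acceptor_break <= acceptor_end)
  paste0(substr(donor, donor_start, donor_break), insertion,
         substr(acceptor, acceptor_break, acceptor_end))
}

# ---- internal engineering of exact junction truths -------------------------

# Maximal shared flank: largest f with donor[d_end-f+1..d_end] ==
# acceptor[a_start-f..a_start-1].
left_flank <- function(donc, accc, d_end, a_start, cap = Inf) {
  f <- 0L
  while (f < cap && d_end - f >= 1L && a_start - 1L - f >= 1L &&
         donc[d_end - f] == accc[a_start - 1L - f]) {
    f <- f + 1L
  }
  f
}

# Rightward both-match extension past the breakpoint.
right_ext <- function(donc, accc, d_end, a_start, cap = Inf) {
  g <- 0L
  while (g < cap && d_end + 1L + g <= length(donc) &&
         a_start + g <= length(accc) &&
         donc[d_end + 1L + g] == accc[a_start + g]) {
    g <- g + 1L
  }
  g
}

# TRUE when no non-empty prefix of `ins` scores net >= 0 against the
# reference continuation `flank` (gapless, match +1 / mismatch -3). Such a
# prefix would make the planted insertion boundary ambiguous to any
# score-maximal parser.
no_absorb <- function(ins_chars, flank_chars, match = 1, mismatch = 3) {
  m <- length(ins_chars)
  if (m == 0L) return(TRUE)
  fl <- flank_chars[seq_len(m)]
  hit <- !is.na(fl) & ins_chars == fl
  all(cumsum(ifelse(hit, match, -mismatch)) < 0)
}

#' Simulate a cohort of switch-junction reads with exact ground truth
#'
#' Draws per-junction repair outcomes from `spec$mix`, engineers breakpoint
#' pairs on the references so that each planted outcome is the unique
#' score-maximal parse (exact microhomology flank, mismatching stop bases,
#' insertion boundaries that cannot be absorbed into either anchor), builds
#' the reads, applies AID-like point mutations in a halo around the junction
#' (sparing a protected exact zone), and optionally re-emits duplicate reads.
#'
#' Microhomologies of 4 nt and longer are engineered by copying the acceptor
#' flank into the donor reference within disjoint windows; all edits are
#' applied before any read is built, so every read is consistent with the
#' returned (possibly edited) donor. **Use the returned `donor` for
#' downstream alignment.**
#'
#' @param spec A [cohort_spec()].
#' @param donor,acceptor `switch_reference` objects (or DNA strings). The
#'   references must be comfortably longer than the longest read.
#' @param decoy Named character vector of decoy contigs (see
#'   [make_decoy_genome()]); required when `spec$mix["ecs"] > 0`.
#' @return A list with `reads` (named character vector), `truth` (data frame:
#'   `read_id`, `category`, `donor_break`, `acceptor_break`, `mh_length`,
#'   `insertion_seq`, `ecs_contig`, `ecs_start`, `ecs_end`, `ecs_strand`,
#'   `read_length`, `n_mutations`, `mutations`, `duplicate_of`), `donor`
#'   (edited), `acceptor`, `donor_edits` (data frame of reference edits) and
#'   `spec`.
#' @export
simulate_cohort <- function(spec, donor, acceptor, decoy = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  don_seq <- ref_sequence(donor); acc_seq <- ref_sequence(acceptor)
  donc <- seq_chars(don_seq); accc <- seq_chars(acc_seq)
  don_len <- length(donc); acc_len <- length(accc)
  rr <- spec$read_length_range
  dmin <- as.integer(ceiling(0.7 * rr[2]))
  kmax <- spec$mh_long_max
  if (don_len < dmin + kmax + 10L || acc_len < dmin + kmax + 10L) {
    stop("references too short for `read_length_range`; need at least ",
         dmin + kmax + 10L, " nt", call. = FALSE)
  }
  n <- spec$n_junctions
  if (spec$mix[["ecs"]] > 0 && is.null(decoy)) {
    stop("cannot generate 'ecs' junctions without a decoy genome",
         call. = FALSE)
  }

  with_seed(spec$seed, {
    cats <- sample(names(spec$mix), n, replace = TRUE, prob = spec$mix)
    Ls <- sample(rr[1]:rr[2], n, replace = TRUE)
    ks <- integer(n)
    ks[cats == "mh_short"] <- sample(1:3, sum(cats == "mh_short"), TRUE)
    ks[cats == "mh_long"] <- sample(4:kmax, sum(cats == "mh_long"), TRUE)

    d_ends <- integer(n); a_starts <- integer(n)
    inss <- character(n)
    ecs_contig <- rep(NA_character_, n)
    ecs_start <- rep(NA_integer_, n); ecs_end <- rep(NA_integer_, n)
    ecs_strand <- rep(NA_character_, n)
    edits <- list()
    win_used <- logical(don_len)
    pair_keys <- new.env(parent = emptyenv())

    draw_pair <- function() {
      c(sample(dmin:(don_len - 2L), 1L),
        sample((kmax + 2L):(acc_len - dmin), 1L))
    }
    key_free <- function(de, as_) {
      !exists(paste(de, as_), envir = pair_keys, inherits = FALSE)
    }
    claim_key <- function(de, as_) {
      assign(paste(de, as_), TRUE, envir = pair_keys)
    }

    # 1) Long microhomologies first: edit the donor in disjoint windows.
    for (i in which(cats == "mh_long")) {
      k <- ks[i]
      for (try in 1:10000) {
        pr <- draw_pair(); de <- pr[1]; as_ <- pr[2]
        w <- (de - k):(de + 1L)
        if (any(win_used[w]) || !key_free(de, as_)) next
        src <- accc[(as_ - k):(as_ - 1L)]
        tgt <- (de - k + 1L):de
        ch <- which(donc[tgt] != src)
        for (j in ch) {
          edits[[length(edits) + 1L]] <-
            data.frame(pos = tgt[j], from = donc[tgt[j]], to = src[j])
        }
        donc[tgt] <- src
        if (donc[de - k] == accc[as_ - k - 1L]) {
          nb <- other_base(accc[as_ - k - 1L])
          edits[[length(edits) + 1L]] <-
            data.frame(pos = de - k, from = donc[de - k], to = nb)
          donc[de - k] <- nb
        }
        if (donc[de + 1L] == accc[as_]) {
          nb <- other_base(accc[as_])
          edits[[length(edits) + 1L]] <-
            data.frame(pos = de + 1L, from = donc[de + 1L], to = nb)
          donc[de + 1L] <- nb
        }
        win_used[w] <- TRUE
        claim_key(de, as_)
        d_ends[i] <- de; a_starts[i] <- as_
        break
      }
      if (d_ends[i] == 0L) {
        stop("could not engineer an 'mh_long' junction; donor too crowded",
             call. = FALSE)
      }
    }

    # 2) Blunt and short-MH: rejection-sample exact flanks on final refs.
    for (i in which(cats %in% c("blunt", "mh_short"))) {
      k <- ks[i]
      ok <- FALSE
      for (try in 1:20000) {
        pr <- draw_pair(); de <- pr[1]; as_ <- pr[2]
        if (!key_free(de, as_)) next
        if (right_ext(donc, accc, de, as_, cap = 1L) != 0L) next
        if (left_flank(donc, accc, de, as_, cap = k + 1L) != k) next
        claim_key(de, as_)
        d_ends[i] <- de; a_starts[i] <- as_
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("could not generate a '%s' junction with mh=%d", cats[i], k),
             call. = FALSE)
      }
    }

    # 3) Insertions: boundaries must be unabsorbable into either anchor.
    for (i in which(cats %in% c("ins_small", "ecs"))) {
      ok <- FALSE
      for (try in 1:20000) {
        pr <- draw_pair(); de <- pr[1]; as_ <- pr[2]
        if (!key_free(de, as_)) next
        if (cats[i] == "ins_small") {
          m <- sample(1:2, 1L)
          ic <- sample(DNA_BASES, m, replace = TRUE)
        } else {
          lmax <- min(spec$ecs_len_range[2], Ls[i] - 80L)
          if (lmax < spec$ecs_len_range[1]) {
            stop("read_length_range too short for the requested ECS lengths",
                 call. = FALSE)
          }
          m <- sample(spec$ecs_len_range[1]:lmax, 1L)
          ci <- sample(seq_along(decoy), 1L)
          cl <- nchar(decoy[[ci]])
          st <- sample(seq_len(cl - m + 1L), 1L)
          frag <- substr(decoy[[ci]], st, st + m - 1L)
          strand <- sample(c("+", "-"), 1L)
          if (strand == "-") frag <- revcomp(frag)
          ic <- seq_chars(frag)
        }
        dflank <- donc[(de + 1L):min(don_len, de + m)]
        length(dflank) <- m                       # pad with NA out of bounds
        aflank <- rev(accc[max(1L, as_ - m):(as_ - 1L)])
        length(aflank) <- m
        if (!no_absorb(ic, dflank) || !no_absorb(rev(ic), aflank)) next
        claim_key(de, as_)
        d_ends[i] <- de; a_starts[i] <- as_
        inss[i] <- paste(ic, collapse = "")
        if (cats[i] == "ecs") {
          ecs_contig[i] <- names(decoy)[ci]
          ecs_start[i] <- st; ecs_end[i] <- st + m - 1L
          ecs_strand[i] <- strand
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("could not generate a '%s' junction", cats[i]),
             call. = FALSE)
      }
    }

    # 4) Build reads from the final references, then mutate the halo.
    min_seg <- 40L
    reads <- character(n)
    n_mut <- integer(n)
    mut_desc <- character(n)
    for (i in seq_len(n)) {
      L <- Ls[i]; m <- nchar(inss[i]); k <- ks[i]
      p <- as.integer(round(stats::runif(1, 0.35, 0.65) * (L - m)))
      p <- min(max(p, min_seg), L - m - min_seg)
      q <- L - m - p
      s <- d_ends[i] - p + 1L
      e <- a_starts[i] + q - 1L
      rd <- c(donc[s:d_ends[i]],
              if (m > 0L) seq_chars(inss[i]) else character(0),
              accc[a_starts[i]:e])
      if (spec$mutation_rate > 0) {
        jl <- if (m > 0L) p + 1L else p - k + 1L
        jr <- if (m > 0L) p + m else p
        if (k == 0L && m == 0L) { jl <- p; jr <- p + 1L }
        pad <- k + 2L
        prot <- max(1L, jl - pad):min(L, jr + pad)
        halo <- max(1L, jl - spec$mutation_window):min(L, jr + spec$mutation_window)
        candidates <- setdiff(halo, prot)
        if (length(candidates) > 0) {
          nm <- stats::rbinom(1L, length(candidates), spec$mutation_rate)
          if (nm > 0L) {
            wts <- rep(1, length(candidates))
            if (spec$hotspot_wrc) {
              b0 <- rd[candidates]
              bm1 <- rd[pmax(1L, candidates - 1L)]
              bp1 <- rd[pmin(L, candidates + 1L)]
              wrc <- (b0 == "C" & bm1 %in% c("A", "G")) |
                     (b0 == "G" & bp1 %in% c("C", "T"))
              wts[wrc] <- 2
            }
            mp <- sort(sample(candidates, nm, prob = wts))
            old <- rd[mp]
            new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L),
                          character(1))
            rd[mp] <- new
            n_mut[i] <- nm
            mut_desc[i] <- paste(sprintf("%d:%s>%s", mp, old, new),
                                 collapse = "|")
          }
        }
      }
      reads[i] <- paste(rd, collapse = "")
    }

    ids <- sprintf("jx%05d", seq_len(n))
    truth <- data.frame(
      read_id = ids, category = cats,
      donor_break = d_ends, acceptor_break = a_starts,
      mh_length = ks, insertion_seq = inss,
      ecs_contig = ecs_contig, ecs_start = ecs_start, ecs_end = ecs_end,
      ecs_strand = ecs_strand,
      read_length = Ls, n_mutations = n_mut, mutations = mut_desc,
      duplicate_of = NA_character_, stringsAsFactors = FALSE
    )

    if (spec$duplication_rate > 0) {
      nd <- round(spec$duplication_rate * n)
      if (nd > 0) {
        src <- sample(seq_len(n), nd, replace = TRUE)
        dup_ids <- sprintf("dup%05d", seq_len(nd))
        reads <- c(reads, reads[src])
        ids <- c(ids, dup_ids)
        dup_rows <- truth[src, ]
        dup_rows$read_id <- dup_ids
        dup_rows$duplicate_of <- truth$read_id[src]
        truth <- rbind(truth, dup_rows)
        rownames(truth) <- NULL
      }
    }
    names(reads) <- ids

    new_donor <- if (inherits(donor, "switch_reference")) {
      donor$sequence <- paste(donc, collapse = "")
      donor
    } else paste(donc, collapse = "")
    edits_df <- if (length(edits)) do.call(rbind, edits) else
      data.frame(pos = integer(0), from = character(0), to = character(0))
    list(reads = reads, truth = truth, donor = new_donor, acceptor = acceptor,
         donor_edits = edits_df, spec = spec)
  })
}

#' Simulate a single junction of a requested outcome
#'
#' Convenience wrapper around [simulate_cohort()] for one junction.
#'
#' @inheritParams simulate_cohort
#' @param outcome One of `"blunt"`, `"mh_short"`, `"mh_long"`,
#'   `"ins_small"`, `"ecs"`.
#' @param params Optional [cohort_spec()] whose settings (read lengths,
#'   mutation model, ...) are reused; its mix is replaced by the degenerate
#'   one.
#' @param seed Integer seed.
#' @return A list with `read` (single string), `truth` (one-row data frame)
#'   and the possibly edited `donor`.
#' @export
simulate_junction <- function(donor, acceptor, outcome, params = NULL,
                              decoy = NULL, seed = 1) {
  cats <- c("blunt", "mh_short", "mh_long", "ins_small", "ecs")
  if (!outcome %in% cats) {
    stop("unknown outcome category: ", outcome, call. = FALSE)
  }
  mix <- stats::setNames(as.numeric(cats == outcome), cats)
  spec <- if (is.null(params)) cohort_spec(1, mix = mix, seed = seed) else {
    params$mix <- mix; params$n_junctions <- 1L; params$seed <- seed
    params
  }
  sim <- simulate_cohort(spec, donor, acceptor, decoy)
  list(read = unname(sim$reads[1]), truth = sim$truth[1, ],
       donor = sim$donor, acceptor = sim$acceptor)
}
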