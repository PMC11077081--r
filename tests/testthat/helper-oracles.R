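# Independent oracles used by the unit and acceptance tests. These are
# written from the definitions, separately from the package implementation,
# so that agreement is evidence rather than tautology.

# ---- split-alignment oracle -------------------------------------------------
#
# Exhaustive enumeration over every alignment diagonal of both references and
# every breakpoint pair b1 <= b2 (donor scores read[1..b1], acceptor scores
# read[(b2+1)..L], the gap is the insertion and is unscored). Microhomology is
# annotated on optimal splits by flank extension. No seeding, no diagonal
# capping, no candidate capping.

oracle_prefix_scores <- function(rc, refc, dd, match, mismatch) {
  # score of read[1..b] against ref diagonal dd, for b = 0..bmax
  bmax <- min(length(rc), length(refc) - dd)
  if (bmax < 1L) return(NULL)
  hit <- rc[1:bmax] == refc[(1:bmax) + dd]
  c(0, cumsum(ifelse(hit, match, -mismatch)))
}

oracle_suffix_scores <- function(rc, refc, da, match, mismatch) {
  # score of read[(b+1)..L] against ref diagonal da, for b = bmin..L
  L <- length(rc)
  bmin <- max(0L, -da)
  if (bmin >= L) return(NULL)
  iA <- (bmin + 1L):L
  hit <- rc[iA] == refc[iA + da]
  c(rev(cumsum(rev(ifelse(hit, match, -mismatch)))), 0)
}

oracle_annotate <- function(rc, donc, accc, b1, b2, dd, da) {
  L <- length(rc)
  if (b1 < b2) {
    list(dend_r = b1, astart_r = b2 + 1L, mh = 0L,
         ins = paste(rc[(b1 + 1L):b2], collapse = ""))
  } else {
    h <- 0L
    while (b1 + h + 1L <= L && b1 + h + 1L + dd <= length(donc) &&
           rc[b1 + h + 1L] == donc[b1 + h + 1L + dd]) h <- h + 1L
    g <- 0L
    while (b1 - g >= 1L && b1 - g + da >= 1L &&
           rc[b1 - g] == accc[b1 - g + da]) g <- g + 1L
    list(dend_r = b1 + h, astart_r = b1 - g + 1L, mh = g + h, ins = "")
  }
}

oracle_core <- function(read, donor, acceptor, match = 1, mismatch = 3) {
  rc <- strsplit(read, "", fixed = TRUE)[[1L]]
  donc <- strsplit(donor, "", fixed = TRUE)[[1L]]
  accc <- strsplit(acceptor, "", fixed = TRUE)[[1L]]
  L <- length(rc)
  dds <- 0:(length(donc) - 1L)
  das <- (1L - L):(length(accc) - L)
  pre <- lapply(dds, function(dd) oracle_prefix_scores(rc, donc, dd, match, mismatch))
  suf <- lapply(das, function(da) oracle_suffix_scores(rc, accc, da, match, mismatch))

  # Best score over all diagonal pairs and b1 <= b2 (prefix max folds b1 in).
  best <- -Inf
  for (i in seq_along(dds)) {
    P <- pre[[i]]
    if (is.null(P)) next
    cmP <- cummax(P)
    bmaxd <- length(P) - 1L
    for (j in seq_along(das)) {
      S <- suf[[j]]
      if (is.null(S)) next
      bmin <- max(0L, -das[j])
      b2s <- bmin:L
      tot <- cmP[pmin(b2s, bmaxd) + 1L] + S
      m <- max(tot)
      if (m > best) best <- m
    }
  }
  if (!is.finite(best)) return(NULL)
  # Enumerate every optimal (b1, b2, dd, da), without caps.
  opt <- list()
  for (i in seq_along(dds)) {
    P <- pre[[i]]
    if (is.null(P)) next
    cmP <- cummax(P)
    bmaxd <- length(P) - 1L
    for (j in seq_along(das)) {
      S <- suf[[j]]
      if (is.null(S)) next
      bmin <- max(0L, -das[j])
      b2s <- bmin:L
      tot <- cmP[pmin(b2s, bmaxd) + 1L] + S
      for (b2 in b2s[tot == best]) {
        b1cap <- min(b2, bmaxd)
        b1s <- which(P[1:(b1cap + 1L)] == cmP[b1cap + 1L]) - 1L
        for (b1 in b1s) {
          opt[[length(opt) + 1L]] <-
            list(score = best, b1 = b1, b2 = b2, dd = dds[i], da = das[j])
        }
      }
    }
  }
  if (length(opt) == 0L) return(NULL)
  ann <- lapply(opt, function(e) {
    a <- oracle_annotate(rc, donc, accc, e$b1, e$b2, e$dd, e$da)
    a$dd <- e$dd; a$da <- e$da
    a$d_end_ref <- a$dend_r + e$dd
    a$a_start_ref <- a$astart_r + e$da
    a
  })
  key <- vapply(ann, function(a)
    paste(a$d_end_ref, a$a_start_ref, a$mh, a$ins, sep = "|"), character(1))
  ann <- ann[!duplicated(key)]
  # Tie-break mirror of the documented convention: larger MH, then shorter
  # insertion, then smallest donor end; remaining disagreement on the
  # insertion content is ambiguous.
  mhv <- vapply(ann, `[[`, numeric(1), "mh")
  insl <- vapply(ann, function(a) nchar(a$ins), numeric(1))
  dendv <- vapply(ann, `[[`, numeric(1), "d_end_ref")
  ord <- order(-mhv, insl, dendv,
               vapply(ann, `[[`, numeric(1), "a_start_ref"),
               vapply(ann, `[[`, numeric(1), "dd"),
               vapply(ann, `[[`, numeric(1), "da"))
  ann <- ann[ord]
  first <- ann[[1L]]
  surv <- ann[mhv[ord] == first$mh & insl[ord] == nchar(first$ins) &
                dendv[ord] == first$d_end_ref]
  ambiguous <- any(vapply(surv, function(a) a$ins != first$ins, logical(1)))
  nD <- first$dend_r
  nA <- L - first$astart_r + 1L
  idD <- if (nD > 0) mean(rc[1:nD] == donc[(1:nD) + first$dd]) else NA_real_
  idA <- if (nA > 0) mean(rc[first$astart_r:L] == accc[(first$astart_r:L) + first$da]) else NA_real_
  list(status = if (ambiguous) "ambiguous" else "called",
       mh = first$mh, ins = first$ins,
       d_end_ref = first$d_end_ref, a_start_ref = first$a_start_ref,
       anchorD = nD, anchorA = nA, idD = idD, idA = idA)
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Full oracle including the anchor/identity acceptance rule and the
# reverse-complement retry, mirroring the documented calling contract.
oracle_call <- function(read, donor, acceptor, min_anchor = 5,
                        min_identity = 0.9, orientation = "forward") {
  res <- oracle_core(read, donor, acceptor)
  fail <- is.null(res) ||
    (res$status == "called" &&
       (res$anchorD < min_anchor || res$anchorA < min_anchor ||
          res$idD < min_identity || res$idA < min_identity))
  if (fail) {
    if (orientation == "forward") {
      return(oracle_call(oracle_revcomp(read), donor, acceptor,
                         min_anchor, min_identity, orientation = "reverse"))
    }
    return(list(status = "unalignable", mh = NA_integer_, ins = NA_character_))
  }
  res$orientation <- orientation
  res
}

# Random small caller instances: random references, a spliced read with an
# optional insertion and a few point mutations.
random_small_instance <- function() {
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  don_len <- sample(40:60, 1)
  acc_len <- sample(40:60, 1)
  donor <- rand_dna(don_len)
  acceptor <- rand_dna(acc_len)
  p <- sample(15:(don_len - 5), 1)          # donor prefix length
  q <- sample(1:(acc_len - 15), 1)          # first acceptor base used
  ins <- rand_dna(sample(0:6, 1))
  suffix_len <- min(acc_len - q + 1, sample(15:40, 1))
  read <- paste0(substr(donor, 1, p), ins,
                 substr(acceptor, q, q + suffix_len - 1))
  rc <- strsplit(read, "", fixed = TRUE)[[1L]]
  nmut <- sample(0:2, 1)
  if (nmut > 0) {
    at <- sample(seq_along(rc), nmut)
    for (i in at) rc[i] <- sample(setdiff(c("A", "C", "G", "T"), rc[i]), 1)
  }
  list(read = paste(rc, collapse = ""), donor = donor, acceptor = acceptor)
}

# ---- Fisher oracle ----------------------------------------------------------
#
# Hypergeometric point probabilities by the ratio recurrence
#   P(x) / P(x - 1) = ((m - x + 1) (k - x + 1)) / (x (n - k + x)),
# normalised to sum to one; two-tailed p by the point-probability rule.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  w <- numeric(length(xs))
  w[1L] <- 1
  if (length(xs) > 1L) {
    for (i in 2L:length(xs)) {
      x <- xs[i]
      w[i] <- w[i - 1L] * ((m - x + 1) * (k - x + 1)) / (x * (n - k + x))
    }
  }
  p <- w / sum(w)
  pobs <- p[a - lo + 1L]
  sum(p[p <= pobs * (1 + 1e-12)])
}
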