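# Shared fixtures (cheap to build; deterministic).
fix_donor <- make_switch_reference("Sd", "donor", 2000, "GAGCT", 0.6,
                                   seed = 101)
fix_acceptor <- make_switch_reference("Sa", "acceptor", 2000, "TGGGG", 0.55,
                                      seed = 102)
fix_decoy <- make_decoy_genome(n_contigs = 3, contig_length = 5000,
                               gc = 0.45, seed = 103)
fix_decoy_index <- build_kmer_index(fix_decoy)

# Map a classification row back to the generator's category vocabulary.
recovered_category <- function(cl) {
  ifelse(cl$ecs, "ecs",
    ifelse(cl$insertion_len > 30, "ins_long_noecs",
      ifelse(cl$insertion_len > 0, "ins_small",
        ifelse(cl$mh_length == 0, "blunt",
          ifelse(cl$mh_length <= 3, "mh_short", "mh_long")))))
}

# End-to-end: simulate -> call -> collapse -> classify, returning everything.
run_pipeline <- function(spec, donor = fix_donor, acceptor = fix_acceptor,
                         decoy = fix_decoy, opts = junction_opts(),
                         genome_index = NULL) {
  sim <- simulate_cohort(spec, donor, acceptor, decoy)
  calls <- suppressMessages(call_cohort(sim$reads, sim$donor, sim$acceptor,
                                        opts))
  uq <- unique_junctions(calls)
  cls <- classify_cohort(uq, genome_index)
  list(sim = sim, calls = calls, unique = uq, classes = cls)
}

# A DNA string of length n none of whose k-mers occurs in `index` (either
# strand); found by seeded rejection and asserted, so tests may rely on it.
absent_insertion <- function(index, n = 40, seed = 1) {
  k <- index$k
  with_seed(seed, {
    repeat {
      x <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      xs <- c(x, revcomp(x))
      kms <- unlist(lapply(xs, function(s) {
        st <- seq_len(nchar(s) - k + 1L)
        substring(s, st, st + k - 1L)
      }))
      if (!any(kms %in% index$kmers)) return(x)
    }
  })
}
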