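toy_opts <- junction_opts(min_anchor = 2, exhaustive = TRUE)

test_that("score_split scores gapless splits with empty-side convention", {
  don <- ref_sequence(fix_donor)
  acc <- ref_sequence(fix_acceptor)
  read <- paste0(substr(don, 101, 140), substr(acc, 201, 240))
  expect_equal(score_split(read, don, acc, d_cut = 140, a_cut = 201, b = 40),
               80)
  rc <- strsplit(read, "")[[1]]
  rc[10] <- setdiff(c("A", "C", "G", "T"), rc[10])[1]
  mut <- paste(rc, collapse = "")
  expect_equal(score_split(mut, don, acc, d_cut = 140, a_cut = 201, b = 40),
               76)
  # b = 0: empty donor side contributes zero
  suffix <- substr(acc, 201, 240)
  expect_equal(score_split(suffix, don, acc, d_cut = 140, a_cut = 201, b = 0),
               40)
  expect_error(score_split(read, don, acc, 140, 201, b = -1), "\\[0, ")
  expect_error(score_split(read, don, acc, 10, 201, b = 40), "bounds")
})

test_that("toy junctions are called blunt, MH and insertion as constructed", {
  blunt <- call_junction("AAAATTTT", "AAAACCCC", "GGGGTTTT", toy_opts)
  expect_identical(blunt$status, "called")
  expect_equal(blunt$d_end, 4)
  expect_equal(blunt$a_start, 5)
  expect_equal(blunt$mh_length, 0)
  expect_identical(blunt$insertion_seq, "")

  mh <- call_junction("AAAACGCGTTTT", "AAAACGCG", "CGCGTTTT", toy_opts)
  expect_identical(mh$status, "called")
  expect_equal(mh$mh_length, 4)
  expect_identical(mh$insertion_seq, "")

  ins <- call_junction("AAAAGGTTTT", "AAAACCCC", "CCCCTTTT", toy_opts)
  expect_identical(ins$status, "called")
  expect_equal(ins$mh_length, 0)
  expect_identical(ins$insertion_seq, "GG")
})

test_that("references shorter than the anchor requirement are rejected", {
  expect_error(call_junction("AAAATTTT", "AAAACCCC", "GGGGTTTT"),
               "min_anchor")
})

test_that("every called row satisfies the blunt/MH/insertion trichotomy", {
  spec <- cohort_spec(150, mix = knockdown_mix(), mutation_rate = 0.01,
                      read_length_range = c(250, 400), seed = 11)
  sim <- simulate_cohort(spec, fix_donor, fix_acceptor, fix_decoy)
  calls <- suppressMessages(call_cohort(sim$reads, sim$donor, sim$acceptor))
  cc <- calls[calls$status == "called", ]
  expect_gt(nrow(cc), 0)
  blunt <- cc$a_start == cc$d_end + 1 & cc$mh_length == 0 &
    cc$insertion_seq == ""
  mh <- cc$a_start <= cc$d_end &
    cc$mh_length == cc$d_end - cc$a_start + 1 & cc$insertion_seq == ""
  ins <- cc$a_start > cc$d_end + 1 & cc$mh_length == 0 &
    nchar(cc$insertion_seq) == cc$a_start - cc$d_end - 1
  expect_true(all(blunt + mh + ins == 1))
  # insertion content equals the read segment between the anchors
  don <- ref_sequence(sim$donor); acc <- ref_sequence(sim$acceptor)
  for (i in which(ins)) {
    rd <- sim$reads[[cc$read_id[i]]]
    expect_identical(cc$insertion_seq[i],
                     substr(rd, cc$d_end[i] + 1, cc$a_start[i] - 1))
  }
  # MH segments match both references exactly
  for (i in which(mh)) {
    rd <- sim$reads[[cc$read_id[i]]]
    seg <- substr(rd, cc$a_start[i], cc$d_end[i])
    expect_identical(seg, substr(don, cc$donor_ref_end[i] - cc$mh_length[i] + 1,
                                 cc$donor_ref_end[i]))
    expect_identical(seg, substr(acc, cc$acceptor_ref_start[i],
                                 cc$acceptor_ref_start[i] + cc$mh_length[i] - 1))
  }
})

test_that("unalignable reads are flagged, not guessed", {
  set.seed(12)
  junk <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  r <- call_junction(junk, fix_donor, fix_acceptor)
  expect_identical(r$status, "unalignable")
  expect_true(is.na(r$mh_length))
  # a 30-nt read cannot satisfy two 20-nt anchors
  short <- paste0(substr(ref_sequence(fix_donor), 500, 514),
                  substr(ref_sequence(fix_acceptor), 800, 814))
  r2 <- call_junction(short, fix_donor, fix_acceptor)
  expect_identical(r2$status, "unalignable")
})

test_that("reverse-complemented reads are recovered with the same call", {
  sj <- simulate_junction(fix_donor, fix_acceptor, "mh_long",
                          params = cohort_spec(1, mutation_rate = 0,
                                               read_length_range = c(250, 350)),
                          seed = 13)
  fwd <- call_junction(sj$read, sj$donor, sj$acceptor)
  rev <- call_junction(revcomp(sj$read), sj$donor, sj$acceptor)
  expect_identical(fwd$orientation, "forward")
  expect_identical(rev$orientation, "reverse")
  expect_equal(rev$mh_length, fwd$mh_length)
  expect_identical(rev$insertion_seq, fwd$insertion_seq)
  expect_equal(rev$donor_ref_end, fwd$donor_ref_end)
})

test_that("extra exact donor context never changes the junction call", {
  spec <- cohort_spec(20, mix = c(blunt = 0.4, mh_short = 0.3, mh_long = 0.3),
                      mutation_rate = 0, read_length_range = c(250, 350),
                      seed = 14)
  sim <- simulate_cohort(spec, fix_donor, fix_acceptor)
  don <- ref_sequence(sim$donor); acc <- ref_sequence(sim$acceptor)
  for (i in seq_len(10)) {
    tt <- sim$truth[i, ]
    rd <- sim$reads[[tt$read_id]]
    base <- call_junction(rd, don, acc)
    # prepend 25 further exact donor bases
    s <- tt$donor_break - (nchar(rd) - (nchar(rd) -
           regexpr(substr(rd, 1, 30), don, fixed = TRUE) + 1)) # donor start
    s <- as.integer(regexpr(substr(rd, 1, 30), don, fixed = TRUE))
    skip_if(s <= 25)  # defensive; generator places junctions deep inside
    ext <- paste0(substr(don, s - 25, s - 1), rd)
    extended <- call_junction(ext, don, acc)
    expect_identical(extended$status, base$status)
    expect_equal(extended$mh_length, base$mh_length)
    expect_identical(extended$insertion_seq, base$insertion_seq)
  }
})

test_that("cohort calling preserves order, logs status, handles empty input", {
  spec <- cohort_spec(30, mix = control_mix(), mutation_rate = 0,
                      read_length_range = c(250, 350), seed = 15)
  sim <- simulate_cohort(spec, fix_donor, fix_acceptor, fix_decoy)
  expect_message(calls <- call_cohort(sim$reads, sim$donor, sim$acceptor),
                 "called")
  expect_identical(calls$read_id, names(sim$reads))
  expect_true(all(calls$status == "called"))
  # permutation invariance: same multiset of calls
  perm <- sample(length(sim$reads))
  calls2 <- suppressMessages(
    call_cohort(sim$reads[perm], sim$donor, sim$acceptor))
  a <- calls[order(calls$read_id), ]; rownames(a) <- NULL
  b <- calls2[order(calls2$read_id), ]; rownames(b) <- NULL
  expect_identical(a, b)
  expect_warning(empty <- call_cohort(character(0), sim$donor, sim$acceptor),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("calling agrees with the exhaustive oracle on random spot checks", {
  set.seed(16)
  o <- junction_opts(min_anchor = 5, exhaustive = TRUE)
  for (i in 1:40) {
    inst <- random_small_instance()
    cr <- call_junction(inst$read, inst$donor, inst$acceptor, o)
    orr <- oracle_call(inst$read, inst$donor, inst$acceptor, min_anchor = 5)
    expect_identical(cr$status, orr$status)
    if (cr$status == "called") {
      expect_equal(cr$mh_length, orr$mh)
      expect_identical(cr$insertion_seq, orr$ins)
    }
  }
})
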