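test_that("switch references are deterministic, sized, and motif-rich", {
  a <- make_switch_reference("Smu", "donor", 2000, "GAGCT", 0.6, seed = 1)
  b <- make_switch_reference("Smu", "donor", 2000, "GAGCT", 0.6, seed = 1)
  expect_identical(a$sequence, b$sequence)
  expect_equal(nchar(a$sequence), 2000)
  n_motif <- length(gregexpr("GAGCT", a$sequence, fixed = TRUE)[[1]])
  expect_gte(n_motif, 2000 / (4 * 5))
  expect_true(grepl("^[ACGT]+$", a$sequence))
  c2 <- make_switch_reference("Smu", "donor", 2000, "GAGCT", 0.6, seed = 2)
  expect_false(identical(a$sequence, c2$sequence))
})

test_that("switch reference construction validates its parameters", {
  expect_error(make_switch_reference("x", "donor", 100), ">= 200")
  expect_error(make_switch_reference("x", "donor", 500, gc_bias = 0),
               "gc_bias")
  expect_error(make_switch_reference("x", "donor", 500, repeat_unit = ""),
               "repeat_unit")
  expect_error(make_switch_reference("x", "donor", 500, repeat_unit = "GAXCT"),
               "repeat_unit")
})

test_that("junction reads concatenate donor prefix, insertion, acceptor suffix", {
  expect_identical(build_junction_read("AAAACCCC", 4, "GGGGTTTT", 5),
                   "AAAATTTT")
  expect_identical(
    build_junction_read("AAAACCCC", 4, "CCCCTTTT", 5, insertion = "GG"),
    "AAAAGGTTTT")
  expect_error(build_junction_read("AAAA", 5, "TTTT", 1))
})

test_that("degenerate mixtures yield the requested outcome only", {
  spec <- cohort_spec(100, mix = c(blunt = 1), mutation_rate = 0,
                      read_length_range = c(200, 300), seed = 3)
  sim <- simulate_cohort(spec, fix_donor, fix_acceptor)
  expect_length(sim$reads, 100)
  expect_true(all(sim$truth$mh_length == 0))
  expect_true(all(sim$truth$insertion_seq == ""))
  expect_true(all(sim$truth$category == "blunt"))
})

test_that("cohort category counts follow the mixture (4 SD at n = 1000)", {
  mix <- c(blunt = 0.2, mh_short = 0.2, mh_long = 0.2, ins_small = 0.2,
           ecs = 0.2)
  spec <- cohort_spec(1000, mix = mix, mutation_rate = 0,
                      read_length_range = c(300, 500), seed = 4)
  don <- make_switch_reference("Sd", "donor", 12000, "GAGCT", 0.6, seed = 41)
  acc <- make_switch_reference("Sa", "acceptor", 12000, "TGGGG", 0.55,
                               seed = 42)
  sim <- simulate_cohort(spec, don, acc, fix_decoy)
  counts <- table(sim$truth$category)
  sd_bin <- sqrt(1000 * 0.2 * 0.8)
  expect_true(all(abs(counts - 200) <= 4 * sd_bin))
})

test_that("duplication re-emits verbatim reads under new IDs", {
  spec <- cohort_spec(100, mix = c(blunt = 0.6, mh_short = 0.4),
                      mutation_rate = 0, duplication_rate = 0.1,
                      read_length_range = c(200, 300), seed = 5)
  sim <- simulate_cohort(spec, fix_donor, fix_acceptor)
  expect_length(sim$reads, 110)
  expect_length(unique(sim$reads), 100)
  dup <- sim$truth[!is.na(sim$truth$duplicate_of), ]
  expect_equal(nrow(dup), 10)
  for (i in seq_len(nrow(dup))) {
    expect_identical(unname(sim$reads[dup$read_id[i]]),
                     unname(sim$reads[dup$duplicate_of[i]]))
  }
})

test_that("planted microhomology flanks match both references exactly", {
  spec <- cohort_spec(60, mix = c(mh_short = 0.5, mh_long = 0.5),
                      mutation_rate = 0, read_length_range = c(200, 300),
                      seed = 6)
  sim <- simulate_cohort(spec, fix_donor, fix_acceptor)
  don <- ref_sequence(sim$donor)   # edited donor must be used downstream
  acc <- ref_sequence(sim$acceptor)
  for (i in seq_len(nrow(sim$truth))) {
    k <- sim$truth$mh_length[i]
    de <- sim$truth$donor_break[i]
    as_ <- sim$truth$acceptor_break[i]
    expect_identical(substr(don, de - k + 1, de),
                     substr(acc, as_ - k, as_ - 1))
    # the flank is exactly k: one more base does not match
    expect_false(substr(don, de - k, de - k) ==
                   substr(acc, as_ - k - 1, as_ - k - 1))
  }
})

test_that("reads reproduce truth coordinates and mutation records", {
  spec <- cohort_spec(50, mix = control_mix(), mutation_rate = 0.01,
                      read_length_range = c(300, 500), seed = 7)
  sim <- simulate_cohort(spec, fix_donor, fix_acceptor, fix_decoy)
  expect_identical(nchar(sim$reads), setNames(sim$truth$read_length,
                                              sim$truth$read_id))
  n_rec <- ifelse(sim$truth$mutations == "", 0L,
                  lengths(strsplit(sim$truth$mutations, "|", fixed = TRUE)))
  expect_identical(as.integer(sim$truth$n_mutations), as.integer(n_rec))
  spec0 <- cohort_spec(50, mix = control_mix(), mutation_rate = 0,
                       read_length_range = c(300, 500), seed = 7)
  sim0 <- simulate_cohort(spec0, fix_donor, fix_acceptor, fix_decoy)
  expect_true(all(sim0$truth$n_mutations == 0))
})

test_that("cohort simulation is seed-deterministic", {
  spec <- cohort_spec(30, mix = control_mix(), seed = 8,
                      read_length_range = c(200, 300))
  s1 <- simulate_cohort(spec, fix_donor, fix_acceptor, fix_decoy)
  s2 <- simulate_cohort(spec, fix_donor, fix_acceptor, fix_decoy)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("cohort specs validate mixtures, lengths and ECS requirements", {
  expect_error(cohort_spec(10, mix = c(blunt = 0.5)), "sum to 1")
  expect_error(cohort_spec(10, mix = c(nope = 1)), "categories")
  expect_error(cohort_spec(10, read_length_range = c(100, 300)),
               "\\[200, 2000\\]")
  spec <- cohort_spec(5, mix = c(ecs = 1), seed = 1)
  expect_error(simulate_cohort(spec, fix_donor, fix_acceptor, decoy = NULL),
               "ecs")
})

test_that("single-junction simulation honours the requested outcome", {
  sj <- simulate_junction(fix_donor, fix_acceptor, "mh_long", seed = 9)
  expect_gte(sj$truth$mh_length, 4)
  expect_identical(sj$truth$insertion_seq, "")
  sj2 <- simulate_junction(fix_donor, fix_acceptor, "ins_small", seed = 10)
  expect_identical(sj2$truth$mh_length, 0L)
  expect_true(nchar(sj2$truth$insertion_seq) %in% 1:2)
  expect_error(simulate_junction(fix_donor, fix_acceptor, "nope"),
               "outcome")
})

test_that("FASTA round trip preserves names and sequences", {
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp))
  x <- c(r1 = "ACGTACGT", r2 = "GGGCCC")
  write_fasta(x, tmp)
  expect_identical(read_fasta(tmp), x)
})

test_that("qPCR panel generator inverts the resection formula", {
  # f = 1 -> delta Ct 0; f = 0.5 -> log2(1.5) + 1
  expect_equal(as.numeric(delta_ct_for_fraction(1)), 0)
  expect_equal(as.numeric(delta_ct_for_fraction(0.5)), log2(1.5) + 1)
  # noiseless panel: digested - mock equals delta_ct(f) exactly
  spec <- default_resection_panel("control", cq_noise_sd = 0, seed = 2)
  panel <- simulate_qpcr_panel(spec)
  truth <- attr(panel, "truth")
  for (amp in truth$amplicon) {
    mock <- panel$cq[panel$amplicon == amp & panel$digestion == "mock"]
    dig <- panel$cq[panel$amplicon == amp & panel$digestion == "digested"]
    expect_equal(mean(dig) - mean(mock),
                 truth$delta_ct[truth$amplicon == amp], tolerance = 1e-12)
  }
  # cap: tiny fraction would need delta Ct above the ceiling
  dct <- delta_ct_for_fraction(1e-6, ceiling = 15)
  expect_equal(as.numeric(dct), 15)
  expect_true(attr(dct, "capped"))
})
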