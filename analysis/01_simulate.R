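#!/usr/bin/env Rscript

# Simulate the two study-arm junction cohorts (control-like vs
# repair-compromised "knockdown"-like) plus the shared references and decoy
# genome, and write everything under results/.

suppressPackageStartupMessages(library(switchjoin))

dir.create("results", showWarnings = FALSE)

donor <- make_switch_reference("Smu_like", "donor", 8000, "GAGCT", 0.6,
                               seed = 101)
acceptor <- make_switch_reference("Salpha_like", "acceptor", 8000, "TGGGG",
                                  0.55, seed = 102)
decoy <- make_decoy_genome(n_contigs = 3, contig_length = 5000, gc = 0.45,
                           seed = 103)

write_fasta(c(Smu_like = donor$sequence), "results/donor.fa")
write_fasta(c(Salpha_like = acceptor$sequence), "results/acceptor.fa")
write_fasta(decoy, "results/decoy.fa")

specs <- list(
  control = cohort_spec(400, mix = control_mix(), mutation_rate = 0.005,
                        duplication_rate = 0.05,
                        read_length_range = c(250, 450), seed = 201),
  knockdown = cohort_spec(400, mix = knockdown_mix(), mutation_rate = 0.005,
                          duplication_rate = 0.05,
                          read_length_range = c(250, 450), seed = 202)
)

for (cond in names(specs)) {
  sim <- simulate_cohort(specs[[cond]], donor, acceptor, decoy)
  # the donor comes back with the engineered microhomology edits applied;
  # downstream calling must use this version
  write_fasta(c(Smu_like = ref_sequence(sim$donor)),
              sprintf("results/%s_donor_used.fa", cond))
  write_fasta(sim$reads, sprintf("results/%s_reads.fa", cond))
  write.table(sim$truth, sprintf("results/%s_truth.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d reads (%d planted junctions)\n",
              cond, length(sim$reads), specs[[cond]]$n))
}
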