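#!/usr/bin/env Rscript

# Call the donor/acceptor breakpoint, microhomology and insertion for every
# simulated read written by 01_simulate.R.

suppressPackageStartupMessages(library(switchjoin))

acceptor <- read_fasta("results/acceptor.fa")[[1]]

for (cond in c("control", "knockdown")) {
  donor <- read_fasta(sprintf("results/%s_donor_used.fa", cond))[[1]]
  reads <- read_fasta(sprintf("results/%s_reads.fa", cond))
  calls <- call_cohort(reads, donor, acceptor)
  write.table(calls, sprintf("results/%s_calls.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d/%d reads called\n", cond,
              sum(calls$status == "called"), nrow(calls)))
}
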