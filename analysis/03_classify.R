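#!/usr/bin/env Rscript

# Collapse PCR duplicates to unique junctions and classify each into a
# repair pathway (C-NHEJ vs A-EJ), locating ectopic insertions against the
# decoy genome.

suppressPackageStartupMessages(library(switchjoin))

decoy_index <- build_kmer_index(read_fasta("results/decoy.fa"))

for (cond in c("control", "knockdown")) {
  calls <- read.delim(sprintf("results/%s_calls.tsv", cond),
                      na.strings = "NA")
  calls$insertion_seq[is.na(calls$insertion_seq)] <- ""
  uq <- unique_junctions(calls)
  cls <- classify_cohort(uq, decoy_index)
  write.table(cls, sprintf("results/%s_classified.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d unique junctions (%d duplicates removed), %d ECS\n",
              cond, nrow(cls), attr(uq, "n_duplicates"), sum(cls$ecs)))
}
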