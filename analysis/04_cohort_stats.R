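#!/usr/bin/env Rscript

# Summarise both classified cohorts and test whether the knockdown-like arm
# shifts repair away from C-NHEJ, as read out by the microhomology spectrum.

suppressPackageStartupMessages({
  library(switchjoin)
  library(jsonlite)
})

cls <- lapply(c(control = "control", knockdown = "knockdown"), function(cond) {
  read.delim(sprintf("results/%s_classified.tsv", cond), na.strings = "NA")
})

summaries <- lapply(names(cls), function(cond) {
  s <- summarize_cohort(cls[[cond]], condition = cond)
  print(s)
  s
})
names(summaries) <- names(cls)

pathway <- compare_conditions(summaries$control, summaries$knockdown,
                              "pathway")
per_cat <- compare_conditions(summaries$control, summaries$knockdown,
                              "per_category")
ecs <- ecs_size_distribution(cls)

cat(sprintf("pathway contrast: p = %.3g, odds ratio = %.3g\n",
            pathway$p, pathway$odds_ratio))

write.table(per_cat, "results/per_category_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
report <- list(
  summaries = lapply(summaries, function(s) {
    list(condition = s$condition, n_unique = s$n_unique,
         counts = as.list(s$counts),
         partition3 = s$partition3,
         pathway_counts = as.list(s$pathway_counts),
         ecs_sizes = s$ecs_sizes)
  }),
  pathway_contrast = as.list(pathway),
  ecs = list(summary = ecs$summary, sizes = ecs$sizes)
)
write_json(report, "results/cohort_stats.json", auto_unbox = TRUE,
           digits = NA, pretty = TRUE)
cat("wrote results/cohort_stats.json\n")
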