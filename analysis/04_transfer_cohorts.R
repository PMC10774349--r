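#!/usr/bin/env Rscript
# Validation phase: transfer the discovery signature into each validation
# cohort by exact subsequence matching (the cohorts were sequenced with
# longer reads, so a signature ASV counts as present when its sequence
# occurs verbatim inside a validation ASV; counts of all containing ASVs
# are aggregated), then re-evaluate the aggregated features with the
# five-classifier panel. Writes a Yes/No presence table and an AUC table
# per cohort.

suppressMessages(library(refsig))

seed <- 20240
data_dir <- "results/data"
out <- "results/transfer"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

disc <- read_asv_table(
  file.path(data_dir, "discovery_counts.tsv"),
  file.path(data_dir, "discovery_asvs.fasta"),
  file.path(data_dir, "discovery_labels.tsv")
)
selected <- readLines("results/selection/selected_ids.txt")
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"), simplifyVector = TRUE)

for (cohort in c("cohortB", "cohortC")) {
  vt <- read_asv_table(
    file.path(data_dir, sprintf("%s_counts.tsv", cohort)),
    file.path(data_dir, sprintf("%s_asvs.fasta", cohort)),
    file.path(data_dir, sprintf("%s_labels.tsv", cohort))
  )
  mr <- match_signature(disc$sequences[selected], vt)
  cat(sprintf("-- %s --\n", cohort))
  print(mr)
  utils::write.table(match_presence_table(mr, cohort),
    file.path(out, sprintf("presence_%s.tsv", cohort)),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  rep <- crossval_auc(mr$reduced_table, mr$matched_asv_ids,
    n_folds = 10, seed = seed + match(cohort, c("cohortB", "cohortC"))
  )
  print(rep)
  utils::write.table(validation_report_table(rep),
    file.path(out, sprintf("validation_auc_%s.tsv", cohort)),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}
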