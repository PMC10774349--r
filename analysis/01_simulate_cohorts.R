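#!/usr/bin/env Rscript
# Simulate the study system: a discovery cohort (short reads, sibling-style
# case/control design) plus two independent validation cohorts sequenced
# with longer reads whose ASVs contain discovery ASVs as exact
# subsequences. One validation cohort keeps every planted signature ASV,
# the other loses 20% of them — emulating taxa that a second cohort simply
# does not carry.
#
# Writes counts/FASTA/labels per cohort plus the ground truth under
# results/data/.

suppressMessages(library(refsig))

seed <- 20240
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# benchmark scale: 200 samples x 500 ASVs, 15 discriminative ASVs at
# log-fold effect 2 (see the methods vignette for the rationale)
cfg <- synthetic_config(
  n_case = 100L, n_control = 100L, n_asv = 500L, n_informative = 15L,
  effect_size = 2, seed = seed
)

disc <- generate_discovery(cfg)
write_asv_table(
  disc$table,
  file.path(out, "discovery_counts.tsv"),
  file.path(out, "discovery_asvs.fasta"),
  file.path(out, "discovery_labels.tsv")
)

val_full <- generate_validation(cfg, disc, drop_fraction = 0, seed_offset = 1L)
val_drop <- generate_validation(cfg, disc, drop_fraction = 0.2, seed_offset = 2L)
for (pair in list(list("cohortB", val_full), list("cohortC", val_drop))) {
  id <- pair[[1]]
  write_asv_table(
    pair[[2]]$table,
    file.path(out, sprintf("%s_counts.tsv", id)),
    file.path(out, sprintf("%s_asvs.fasta", id)),
    file.path(out, sprintf("%s_labels.tsv", id))
  )
}

truth <- list(
  seed = seed,
  informative_asv_ids = disc$truth$informative_asv_ids,
  effects = as.list(disc$truth$effects),
  cohortB_containment = val_full$truth$containment_map,
  cohortC_containment = val_drop$truth$containment_map,
  cohortC_dropped = val_drop$truth$dropped_asv_ids
)
jsonlite::write_json(truth, file.path(out, "truth.json"), auto_unbox = TRUE)

cat(sprintf(
  "discovery: %d x %d (%d planted); cohortB keeps all signature ASVs, cohortC drops %d\n",
  nrow(disc$table$counts), ncol(disc$table$counts),
  length(disc$truth$informative_asv_ids),
  length(val_drop$truth$dropped_asv_ids)
))
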