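#!/usr/bin/env Rscript
# Differential-abundance summary of the selected signature on the
# discovery cohort: standardized abundances (zero mean, unit variance per
# ASV), group means, abundance direction (increased/decreased in cases)
# and structural-absence flags, plus the heat-map of standardized
# abundances in signature rank order. Also tallies the packaged published
# 26-ASV signature by taxonomic rank for comparison with the simulated
# run's output shape.

suppressMessages(library(refsig))

data_dir <- "results/data"
out <- "results/diffabundance"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

disc <- read_asv_table(
  file.path(data_dir, "discovery_counts.tsv"),
  file.path(data_dir, "discovery_asvs.fasta"),
  file.path(data_dir, "discovery_labels.tsv")
)
selected <- readLines("results/selection/selected_ids.txt")

da <- differential_abundance(disc, selected)
utils::write.table(as.data.frame(da),
  file.path(out, "differential_abundance.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat(sprintf(
  "%d increased in cases, %d decreased, %d structurally absent in one group\n",
  sum(da$direction == "ASD increased"),
  sum(da$direction == "ASD decreased"),
  sum(da$absent_in_case | da$absent_in_control)
))

export_heatmap(disc, selected, file.path(out, "heatmap"))
cat("heat-map written to", file.path(out, "heatmap.png"), "\n")

sig <- read_signature_table(
  system.file("extdata", "asd_signature_table.tsv", package = "refsig")
)
for (rank in c("phylum", "family", "genus")) {
  cat(sprintf("published signature at %s level:\n", rank))
  print(summarize_taxonomy(sig, rank))
}
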