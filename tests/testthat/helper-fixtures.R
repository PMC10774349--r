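# Fixtures are built in code at test time; nothing binary is shipped.

# A 3-sample x 4-ASV toy table with hand-checkable counts.
toy_table <- function() {
  counts <- matrix(
    c(
      5L, 0L, 2L, 7L,
      1L, 3L, 0L, 2L,
      0L, 4L, 6L, 1L
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), c("a1", "a2", "a3", "a4"))
  )
  seqs <- c(
    a1 = strrep("ACGT", 15),
    a2 = paste0(strrep("TTGA", 14), "ACGTAA"),
    a3 = paste0("C", strrep("GATC", 15)),
    a4 = paste0(strrep("AACG", 13), "TTTTTTTTTT")
  )
  labels <- c(s1 = "case", s2 = "control", s3 = "case")
  asv_table(counts, seqs, labels)
}

# Write an asv_table to a temporary trio of files; returns the paths.
write_toy_files <- function(tab, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    fasta = file.path(dir, "asvs.fasta"),
    labels = file.path(dir, "labels.tsv")
  )
  write_asv_table(tab, paths$counts, paths$fasta, paths$labels)
  paths
}

# Independent Mann-Whitney oracle for AUC: explicit concordant-pair count
# with half credit for ties. Deliberately brute force.
mw_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Independent naive substring scan used as the matching oracle: character
# by character, no regex or fixed-string library search.
naive_contains <- function(needle, haystack) {
  ln <- nchar(needle)
  lh <- nchar(haystack)
  if (ln > lh) {
    return(FALSE)
  }
  for (i in seq_len(lh - ln + 1L)) {
    if (substr(haystack, i, i + ln - 1L) == needle) {
      return(TRUE)
    }
  }
  FALSE
}

small_cfg <- function(seed, ...) {
  args <- list(
    n_case = 20L, n_control = 20L, n_asv = 60L, n_informative = 6L,
    effect_size = 2, library_size_mean = 5000L, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

quiet_refs <- function(...) suppressMessages(run_refs(...))

sig_fixture_path <- function() {
  system.file("extdata", "asd_signature_table.tsv", package = "refsig")
}
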