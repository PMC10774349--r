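test_that("count/FASTA/label trio round-trips through files unchanged", {
  tab <- toy_table()
  paths <- write_toy_files(tab)
  back <- read_asv_table(paths$counts, paths$fasta, paths$labels)
  expect_identical(dim(back), c(3L, 4L))
  expect_identical(back$counts, tab$counts)
  expect_identical(back$sequences, tab$sequences)
  expect_identical(back$labels, tab$labels)

  # a larger machine-generated table round-trips field-wise too
  synth <- generate_discovery(small_cfg(1, n_asv = 100L))$table
  paths2 <- write_toy_files(synth)
  back2 <- read_asv_table(paths2$counts, paths2$fasta, paths2$labels)
  expect_identical(back2$counts, synth$counts)
  expect_identical(back2$sequences, synth$sequences)
  expect_identical(back2$labels, synth$labels)
})

test_that("invalid counts, sequences and labels are rejected with context", {
  tab <- toy_table()
  paths <- write_toy_files(tab)
  # corrupt one cell to a negative count
  lines <- readLines(paths$counts)
  lines[2] <- sub("\t5\t", "\t-1\t", lines[2])
  writeLines(lines, paths$counts)
  expect_error(
    read_asv_table(paths$counts, paths$fasta, paths$labels),
    "negative count.*'s1'.*'a1'"
  )

  # missing sequence for one ASV names the ASV
  seqs <- tab$sequences[c("a1", "a2", "a3")]
  expect_error(asv_table(tab$counts, seqs, tab$labels), "a4")
  # short and ambiguous sequences are refused
  expect_error(
    asv_table(tab$counts, replace(tab$sequences, 1, "ACGT"), tab$labels),
    "at least 50"
  )
  expect_error(
    asv_table(
      tab$counts,
      replace(tab$sequences, 2, paste0("N", strrep("ACGT", 13))),
      tab$labels
    ),
    "A/C/G/T"
  )
  # unknown label alias
  expect_error(refsig:::normalize_labels(c("case", "sibling")), "sibling")
})

test_that("label dialects ASD/NT and 1/0 map onto case/control", {
  expect_identical(
    refsig:::normalize_labels(c("ASD", "nt", "1", "0", "Case", "CONTROL")),
    c("case", "control", "case", "control", "case", "control")
  )
})

test_that("the packaged 26-ASV signature table loads and validates", {
  sig <- read_signature_table(sig_fixture_path())
  expect_s3_class(sig, "signature_table")
  expect_identical(nrow(sig), 26L)
  expect_identical(sig$index, 1:26)
  # row 21 is fully unassigned; row 25 is assigned at domain only
  expect_true(all(is.na(unlist(sig[21, refsig:::TAXONOMY_RANKS]))))
  expect_identical(sig$domain[25], "Bacteria")
  expect_true(all(is.na(unlist(sig[25, refsig:::TAXONOMY_RANKS[-1]]))))
  expect_setequal(attr(sig, "cohorts"), c("PRJNA578223", "PRJNA589343"))
  # presence totals match the published counts per validation cohort
  expect_identical(sum(sig$present_PRJNA589343 == "Yes"), 22L)
  expect_identical(sum(sig$present_PRJNA578223 == "Yes"), 20L)
})

test_that("malformed signature tables are rejected", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    "index\tdomain\tphylum\tclass\torder\tfamily\tgenus\tspecies\tdirection",
    empty
  )
  expect_error(read_signature_table(empty), "no records")

  dup <- withr::local_tempfile(fileext = ".tsv")
  df <- utils::read.delim(sig_fixture_path(), colClasses = "character")
  df$index[2] <- "1"
  utils::write.table(df, dup, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_table(dup), "duplicate index")

  baddir <- withr::local_tempfile(fileext = ".tsv")
  df2 <- utils::read.delim(sig_fixture_path(), colClasses = "character")
  df2$direction[1] <- "higher in cases"
  utils::write.table(df2, baddir, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_table(baddir), "unknown direction")
})

test_that("taxonomy summaries conserve the record count at every rank", {
  sig <- read_signature_table(sig_fixture_path())
  for (rank in refsig:::TAXONOMY_RANKS) {
    counts <- summarize_taxonomy(sig, rank)
    expect_identical(sum(counts), 26L)
  }
  one <- sig[1, , drop = FALSE]
  expect_identical(sum(summarize_taxonomy(one, "species")), 1L)
  expect_identical(names(summarize_taxonomy(one, "species")), "unassigned")
})

test_that("signature round-trips through write_signature_table", {
  sig <- read_signature_table(sig_fixture_path())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_table(sig, path)
  back <- read_signature_table(path)
  expect_identical(as.data.frame(back), as.data.frame(sig))
})
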