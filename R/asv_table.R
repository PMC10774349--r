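#' ASV count tables
#'
#' An `asv_table` bundles the three ingredients every stage of the pipeline
#' needs: an integer count matrix (samples in rows, amplicon sequence
#' variants in columns), the representative DNA sequence of each ASV, and a
#' binary case/control label per sample. It is the universal currency passed
#' between feature selection, validation, matching and differential
#' abundance.
#'
#' @param counts integer matrix, samples x ASVs, with row and column names.
#' @param sequences named character vector mapping ASV id to a DNA string
#'   over `A`, `C`, `G`, `T` (at least 50 nt; `U` is converted to `T` on
#'   construction, ambiguity codes are rejected).
#' @param labels named character vector mapping sample id to `"case"` or
#'   `"control"`.
#'
#' @return An object of class `asv_table` with elements `counts`,
#'   `sequences` and `labels`, aligned to the row/column order of `counts`.
#' @export
asv_table <- function(counts, sequences, labels) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  sequences <- toupper(gsub("U", "T", sequences, ignore.case = TRUE))
  obj <- structure(
    list(counts = counts, sequences = sequences, labels = labels),
    class = "asv_table"
  )
  validate_asv_table(obj)
}

#' Validate an ASV table
#'
#' Checks the structural invariants: non-negative integer counts, one
#' sequence of length >= 50 per ASV over the plain DNA alphabet, and one
#' case/control label per sample. Called by every constructor and reader;
#' exposed so externally assembled objects can be checked too.
#'
#' @param x an `asv_table`.
#' @return `x`, invisibly reordered so sequences and labels follow the
#'   count-matrix order.
#' @export
validate_asv_table <- function(x) {
  counts <- x$counts
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have sample row names and ASV column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids")
  bad <- which(is.na(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "negative or missing count at sample '%s', ASV '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  missing_seq <- setdiff(colnames(counts), names(x$sequences))
  if (length(missing_seq) > 0L) {
    stop("missing sequence for ASV: ", paste(missing_seq, collapse = ", "))
  }
  seqs <- x$sequences[colnames(counts)]
  if (any(nchar(seqs) < 50L)) {
    stop(
      "ASV sequences must be at least 50 nt; offending: ",
      paste(colnames(counts)[nchar(seqs) < 50L], collapse = ", ")
    )
  }
  if (any(grepl("[^ACGT]", seqs))) {
    stop(
      "ASV sequences must use only A/C/G/T; offending: ",
      paste(colnames(counts)[grepl("[^ACGT]", seqs)], collapse = ", ")
    )
  }
  missing_lab <- setdiff(rownames(counts), names(x$labels))
  if (length(missing_lab) > 0L) {
    stop("missing label for sample: ", paste(missing_lab, collapse = ", "))
  }
  labs <- x$labels[rownames(counts)]
  if (!all(labs %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  x$sequences <- seqs
  x$labels <- labs
  x
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf(
    "<asv_table> %d samples x %d ASVs (%d case / %d control), read length %d-%d nt\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$labels == "case"), sum(x$labels == "control"),
    min(nchar(x$sequences)), max(nchar(x$sequences))
  ))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

# Map the label dialects seen in practice onto case/control. Table-style
# ASD/NT and 0/1 codings are accepted case-insensitively.
normalize_labels <- function(labels) {
  lab <- tolower(trimws(as.character(labels)))
  out <- ifelse(lab %in% c("case", "asd", "1"), "case",
    ifelse(lab %in% c("control", "nt", "0"), "control", NA_character_)
  )
  if (anyNA(out)) {
    stop(
      "unrecognised label(s): ",
      paste(unique(labels[is.na(out)]), collapse = ", "),
      " (expected case/ASD/1 or control/NT/0)"
    )
  }
  out
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an ASV table from count, FASTA and label files
#'
#' @param counts_path TSV or CSV count table. By default samples are rows
#'   and ASVs are columns, with the sample id in the first column;
#'   `transpose = TRUE` accepts the ASV-per-row dialect.
#' @param fasta_path FASTA file of ASV representative sequences whose ids
#'   match the count-table ASV names.
#' @param labels_path TSV with columns `sample_id` and `label`; labels may
#'   be `case`/`control`, `ASD`/`NT` or `1`/`0` (case-insensitive).
#' @param transpose logical; set when the count file stores ASVs as rows.
#' @param delim field delimiter of the count file; sniffed from the first
#'   line when `NULL`.
#'
#' @return A validated [asv_table()], preserving file order.
#' @export
read_asv_table <- function(counts_path, fasta_path, labels_path,
                           transpose = FALSE, delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(counts_path)
  raw <- utils::read.delim(counts_path,
    sep = delim, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- ids
  if (transpose) mat <- t(mat)
  if (!is.numeric(mat)) stop("count table contains non-numeric entries")
  nonint <- which(mat != floor(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(nonint) > 0L) {
    stop(sprintf(
      "non-integer or negative count at sample '%s', ASV '%s' in %s",
      rownames(mat)[nonint[1, 1]], colnames(mat)[nonint[1, 2]], counts_path
    ))
  }
  seqs_set <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- as.character(seqs_set)
  names(seqs) <- sub("\\s.*$", "", names(seqs_set))
  lab_df <- read_tsv(labels_path)
  if (!all(c("sample_id", "label") %in% names(lab_df))) {
    stop("labels file must have columns 'sample_id' and 'label'")
  }
  labels <- normalize_labels(lab_df$label)
  names(labels) <- as.character(lab_df$sample_id)
  asv_table(mat, seqs, labels)
}

#' Write an ASV table to count, FASTA and label files
#'
#' Inverse of [read_asv_table()]: writing then re-reading reproduces the
#' table field-for-field.
#'
#' @param x an `asv_table`.
#' @param counts_path,fasta_path,labels_path output paths.
#' @return The paths, invisibly.
#' @export
write_asv_table <- function(x, counts_path, fasta_path, labels_path) {
  df <- data.frame(sample_id = rownames(x$counts), x$counts, check.names = FALSE)
  write_tsv(df, counts_path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(x$sequences), fasta_path
  )
  write_tsv(
    data.frame(sample_id = rownames(x$counts), label = unname(x$labels)),
    labels_path
  )
  invisible(c(counts_path, fasta_path, labels_path))
}

# Restrict a table to a subset of ASVs (order taken from `asv_ids`).
subset_asvs <- function(x, asv_ids) {
  missing <- setdiff(asv_ids, colnames(x$counts))
  if (length(missing) > 0L) {
    stop("ASV ids absent from table: ", paste(missing, collapse = ", "))
  }
  asv_table(
    x$counts[, asv_ids, drop = FALSE],
    x$sequences[asv_ids],
    x$labels
  )
}

# 0/1 numeric coding of the labels (case = 1), aligned to the sample order.
label01 <- function(x) {
  as.integer(x$labels[rownames(x$counts)] == "case")
}
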