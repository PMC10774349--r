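TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Read a signature table
#'
#' A signature table is the ordered outcome of feature selection: one row
#' per selected ASV, ranked by importance (`index`), with its seven-rank
#' taxonomy, the direction of its differential abundance in cases versus
#' controls, optional sequence, and a Yes/No presence flag per validation
#' cohort. The packaged fixture `asd_signature_table.tsv` is a
#' transcription of the published 26-ASV autism spectrum disorder
#' signature; its sequence column is empty because the study did not
#' publish the nucleotide sequences.
#'
#' @param path TSV with columns `index`, optional `sequence`, the seven
#'   taxonomy ranks `domain` ... `species` (`NA` for unassigned),
#'   `direction` (`"ASD increased"` or `"ASD decreased"`), and zero or more
#'   `present_<cohort>` Yes/No columns.
#'
#' @return A `signature_table`: a data frame with one row per record, the
#'   taxonomy ranks as character columns (`NA` = unassigned), and
#'   attribute `cohorts` naming the presence columns.
#' @export
#'
#' @examples
#' sig <- read_signature_table(
#'   system.file("extdata", "asd_signature_table.tsv", package = "refsig")
#' )
#' nrow(sig) # 26
#' summarize_taxonomy(sig, "phylum")
read_signature_table <- function(path) {
  df <- read_tsv(path, colClasses = "character", na.strings = character())
  if (nrow(df) == 0L) stop("no records in signature table ", path)
  required <- c("index", TAXONOMY_RANKS, "direction")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("signature table missing column(s): ", paste(missing, collapse = ", "))
  }
  df$index <- as.integer(df$index)
  if (anyNA(df$index)) stop("non-integer index in signature table")
  if (anyDuplicated(df$index)) {
    stop("duplicate index in signature table: ", df$index[duplicated(df$index)][1L])
  }
  if (!identical(sort(df$index), seq_len(nrow(df)))) {
    stop("signature indices must be consecutive 1..N")
  }
  df <- df[order(df$index), , drop = FALSE]
  rownames(df) <- NULL
  for (r in TAXONOMY_RANKS) {
    df[[r]][df[[r]] %in% c("NA", "")] <- NA_character_
  }
  # prefix consistency: once unassigned, all lower ranks unassigned
  na_mat <- is.na(as.matrix(df[TAXONOMY_RANKS]))
  bad <- apply(na_mat, 1L, function(z) any(diff(as.integer(z)) < 0L))
  if (any(bad)) {
    stop(
      "taxonomy not prefix-consistent at index ",
      paste(df$index[bad], collapse = ", ")
    )
  }
  ok_dir <- df$direction %in% c("ASD increased", "ASD decreased")
  if (!all(ok_dir)) {
    stop("unknown direction string: ", df$direction[!ok_dir][1L])
  }
  cohorts <- grep("^present_", names(df), value = TRUE)
  for (co in cohorts) {
    if (!all(df[[co]] %in% c("Yes", "No"))) {
      stop("presence column ", co, " must be Yes/No")
    }
  }
  if (!"sequence" %in% names(df)) df$sequence <- NA_character_
  df$sequence[df$sequence %in% c("", "NA")] <- NA_character_
  structure(df,
    cohorts = sub("^present_", "", cohorts),
    class = c("signature_table", "data.frame")
  )
}

#' Write a signature table
#'
#' @param sig a `signature_table` (or compatible data frame).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature_table <- function(sig, path) {
  out <- as.data.frame(sig)
  for (r in c(TAXONOMY_RANKS, "sequence")) {
    if (r %in% names(out)) out[[r]][is.na(out[[r]])] <- "NA"
  }
  write_tsv(out, path)
}

#' Count signature records at a taxonomy rank
#'
#' Tallies how many signature ASVs are assigned to each name at the given
#' rank; unassigned records (`NA` at that rank) are grouped under
#' `"unassigned"`. The counts always sum to the number of records.
#'
#' @param sig a `signature_table`.
#' @param rank one of `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @return Named integer vector of counts, decreasing, `"unassigned"` last.
#' @export
summarize_taxonomy <- function(sig, rank) {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  vals <- sig[[rank]]
  vals[is.na(vals)] <- "unassigned"
  tab <- table(vals)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  named <- counts[names(counts) != "unassigned"]
  named <- named[order(-named, names(named))]
  if ("unassigned" %in% names(counts)) {
    named <- c(named, counts["unassigned"])
  }
  named
}

#' Build a signature table from a feature-selection result
#'
#' Converts the selected, importance-ranked ASVs of a [run_refs()] result
#' into signature-table rows carrying the ASV id and sequence; taxonomy is
#' left unassigned (assignment is an upstream concern).
#'
#' @param refs a `refs_result` from [run_refs()].
#' @param table the discovery `asv_table` the result came from.
#' @param directions optional named character vector of per-ASV abundance
#'   directions (see [differential_abundance()]).
#' @return A `signature_table` with an extra `asv_id` column.
#' @export
signature_from_refs <- function(refs, table, directions = NULL) {
  ids <- refs$selected_asv_ids
  dir <- if (is.null(directions)) {
    rep("ASD increased", length(ids))
  } else {
    unname(directions[ids])
  }
  df <- data.frame(
    index = seq_along(ids),
    asv_id = ids,
    sequence = unname(table$sequences[ids]),
    domain = NA_character_, phylum = NA_character_, class = NA_character_,
    order = NA_character_, family = NA_character_, genus = NA_character_,
    species = NA_character_,
    direction = dir,
    stringsAsFactors = FALSE
  )
  structure(df, cohorts = character(), class = c("signature_table", "data.frame"))
}
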