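revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(s, function(x) {
    paste(rev(strsplit(x, "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}

#' Transfer a signature into a cohort by exact subsequence matching
#'
#' A discovery ASV is "present" in a validation cohort when its (shorter)
#' sequence occurs verbatim inside at least one of the cohort's ASV
#' sequences — different cohorts sequence different 16S regions at
#' different read lengths, so identity cannot be required. The counts of
#' all containing validation ASVs are summed and treated as one feature
#' named after the discovery ASV; a validation ASV containing two distinct
#' signature sequences contributes its counts to both aggregated columns
#' (flagged in the report). Matching is case-insensitive on the forward
#' strand; `rc = TRUE` additionally searches the reverse complement
#' (cohorts sequenced in opposite orientation), a hit on either
#' orientation counting once.
#'
#' @param signature_seqs named character vector, discovery ASV id -> DNA
#'   sequence.
#' @param validation an [asv_table()] for the validation cohort.
#' @param rc also search the reverse complement.
#' @return A `match_report`: `matches` (per discovery ASV: `matched`,
#'   `containing_asv_ids`, `n_containing`), `n_matched`, `shared_hosts`
#'   (validation ASVs contributing to more than one signature column) and
#'   `reduced_table`, an [asv_table()] of the validation samples over the
#'   matched discovery ids with aggregated counts.
#' @export
match_signature <- function(signature_seqs, validation, rc = FALSE) {
  if (length(signature_seqs) == 0L || is.null(names(signature_seqs))) {
    stop("signature_seqs must be a non-empty named vector")
  }
  if (ncol(validation$counts) == 0L) stop("validation table has no ASVs")
  sig <- toupper(gsub("U", "T", signature_seqs, ignore.case = TRUE))
  vseq <- toupper(validation$sequences)
  too_long <- nchar(sig) > max(nchar(vseq))
  if (any(too_long)) {
    warning(
      "signature sequence(s) longer than every validation sequence ",
      "(automatic non-match): ", paste(names(sig)[too_long], collapse = ", ")
    )
  }
  matches <- lapply(names(sig), function(d) {
    hit <- grepl(sig[[d]], vseq, fixed = TRUE)
    if (rc) hit <- hit | grepl(revcomp(sig[[d]]), vseq, fixed = TRUE)
    ids <- names(vseq)[hit]
    list(
      matched = length(ids) > 0L,
      containing_asv_ids = ids,
      n_containing = length(ids)
    )
  })
  names(matches) <- names(sig)
  matched_ids <- names(sig)[vapply(matches, `[[`, logical(1), "matched")]
  host_use <- table(unlist(lapply(matches[matched_ids], `[[`, "containing_asv_ids")))
  shared_hosts <- names(host_use)[host_use > 1L]
  reduced <- NULL
  if (length(matched_ids) > 0L) {
    agg <- vapply(matched_ids, function(d) {
      cols <- matches[[d]]$containing_asv_ids
      as.integer(rowSums(validation$counts[, cols, drop = FALSE]))
    }, integer(nrow(validation$counts)))
    agg <- matrix(agg,
      nrow = nrow(validation$counts),
      dimnames = list(rownames(validation$counts), matched_ids)
    )
    # built directly: the columns carry the (possibly shorter) signature
    # sequences, so the >= 50 nt ASV invariant does not apply here
    reduced <- structure(
      list(
        counts = agg,
        sequences = sig[matched_ids],
        labels = validation$labels[rownames(agg)]
      ),
      class = "asv_table"
    )
  }
  structure(
    list(
      matches = matches,
      n_matched = length(matched_ids),
      matched_asv_ids = matched_ids,
      shared_hosts = shared_hosts,
      reduced_table = reduced,
      rc = rc
    ),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> %d/%d signature ASVs matched%s\n",
    x$n_matched, length(x$matches),
    if (length(x$shared_hosts) > 0L) {
      sprintf(
        " (%d validation ASV(s) shared between signature columns)",
        length(x$shared_hosts)
      )
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Yes/No presence table of a match report
#'
#' @param report a `match_report`.
#' @param cohort_id column label for the cohort.
#' @return Data frame with columns `asv_id`, `present_<cohort_id>`
#'   (Yes/No) and `n_containing` — the per-cohort presence-column shape of
#'   a signature table.
#' @export
match_presence_table <- function(report, cohort_id = "validation") {
  df <- data.frame(
    asv_id = names(report$matches),
    presence = ifelse(
      vapply(report$matches, `[[`, logical(1), "matched"), "Yes", "No"
    ),
    n_containing = vapply(report$matches, `[[`, integer(1), "n_containing"),
    stringsAsFactors = FALSE
  )
  names(df)[2L] <- paste0("present_", cohort_id)
  rownames(df) <- NULL
  df
}
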