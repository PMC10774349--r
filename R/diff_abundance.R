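#' Standardized differential-abundance summary
#'
#' For each selected ASV the counts are standardized to zero mean and unit
#' variance over all samples (the same scaling the heat-maps use), and the
#' group means on that scale determine the abundance direction: "ASD
#' increased" when the case mean exceeds the control mean (sign-equivalent
#' to comparing raw means), "ASD decreased" when lower, "tied" on exact
#' equality. Structural-absence flags come from the raw counts: a taxon is
#' flagged absent in a group when every sample of that group has zero
#' counts.
#'
#' @param table an [asv_table()] containing both classes.
#' @param feature_ids subset of the table's ASV ids (defaults to all).
#' @return An `abundance_summary` data frame with one row per feature:
#'   `asv_id`, `mean_case`, `mean_control` (standardized scale),
#'   `direction`, `absent_in_case`, `absent_in_control`. The standardized
#'   samples x features matrix is attached as attribute `standardized`.
#' @export
differential_abundance <- function(table, feature_ids = colnames(table$counts)) {
  missing <- setdiff(feature_ids, colnames(table$counts))
  if (length(missing) > 0L) {
    stop("features absent from table: ", paste(missing, collapse = ", "))
  }
  sub <- subset_asvs(table, feature_ids)
  is_case <- sub$labels == "case"
  if (sum(is_case) == 0L || sum(!is_case) == 0L) {
    stop("both groups must be non-empty")
  }
  Z <- zscore_normalize(sub)
  mean_case <- colMeans(Z[is_case, , drop = FALSE])
  mean_control <- colMeans(Z[!is_case, , drop = FALSE])
  raw <- sub$counts
  out <- data.frame(
    asv_id = feature_ids,
    mean_case = unname(mean_case),
    mean_control = unname(mean_control),
    direction = ifelse(mean_case > mean_control, "ASD increased",
      ifelse(mean_case < mean_control, "ASD decreased", "tied")
    ),
    absent_in_case = unname(colSums(raw[is_case, , drop = FALSE]) == 0L),
    absent_in_control = unname(colSums(raw[!is_case, , drop = FALSE]) == 0L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "standardized") <- Z
  class(out) <- c("abundance_summary", "data.frame")
  out
}

#' Export a differential-abundance heat-map
#'
#' Writes the standardized samples x features matrix as TSV (bit-exact;
#' columns in the order of `feature_ids`, i.e. signature importance rank)
#' and renders a heat-map image with samples annotated by group. The TSV
#' is the testable artifact; the image is presentation only.
#'
#' @param table an [asv_table()].
#' @param feature_ids ordered feature set (signature rank order).
#' @param path_prefix output path without extension; writes
#'   `<prefix>.tsv` and `<prefix>.png`.
#' @param cluster_rows,cluster_cols passed to [pheatmap::pheatmap()].
#' @return Named character vector of the two paths, invisibly.
#' @export
export_heatmap <- function(table, feature_ids, path_prefix,
                           cluster_rows = FALSE, cluster_cols = FALSE) {
  if (length(feature_ids) == 0L) stop("feature selection is empty")
  summary <- differential_abundance(table, feature_ids)
  Z <- attr(summary, "standardized")
  tsv <- paste0(path_prefix, ".tsv")
  png <- paste0(path_prefix, ".png")
  write_tsv(
    data.frame(sample_id = rownames(Z), Z, check.names = FALSE),
    tsv
  )
  ann <- data.frame(
    group = unname(table$labels[rownames(Z)]),
    row.names = rownames(Z)
  )
  grDevices::png(png, width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  pheatmap::pheatmap(
    t(Z),
    cluster_rows = cluster_rows, cluster_cols = cluster_cols,
    annotation_col = ann, show_colnames = nrow(Z) <= 40,
    main = "Standardized abundance of selected ASVs"
  )
  invisible(c(tsv = tsv, png = png))
}
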