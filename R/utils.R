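#' @keywords internal
"_PACKAGE"

# Deterministic seed derivation. All randomness in the package flows from a
# master seed through this function, so replicate runs / folds / cohorts get
# independent but reproducible streams. Result stays below 2^31 - 1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in idx) {
    s <- (s * 69069 + as.double(k) * 7907 + 12345) %% 2147483647
  }
  as.integer(s) + 1L
}

# Stratified fold assignment keyed to *sorted* sample ids, so the assignment
# is invariant to input row order. Fold sizes within each class differ by at
# most one. If the rarer class has fewer samples than n_folds, the fold count
# is reduced to that class size (with a warning); < 2 per class is an error.
make_stratified_folds <- function(labels, n_folds, seed) {
  stopifnot(!is.null(names(labels)))
  labels <- labels[order(names(labels))]
  classes <- unique(labels)
  if (length(classes) < 2L) {
    stop("both classes must be present for stratified cross-validation")
  }
  min_class <- min(table(labels))
  if (min_class < 2L) {
    stop("need at least 2 samples in each class for cross-validation")
  }
  if (min_class < n_folds) {
    warning(sprintf(
      "reducing fold count from %d to %d (size of the rarer class)",
      n_folds, min_class
    ))
    n_folds <- min_class
  }
  set.seed(seed)
  fold <- integer(length(labels))
  names(fold) <- names(labels)
  for (cl in sort(classes)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Dirichlet draw that treats zero concentrations as structural zeros.
rdirichlet1 <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  total <- sum(g)
  if (total == 0) stop("all Dirichlet concentrations are zero")
  g / total
}

# TSV writers shared by the pipeline and the export helpers; no timestamps,
# fixed number formatting, so identical inputs give byte-identical files.
write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = row_names, col.names = TRUE
  )
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
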