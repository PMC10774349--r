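#' Empirical ROC curve points
#'
#' Standard empirical ROC: one threshold per distinct score, from
#' `(0, 0)` to `(1, 1)`, tied scores collapsed onto a single point (which
#' makes the trapezoidal area equal to the Mann-Whitney statistic with
#' ties counted half).
#'
#' @param scores numeric vector, larger = more case-like.
#' @param labels 0/1 vector (1 = case), same length.
#' @return Data frame with columns `fpr` and `tpr`, both monotone
#'   non-decreasing.
#' @export
roc_curve_points <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  last <- c(s[-1L] != s[-length(s)], TRUE) # keep last index of each tie group
  data.frame(
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve_points()]; numerically identical to
#' the probability that a random case outscores a random control, with
#' ties counted one half.
#'
#' @inheritParams roc_curve_points
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pts <- roc_curve_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Cross-validated AUC of a fixed feature set
#'
#' The held-out evaluation of a signature: the table is restricted to the
#' given features, z-score normalized (same policy as selection), and each
#' of the five validation classifiers is scored by ROC AUC in stratified
#' ten-fold cross-validation. Continuous scores are used throughout —
#' class probabilities where the learner provides them, otherwise its
#' decision function (for the lasso, the continuous regression prediction
#' against 0/1-coded labels).
#'
#' @param table an [asv_table()].
#' @param feature_ids non-empty subset of the table's ASV ids.
#' @param n_folds folds (stratified; reduced with a warning if a class is
#'   smaller).
#' @param seed seed for fold assignment and classifier randomness.
#' @param spec classifier panel, default [validation_classifier_spec()].
#' @param fold_safe_scaling as in [run_refs()].
#' @return A `validation_report`: `per_classifier` (mean_auc, sd,
#'   fold_aucs), `ensemble_mean` (mean of the five mean AUCs), and
#'   `roc_points` (per classifier, ROC of the scores pooled across
#'   folds).
#' @export
crossval_auc <- function(table, feature_ids, n_folds = 10L, seed = 1L,
                         spec = validation_classifier_spec(),
                         fold_safe_scaling = FALSE) {
  if (length(feature_ids) == 0L) stop("feature_ids must be non-empty")
  missing <- setdiff(feature_ids, colnames(table$counts))
  if (length(missing) > 0L) {
    stop("features absent from table: ", paste(missing, collapse = ", "))
  }
  sub <- subset_asvs(table, feature_ids)
  y01 <- label01(sub)
  names(y01) <- rownames(sub$counts)
  raw <- matrix(as.numeric(sub$counts),
    nrow = nrow(sub$counts), dimnames = dimnames(sub$counts)
  )
  # canonical sample order: the report is invariant to input row order
  raw <- raw[order(rownames(raw)), , drop = FALSE]
  y01 <- y01[rownames(raw)]
  X <- if (fold_safe_scaling) raw else zscore_normalize(raw)
  folds <- make_stratified_folds(y01, n_folds, derive_seed(seed, 7L))
  fold_of <- folds[rownames(X)]
  n_folds_eff <- max(folds)
  per <- list()
  roc_points <- list()
  for (cname in names(spec)) {
    clf <- spec[[cname]]
    fold_aucs <- numeric(n_folds_eff)
    pooled_scores <- numeric(0)
    pooled_labels <- integer(0)
    for (f in seq_len(n_folds_eff)) {
      tr <- which(fold_of != f)
      te <- which(fold_of == f)
      if (fold_safe_scaling) {
        mu <- colMeans(raw[tr, , drop = FALSE])
        sdp <- sqrt(colMeans(sweep(raw[tr, , drop = FALSE], 2L, mu)^2))
        sdp[sdp == 0] <- 1
        Xtr <- sweep(sweep(raw[tr, , drop = FALSE], 2L, mu), 2L, sdp, "/")
        Xte <- sweep(sweep(raw[te, , drop = FALSE], 2L, mu), 2L, sdp, "/")
      } else {
        Xtr <- X[tr, , drop = FALSE]
        Xte <- X[te, , drop = FALSE]
      }
      Xtr <- pad_single_column(Xtr)
      Xte <- pad_single_column(Xte)
      model <- clf$fit(Xtr, y01[tr], derive_seed(seed, f, match(cname, names(spec))))
      sc <- clf$score(model, Xte)
      fold_aucs[f] <- auc_score(sc, y01[te])
      pooled_scores <- c(pooled_scores, sc)
      pooled_labels <- c(pooled_labels, y01[te])
    }
    per[[cname]] <- list(
      mean_auc = mean(fold_aucs),
      sd = stats::sd(fold_aucs),
      fold_aucs = fold_aucs
    )
    roc_points[[cname]] <- roc_curve_points(pooled_scores, pooled_labels)
  }
  structure(
    list(
      per_classifier = per,
      ensemble_mean = mean(vapply(per, `[[`, numeric(1), "mean_auc")),
      roc_points = roc_points,
      n_folds = n_folds_eff,
      feature_ids = feature_ids,
      seed = seed
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d features, %d-fold CV\n",
    length(x$feature_ids), x$n_folds
  ))
  for (cname in names(x$per_classifier)) {
    p <- x$per_classifier[[cname]]
    cat(sprintf("  %-14s mean AUC %.3f (sd %.3f)\n", cname, p$mean_auc, p$sd))
  }
  cat(sprintf("  %-14s %.3f\n", "average", x$ensemble_mean))
  invisible(x)
}

#' Tabulate a validation report
#'
#' @param report a `validation_report`.
#' @return Data frame with one row per classifier plus an `average` row
#'   (columns `classifier`, `mean_auc`, `sd`) — the per-cohort AUC-table
#'   shape.
#' @export
validation_report_table <- function(report) {
  rows <- lapply(names(report$per_classifier), function(cname) {
    p <- report$per_classifier[[cname]]
    data.frame(
      classifier = cname, mean_auc = p$mean_auc, sd = p$sd,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(
    classifier = "average",
    mean_auc = report$ensemble_mean,
    sd = mean(out$sd)
  ))
}
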