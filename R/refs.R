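#' Z-score normalize a count matrix
#'
#' Per-feature (column) standardization to zero mean and unit variance,
#' computed with the population (biased, 1/n) standard deviation over all
#' samples. Constant columns, which carry no information, map to all
#' zeros.
#'
#' @param table an [asv_table()], or a numeric samples x features matrix.
#' @return Numeric matrix of the same shape.
#' @export
zscore_normalize <- function(table) {
  X <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  if (nrow(X) < 2L) stop("z-score normalization needs at least 2 samples")
  X <- matrix(as.numeric(X), nrow = nrow(X), dimnames = dimnames(X))
  mu <- colMeans(X)
  sdp <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  Xc <- sweep(X, 2L, mu)
  nz <- sdp > 0
  Xc[, nz] <- sweep(Xc[, nz, drop = FALSE], 2L, sdp[nz], "/")
  Xc[, !nz] <- 0
  Xc
}

#' Recursive-elimination feature schedule
#'
#' Feature counts visited when the 20% least important features (at least
#' one) are removed each cycle until a single feature remains:
#' `n_{k+1} = n_k - max(1, floor(0.2 n_k))`. Starting from 2040 features
#' the schedule passes through 26, the published signature size.
#'
#' @param n_start starting feature count (>= 1).
#' @return Integer vector from `n_start` down to 1.
#' @export
elimination_schedule <- function(n_start) {
  n_start <- as.integer(n_start)
  if (n_start < 1L) stop("n_start must be at least 1")
  out <- n_start
  n <- n_start
  while (n > 1L) {
    n <- n - max(1L, as.integer(floor(0.2 * n)))
    out <- c(out, n)
  }
  out
}

#' Ensemble feature importance under stratified cross-validation
#'
#' For each of `n_folds` stratified folds and each of the eight ensemble
#' members: the member is fitted on the training fold, its per-feature
#' importance vector is extracted and L1-normalized (so members with
#' different importance scales contribute equally), and its accuracy and
#' ROC AUC on the held-out fold are recorded. The returned importance is
#' the mean over all fold x member vectors, itself summing to one.
#'
#' @param X numeric samples x features matrix with column names
#'   (normalized; see [zscore_normalize()]).
#' @param y01 0/1 integer labels (1 = case), named by sample id.
#' @param spec ensemble definition, by default [refs_ensemble_spec()].
#' @param n_folds outer folds (reduced with a warning when the rarer class
#'   is smaller).
#' @param seed seed controlling fold assignment and member randomness.
#' @return List with `importance` (named, non-negative, sums to 1) and
#'   `fold_scores` (data frame: fold, member, accuracy, auc).
#' @export
ensemble_importance <- function(X, y01, spec = refs_ensemble_spec(),
                                n_folds = 10L, seed = 1L) {
  p <- ncol(X)
  if (is.null(names(y01))) names(y01) <- rownames(X)
  # canonical sample order: results do not depend on input row order
  X <- X[order(rownames(X)), , drop = FALSE]
  y01 <- y01[rownames(X)]
  folds <- make_stratified_folds(y01, n_folds, derive_seed(seed, 101L))
  # fold assignment is keyed to sample ids; recover per-row fold
  fold_of <- folds[rownames(X)]
  n_folds_eff <- max(folds)
  imp_sum <- numeric(p)
  n_imp <- 0L
  scores <- vector("list", n_folds_eff * length(spec))
  k <- 0L
  for (f in seq_len(n_folds_eff)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    Xtr <- pad_single_column(X[tr, , drop = FALSE])
    Xte <- pad_single_column(X[te, , drop = FALSE])
    ytr <- y01[tr]
    yte <- y01[te]
    for (mname in names(spec)) {
      k <- k + 1L
      member <- spec[[mname]]
      mseed <- derive_seed(seed, f, match(mname, names(spec)))
      model <- member$fit(Xtr, ytr, mseed)
      imp <- member$importance(model, ncol(Xtr))[seq_len(p)]
      imp[!is.finite(imp) | imp < 0] <- 0
      s <- sum(imp)
      if (s > 0) {
        imp_sum <- imp_sum + imp / s
        n_imp <- n_imp + 1L
      }
      sc <- member$score(model, Xte)
      pred <- as.integer(sc > score_threshold(member, model, sc))
      acc <- mean(pred == yte)
      auc <- if (length(unique(yte)) == 2L) auc_score(sc, yte) else NA_real_
      scores[[k]] <- data.frame(
        fold = f, member = mname, accuracy = acc, auc = auc,
        stringsAsFactors = FALSE
      )
    }
  }
  importance <- if (n_imp > 0L) imp_sum / n_imp else rep(1 / p, p)
  # renormalize: members whose importance degenerated to all-zero are skipped
  importance <- importance / sum(importance)
  names(importance) <- colnames(X)
  list(importance = importance, fold_scores = do.call(rbind, scores))
}

# Probability-like scores are cut at 0.5, margins at 0.
score_threshold <- function(member, model, scores) {
  if (all(scores >= 0 & scores <= 1)) 0.5 else 0
}

# Several learners require >= 2 columns; the final single-feature cycle is
# fitted with a constant zero pad column whose importance is discarded.
pad_single_column <- function(X) {
  if (ncol(X) > 1L) {
    return(X)
  }
  cbind(X, .pad = 0)
}

stratified_fold_assignment <- function(labels, n_folds, seed) {
  make_stratified_folds(labels, n_folds, seed)
}

#' Recursive ensemble feature selection (REFS)
#'
#' The complete selection procedure: the count matrix is z-score
#' normalized once on the full data (the procedure's stated order; see
#' `fold_safe_scaling` for the leak-free alternative), then each of
#' `n_runs` independently seeded runs iterates elimination cycles — score
#' the currently retained features with [ensemble_importance()], record
#' the mean held-out accuracy as the cycle score, and drop the 20% least
#' important features — until one feature remains. The best cycle of a run
#' maximizes mean accuracy (ties prefer fewer features); the best run
#' maximizes its best cycle's score (ties prefer the lower run index). The
#' selected signature is that cycle's retained set, ranked by decreasing
#' ensemble importance.
#'
#' @param table an [asv_table()] with both classes present.
#' @param spec ensemble definition, default [refs_ensemble_spec()].
#' @param n_runs number of replicate runs (each with a derived seed).
#' @param n_folds cross-validation folds per cycle.
#' @param seed master seed; run seeds are derived by run index, so results
#'   do not depend on execution order.
#' @param fold_safe_scaling when `TRUE`, normalization statistics are
#'   computed on each training fold only and applied to its test fold,
#'   avoiding the information leak of whole-matrix scaling (off by
#'   default, matching the procedure as published; a warning notes the
#'   leak when off).
#' @param verbose print per-run progress.
#' @return A `refs_result`: `runs` (per run: seed and a cycle data frame
#'   with `n_features`, `mean_score` (accuracy), `score_sd`, `mean_auc`,
#'   retained ids), `curve` (all runs stacked), `best_run`, `best_cycle`,
#'   `selected_asv_ids` (importance-ranked) and `importance_rank`.
#' @export
run_refs <- function(table, spec = refs_ensemble_spec(), n_runs = 30L,
                     n_folds = 10L, seed = 1L, fold_safe_scaling = FALSE,
                     verbose = FALSE) {
  y01 <- label01(table)
  names(y01) <- rownames(table$counts)
  if (length(unique(y01)) < 2L) stop("both classes must be present")
  if (!fold_safe_scaling) {
    message(
      "normalization is fitted on the full matrix before cross-validation ",
      "(the procedure's published order); set fold_safe_scaling = TRUE for ",
      "leak-free per-fold scaling"
    )
  }
  Xfull <- if (fold_safe_scaling) {
    matrix(as.numeric(table$counts),
      nrow = nrow(table$counts),
      dimnames = dimnames(table$counts)
    )
  } else {
    zscore_normalize(table)
  }
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, 1000L + r)
    retained <- colnames(Xfull)
    cycles <- list()
    cyc <- 0L
    repeat {
      cyc <- cyc + 1L
      Xc <- Xfull[, retained, drop = FALSE]
      if (fold_safe_scaling) {
        ei <- ensemble_importance_foldsafe(
          Xc, y01, spec, n_folds,
          derive_seed(run_seed, cyc)
        )
      } else {
        ei <- ensemble_importance(Xc, y01, spec, n_folds, derive_seed(run_seed, cyc))
      }
      cycles[[cyc]] <- list(
        cycle_index = cyc,
        retained_asv_ids = retained,
        n_features = length(retained),
        mean_score = mean(ei$fold_scores$accuracy),
        score_sd = stats::sd(ei$fold_scores$accuracy),
        mean_auc = mean(ei$fold_scores$auc, na.rm = TRUE),
        importance = ei$importance
      )
      if (length(retained) == 1L) break
      n_drop <- max(1L, as.integer(floor(0.2 * length(retained))))
      # stable ordering: ties broken by current column position
      ord <- order(ei$importance, seq_along(ei$importance), decreasing = TRUE)
      retained <- retained[sort(ord[seq_len(length(retained) - n_drop)])]
    }
    if (verbose) {
      message(sprintf(
        "run %d/%d: best cycle score %.3f", r, n_runs,
        max(vapply(cycles, `[[`, numeric(1), "mean_score"))
      ))
    }
    runs[[r]] <- list(run_seed = run_seed, cycles = cycles)
  }
  curve <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    do.call(rbind, lapply(runs[[r]]$cycles, function(cy) {
      data.frame(
        run = r, cycle = cy$cycle_index, n_features = cy$n_features,
        mean_score = cy$mean_score, score_sd = cy$score_sd,
        mean_auc = cy$mean_auc
      )
    }))
  }))
  best_cycle_of_run <- integer(n_runs)
  best_score_of_run <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    sc <- vapply(runs[[r]]$cycles, `[[`, numeric(1), "mean_score")
    nf <- vapply(runs[[r]]$cycles, `[[`, integer(1), "n_features")
    # max score; ties resolved toward fewer features
    cand <- which(sc == max(sc))
    best_cycle_of_run[r] <- cand[which.min(nf[cand])]
    best_score_of_run[r] <- max(sc)
  }
  best_run <- which.max(best_score_of_run) # ties: lower run index
  best_cycle <- best_cycle_of_run[best_run]
  chosen <- runs[[best_run]]$cycles[[best_cycle]]
  ord <- order(chosen$importance, seq_along(chosen$importance), decreasing = TRUE)
  selected <- chosen$retained_asv_ids[ord]
  rank <- seq_along(selected)
  names(rank) <- selected
  structure(
    list(
      runs = runs, curve = curve, best_run = best_run,
      best_cycle = best_cycle, selected_asv_ids = selected,
      importance_rank = rank, n_runs = n_runs, n_folds = n_folds,
      seed = seed
    ),
    class = "refs_result"
  )
}

#' @export
print.refs_result <- function(x, ...) {
  chosen <- x$runs[[x$best_run]]$cycles[[x$best_cycle]]
  cat(sprintf(
    paste0(
      "<refs_result> %d runs x %d-fold CV\n",
      "  best run %d, cycle %d: %d features, mean accuracy %.3f (AUC %.3f)\n"
    ),
    x$n_runs, x$n_folds, x$best_run, x$best_cycle,
    chosen$n_features, chosen$mean_score, chosen$mean_auc
  ))
  invisible(x)
}

# Fold-safe variant: per-fold training-set scaling. Slower and not the
# procedure's published order; exposed through run_refs(fold_safe_scaling=).
ensemble_importance_foldsafe <- function(Xraw, y01, spec, n_folds, seed) {
  Xraw <- Xraw[order(rownames(Xraw)), , drop = FALSE]
  y01 <- y01[rownames(Xraw)]
  folds <- make_stratified_folds(y01, n_folds, derive_seed(seed, 101L))
  fold_of <- folds[rownames(Xraw)]
  n_folds_eff <- max(folds)
  p <- ncol(Xraw)
  imp_sum <- numeric(p)
  n_imp <- 0L
  scores <- list()
  k <- 0L
  for (f in seq_len(n_folds_eff)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    mu <- colMeans(Xraw[tr, , drop = FALSE])
    sdp <- sqrt(colMeans(sweep(Xraw[tr, , drop = FALSE], 2L, mu)^2))
    sdp[sdp == 0] <- 1
    Xtr <- pad_single_column(
      sweep(sweep(Xraw[tr, , drop = FALSE], 2L, mu), 2L, sdp, "/")
    )
    Xte <- pad_single_column(
      sweep(sweep(Xraw[te, , drop = FALSE], 2L, mu), 2L, sdp, "/")
    )
    for (mname in names(spec)) {
      k <- k + 1L
      member <- spec[[mname]]
      model <- member$fit(Xtr, y01[tr], derive_seed(seed, f, match(mname, names(spec))))
      imp <- member$importance(model, ncol(Xtr))[seq_len(p)]
      imp[!is.finite(imp) | imp < 0] <- 0
      if (sum(imp) > 0) {
        imp_sum <- imp_sum + imp / sum(imp)
        n_imp <- n_imp + 1L
      }
      sc <- member$score(model, Xte)
      pred <- as.integer(sc > score_threshold(member, model, sc))
      scores[[k]] <- data.frame(
        fold = f, member = mname,
        accuracy = mean(pred == y01[te]),
        auc = if (length(unique(y01[te])) == 2L) auc_score(sc, y01[te]) else NA_real_
      )
    }
  }
  importance <- if (n_imp > 0L) imp_sum / n_imp else rep(1 / p, p)
  importance <- importance / sum(importance)
  names(importance) <- colnames(Xraw)
  list(importance = importance, fold_scores = do.call(rbind, scores))
}
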