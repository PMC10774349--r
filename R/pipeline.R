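run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Run the full discovery-and-validation workflow
#'
#' Orchestrates the two-phase pipeline on in-memory tables: feature
#' selection on the discovery cohort ([run_refs()]), held-out evaluation
#' of the selected signature ([crossval_auc()]), then for each validation
#' cohort a sequence-matching transfer ([match_signature()]) followed by
#' held-out evaluation of the aggregated features, and finally a
#' standardized differential-abundance summary and heat-map for the
#' discovery signature. Every artifact is written under `out_dir` without
#' timestamps, and a manifest records the resolved configuration, the
#' master seed and an MD5 per file — so a rerun under the same seed
#' produces byte-identical tables.
#'
#' @param discovery an [asv_table()] for the discovery cohort.
#' @param validation_cohorts named list of [asv_table()]s (may be empty).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stage derives its stream from it.
#' @param n_runs,n_folds passed to [run_refs()] / [crossval_auc()].
#' @param fold_safe_scaling passed through to selection and validation.
#' @param heatmap also render the heat-map image (the TSV is always
#'   written).
#' @return The manifest, invisibly: resolved config, per-stage summaries
#'   and the artifact table. Also written as `manifest.json`.
#' @export
run_pipeline <- function(discovery, validation_cohorts = list(),
                         out_dir, seed = 1L, n_runs = 30L, n_folds = 10L,
                         fold_safe_scaling = FALSE, heatmap = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    artifacts <<- c(artifacts, path)
    path
  }

  refs <- run_stage("select", run_refs(discovery,
    n_runs = n_runs, n_folds = n_folds,
    seed = derive_seed(seed, 11L), fold_safe_scaling = fold_safe_scaling
  ))
  da <- run_stage("report", differential_abundance(discovery, refs$selected_asv_ids))
  directions <- da$direction
  names(directions) <- da$asv_id
  sig <- signature_from_refs(refs, discovery, directions)
  write_signature_table(sig, emit("signature.tsv"))
  write_tsv(refs$curve, emit("refs_curve.tsv"))

  disc_report <- run_stage("validate", crossval_auc(
    discovery, refs$selected_asv_ids,
    n_folds = n_folds, seed = derive_seed(seed, 12L),
    fold_safe_scaling = fold_safe_scaling
  ))
  write_tsv(validation_report_table(disc_report), emit("discovery_auc.tsv"))

  cohort_summaries <- list()
  for (cohort_id in names(validation_cohorts)) {
    vt <- validation_cohorts[[cohort_id]]
    rep_match <- run_stage(
      paste0("match:", cohort_id),
      match_signature(discovery$sequences[refs$selected_asv_ids], vt)
    )
    write_tsv(
      match_presence_table(rep_match, cohort_id),
      emit(sprintf("presence_%s.tsv", cohort_id))
    )
    if (rep_match$n_matched == 0L) {
      cohort_summaries[[cohort_id]] <- list(n_matched = 0L, mean_auc = NA_real_)
      next
    }
    write_tsv(
      data.frame(
        sample_id = rownames(rep_match$reduced_table$counts),
        rep_match$reduced_table$counts, check.names = FALSE
      ),
      emit(sprintf("reduced_counts_%s.tsv", cohort_id))
    )
    vrep <- run_stage(
      paste0("validate:", cohort_id),
      crossval_auc(
        rep_match$reduced_table, rep_match$matched_asv_ids,
        n_folds = n_folds,
        seed = derive_seed(seed, 13L, match(cohort_id, names(validation_cohorts))),
        fold_safe_scaling = fold_safe_scaling
      )
    )
    write_tsv(
      validation_report_table(vrep),
      emit(sprintf("validation_auc_%s.tsv", cohort_id))
    )
    cohort_summaries[[cohort_id]] <- list(
      n_matched = rep_match$n_matched,
      mean_auc = vrep$ensemble_mean
    )
  }

  write_tsv(as.data.frame(da), emit("differential_abundance.tsv"))
  if (heatmap) {
    run_stage("report", export_heatmap(
      discovery, refs$selected_asv_ids,
      file.path(out_dir, "heatmap")
    ))
    artifacts <- c(artifacts, file.path(out_dir, c("heatmap.tsv", "heatmap.png")))
  } else {
    run_stage("report", {
      Z <- attr(da, "standardized")
      write_tsv(
        data.frame(sample_id = rownames(Z), Z, check.names = FALSE),
        emit("heatmap.tsv")
      )
    })
  }

  manifest <- list(
    config = list(
      seed = seed, n_runs = n_runs, n_folds = n_folds,
      fold_safe_scaling = fold_safe_scaling,
      discovery_dim = dim(discovery$counts),
      validation_cohorts = names(validation_cohorts)
    ),
    selection = list(
      n_selected = length(refs$selected_asv_ids),
      best_run = refs$best_run,
      best_cycle = refs$best_cycle,
      selected_asv_ids = refs$selected_asv_ids,
      best_cycle_accuracy =
        refs$runs[[refs$best_run]]$cycles[[refs$best_cycle]]$mean_score
    ),
    discovery_auc = disc_report$ensemble_mean,
    cohorts = cohort_summaries,
    artifacts = data.frame(
      path = basename(artifacts),
      md5 = unname(tools::md5sum(artifacts)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
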