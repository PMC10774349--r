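#' Configuration for the synthetic cohort generator
#'
#' The simulator emulates the statistical structure a 16S case-control
#' study hands to feature selection: overdispersed compositional counts
#' (Dirichlet-multinomial), a small planted set of discriminative ASVs, a
#' few taxa structurally absent from one group, and a second cohort
#' sequenced with longer reads whose ASVs contain discovery ASVs as exact
#' subsequences.
#'
#' Defaults mirror the discovery study design this pipeline was built
#' around: 60 cases and 57 sibling controls, a signature-sized planted set
#' of 26 discriminative ASVs, 150 nt discovery reads and 250 nt validation
#' reads, and roughly 15% of informative ASVs structurally absent in one
#' group (4 of the 26 published signature taxa were reported absent from
#' one group).
#'
#' @param n_case,n_control samples per group.
#' @param n_asv total number of ASVs.
#' @param n_informative number of planted discriminative ASVs.
#' @param effect_size log-fold separation of an informative ASV's expected
#'   relative abundance between groups: group concentrations are multiplied
#'   by `exp(+/- effect_size / 2)`, so the expected case:control
#'   relative-abundance ratio is about `exp(effect_size)`.
#' @param library_size_mean mean sequencing depth per sample; depths are
#'   drawn as `min_library_size + Poisson(library_size_mean - min_library_size)`.
#' @param min_library_size lower bound of the shifted-Poisson depth law.
#' @param overdispersion total Dirichlet concentration; smaller values give
#'   noisier compositions (count variance is inflated roughly by
#'   `(depth + overdispersion) / (1 + overdispersion)` relative to
#'   multinomial sampling).
#' @param discovery_read_len,validation_read_len ASV sequence lengths (nt)
#'   in the two cohorts; validation reads must be at least as long.
#' @param frac_absent_in_one_group fraction of informative ASVs whose
#'   concentration is zeroed in their depleted group (structural absence).
#' @param seed master seed; fixes every downstream draw bit-exactly.
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_case = 60L, n_control = 57L, n_asv = 2040L,
                             n_informative = 26L, effect_size = 2,
                             library_size_mean = 10000L,
                             min_library_size = 1000L,
                             overdispersion = 200,
                             discovery_read_len = 150L,
                             validation_read_len = 250L,
                             frac_absent_in_one_group = 0.15,
                             seed = 1L) {
  cfg <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_asv = as.integer(n_asv), n_informative = as.integer(n_informative),
    effect_size = effect_size,
    library_size_mean = as.integer(library_size_mean),
    min_library_size = as.integer(min_library_size),
    overdispersion = overdispersion,
    discovery_read_len = as.integer(discovery_read_len),
    validation_read_len = as.integer(validation_read_len),
    frac_absent_in_one_group = frac_absent_in_one_group,
    seed = as.integer(seed)
  )
  if (cfg$n_case < 1L || cfg$n_control < 1L) stop("need at least one sample per group")
  if (cfg$n_informative > cfg$n_asv) stop("n_informative exceeds n_asv")
  if (cfg$discovery_read_len < 50L || cfg$validation_read_len < 50L) {
    stop("read lengths must be at least 50 nt")
  }
  if (cfg$validation_read_len < cfg$discovery_read_len) {
    stop("validation_read_len must be >= discovery_read_len")
  }
  if (cfg$effect_size < 0) stop("effect_size must be non-negative")
  if (cfg$overdispersion <= 0) stop("overdispersion must be positive")
  if (cfg$frac_absent_in_one_group < 0 || cfg$frac_absent_in_one_group > 1) {
    stop("frac_absent_in_one_group must be in [0, 1]")
  }
  if (cfg$library_size_mean <= cfg$min_library_size) {
    stop("library_size_mean must exceed min_library_size")
  }
  structure(cfg, class = "synthetic_config")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

# Generative model shared by both cohorts of a study: a log-normal baseline
# relative-abundance profile scaled to the Dirichlet concentration, with
# per-group concentration vectors after applying planted effects and
# structural zeros. Draw order (profile, effect signs, absences) is fixed so
# a seed pins the model bit-exactly.
build_generative_model <- function(cfg, asv_prefix = "ASV") {
  informative <- seq_len(cfg$n_informative)
  base <- exp(stats::rnorm(cfg$n_asv, mean = 0, sd = 1))
  base <- base / sum(base)
  alpha <- base * cfg$overdispersion
  signs <- if (cfg$n_informative > 0L) {
    ifelse(stats::runif(cfg$n_informative) < 0.5, 1, -1)
  } else {
    numeric(0)
  }
  alpha_case <- alpha
  alpha_control <- alpha
  if (cfg$n_informative > 0L) {
    alpha_case[informative] <- alpha[informative] * exp(signs * cfg$effect_size / 2)
    alpha_control[informative] <- alpha[informative] * exp(-signs * cfg$effect_size / 2)
    n_absent <- floor(cfg$frac_absent_in_one_group * cfg$n_informative)
    if (n_absent > 0L) {
      absent <- sample(informative, n_absent)
      for (j in absent) {
        if (signs[j] > 0) alpha_control[j] <- 0 else alpha_case[j] <- 0
      }
    }
  }
  asv_ids <- sprintf("%s%04d", asv_prefix, seq_len(cfg$n_asv))
  list(
    asv_ids = asv_ids,
    alpha_case = alpha_case,
    alpha_control = alpha_control,
    informative_idx = informative,
    signs = signs
  )
}

sample_cohort_counts <- function(model, cfg, sample_prefix) {
  n <- cfg$n_case + cfg$n_control
  groups <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))
  counts <- matrix(0L, nrow = n, ncol = cfg$n_asv)
  lib <- cfg$min_library_size +
    stats::rpois(n, cfg$library_size_mean - cfg$min_library_size)
  for (i in seq_len(n)) {
    alpha <- if (groups[i] == "case") model$alpha_case else model$alpha_control
    p <- rdirichlet1(alpha)
    counts[i, ] <- as.integer(stats::rmultinom(1L, size = lib[i], prob = p))
  }
  rownames(counts) <- sprintf("%s%03d", sample_prefix, seq_len(n))
  colnames(counts) <- model$asv_ids
  labels <- groups
  names(labels) <- rownames(counts)
  list(counts = counts, labels = labels)
}

#' Generate a synthetic discovery cohort
#'
#' Per sample, a library size is drawn from a shifted Poisson, a
#' composition from a Dirichlet whose concentration encodes the group's
#' planted effects, and counts from the corresponding multinomial. ASV
#' sequences are i.i.d. uniform DNA of the discovery read length, pairwise
#' distinct. One RNG stream is seeded per call; counts are drawn before
#' sequences, so the draw order (and hence every output) is fixed by the
#' config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `table` (the [asv_table()]) and `truth`, the ground
#'   truth: `informative_asv_ids`, per-ASV signed log-fold effects
#'   (`effects`, positive = enriched in cases), structural-absence flags,
#'   and the generative model used (so an independent cohort from the same
#'   law can be drawn with [generate_validation()]).
#' @export
generate_discovery <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  model <- build_generative_model(cfg, asv_prefix = "ASV")
  cohort <- sample_cohort_counts(model, cfg, sample_prefix = "S")
  seqs <- unique_dna_sequences(cfg$n_asv, cfg$discovery_read_len)
  names(seqs) <- model$asv_ids
  table <- asv_table(cohort$counts, seqs, cohort$labels)
  effects <- model$signs * cfg$effect_size
  names(effects) <- model$asv_ids[model$informative_idx]
  truth <- list(
    informative_asv_ids = model$asv_ids[model$informative_idx],
    effects = effects,
    absent_in_case = model$asv_ids[model$alpha_case == 0],
    absent_in_control = model$asv_ids[model$alpha_control == 0],
    containment_map = list(),
    model = model
  )
  list(table = table, truth = truth)
}

unique_dna_sequences <- function(n, len) {
  seqs <- random_dna(n, len)
  while (anyDuplicated(seqs)) { # astronomically unlikely at len >= 50
    dup <- which(duplicated(seqs))
    seqs[dup] <- random_dna(length(dup), len)
  }
  seqs
}

#' Generate a synthetic validation cohort with engineered containment
#'
#' Draws an independent cohort whose ASVs follow the same generative law as
#' the discovery cohort (each validation ASV `VASVk` inherits the planted
#' effect of discovery `ASVk`), but sequenced with longer reads: for each
#' discovery informative ASV that is not dropped, its matching validation
#' ASV — plus 0-2 additional random ASVs, emulating distinct but closely
#' related bacteria sharing the amplicon — is given a sequence that
#' contains the discovery sequence verbatim at a random offset. A
#' `drop_fraction` of informative ASVs get no containing validation ASV at
#' all, emulating signature taxa absent from a validation cohort.
#'
#' @param cfg the [synthetic_config()] used for the discovery cohort.
#' @param discovery result of [generate_discovery()] (table + truth).
#' @param drop_fraction fraction of discovery informative ASVs left without
#'   any containing validation ASV.
#' @param seed_offset integer folded into the seed so several validation
#'   cohorts can be drawn from one config.
#' @return A list with `table` and `truth`; `truth$containment_map` maps
#'   each matched discovery ASV id to the validation ASV ids engineered to
#'   contain its sequence.
#' @export
generate_validation <- function(cfg, discovery, drop_fraction = 0,
                                seed_offset = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (drop_fraction < 0 || drop_fraction > 1) stop("drop_fraction must be in [0, 1]")
  if (cfg$validation_read_len < cfg$discovery_read_len) {
    stop("validation_read_len must be >= discovery_read_len")
  }
  model <- discovery$truth$model
  set.seed(derive_seed(cfg$seed, 2L, seed_offset))
  vmodel <- model
  vmodel$asv_ids <- sub("^ASV", "VASV", model$asv_ids)
  cohort <- sample_cohort_counts(vmodel, cfg, sample_prefix = "V")
  vseqs <- unique_dna_sequences(cfg$n_asv, cfg$validation_read_len)
  names(vseqs) <- vmodel$asv_ids

  inf_ids <- discovery$truth$informative_asv_ids
  n_drop <- round(drop_fraction * length(inf_ids))
  dropped <- if (n_drop > 0L) sample(inf_ids, n_drop) else character(0)
  kept <- setdiff(inf_ids, dropped)
  containment <- list()
  used_hosts <- character(0)
  for (d in kept) {
    dseq <- discovery$table$sequences[[d]]
    partner <- sub("^ASV", "VASV", d)
    n_extra <- sample(0:2, 1L)
    # each host carries exactly one embedded signature: overlapping
    # embeddings would silently destroy an earlier containment
    extras <- setdiff(
      vmodel$asv_ids,
      c(partner, sub("^ASV", "VASV", inf_ids), used_hosts)
    )
    hosts <- c(partner, if (n_extra > 0L) sample(extras, n_extra))
    used_hosts <- c(used_hosts, hosts)
    for (h in hosts) {
      offset <- sample.int(cfg$validation_read_len - nchar(dseq) + 1L, 1L) - 1L
      s <- vseqs[[h]]
      substr(s, offset + 1L, offset + nchar(dseq)) <- dseq
      vseqs[[h]] <- s
    }
    containment[[d]] <- hosts
  }
  table <- asv_table(cohort$counts, vseqs, cohort$labels)
  effects <- discovery$truth$effects
  names(effects) <- sub("^ASV", "VASV", names(effects))
  truth <- list(
    informative_asv_ids = sub("^ASV", "VASV", inf_ids),
    effects = effects,
    absent_in_case = vmodel$asv_ids[vmodel$alpha_case == 0],
    absent_in_control = vmodel$asv_ids[vmodel$alpha_control == 0],
    containment_map = containment,
    dropped_asv_ids = dropped,
    model = vmodel
  )
  list(table = table, truth = truth)
}

#' Generate an independent replicate of the discovery cohort
#'
#' Same generative law (baseline profile, planted effects, sequences, read
#' length, ASV ids) as an existing discovery cohort, but freshly sampled
#' subjects — the synthetic analogue of an independent cohort profiled with
#' the identical assay, used for held-out evaluation of a selected
#' signature without the sequence-matching step.
#'
#' @param cfg the [synthetic_config()] used for the discovery cohort.
#' @param discovery result of [generate_discovery()].
#' @param seed_offset integer folded into the seed.
#' @return An [asv_table()].
#' @export
generate_replicate <- function(cfg, discovery, seed_offset = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 3L, seed_offset))
  cohort <- sample_cohort_counts(discovery$truth$model, cfg, sample_prefix = "R")
  asv_table(cohort$counts, discovery$table$sequences, cohort$labels)
}
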