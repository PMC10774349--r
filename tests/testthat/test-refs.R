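test_that("z-score normalization matches the closed form", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2, dimnames = list(c("s1", "s2", "s3"), c("f1", "f2")))
  z <- zscore_normalize(m)
  # population sd of (1,2,3) is sqrt(2/3)
  expect_equal(z[, "f1"], c(s1 = -1, s2 = 0, s3 = 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(unname(z[, "f2"]), c(0, 0, 0))
  expect_error(zscore_normalize(m[1, , drop = FALSE]), "at least 2")

  set.seed(1)
  r <- matrix(rnorm(200), nrow = 20)
  zr <- zscore_normalize(r)
  expect_lt(max(abs(colMeans(zr))), 1e-9)
  expect_lt(max(abs(colMeans(zr^2) - 1)), 1e-9)
})

test_that("the elimination schedule follows n -> n - max(1, floor(0.2 n))", {
  s <- elimination_schedule(2040)
  expect_identical(s[1], 2040L)
  expect_identical(s[length(s)], 1L)
  expect_true(26L %in% s)
  expect_identical(diff(s), -vapply(s[-length(s)], function(n) {
    max(1L, as.integer(floor(0.2 * n)))
  }, integer(1)))
  expect_identical(elimination_schedule(1), 1L)
  expect_identical(elimination_schedule(5), 5:1)
})

test_that("ensemble importance is an L1-normalized non-negative profile", {
  cfg <- small_cfg(2, n_asv = 30L)
  d <- generate_discovery(cfg)
  X <- zscore_normalize(d$table)
  y <- refsig:::label01(d$table)
  names(y) <- rownames(X)
  ei <- ensemble_importance(X, y, n_folds = 5, seed = 4)
  expect_true(all(ei$importance >= 0))
  expect_equal(sum(ei$importance), 1, tolerance = 1e-9)
  expect_identical(names(ei$importance), colnames(X))
  expect_identical(nrow(ei$fold_scores), 5L * 8L)
  expect_true(all(ei$fold_scores$accuracy >= 0 & ei$fold_scores$accuracy <= 1))
})

test_that("a perfectly separating feature dominates the importance ranking", {
  set.seed(3)
  n <- 60
  y <- rep(c(1L, 0L), each = n / 2)
  wins <- 0L
  for (rep in 1:12) {
    X <- matrix(rnorm(n * 50), nrow = n)
    colnames(X) <- sprintf("F%02d", 1:50)
    rownames(X) <- sprintf("s%02d", 1:n)
    X[, 1] <- ifelse(y == 1L, 1, -1) + rnorm(n, sd = 0.1)
    names(y) <- rownames(X)
    ei <- ensemble_importance(zscore_normalize(X), y, n_folds = 5, seed = rep)
    if (which.max(ei$importance) == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 11L)
})

test_that("permuted labels yield no dominant feature", {
  # under a null labelling no feature should approach the importance mass a
  # truly separating feature attracts (~0.4 of the total at p = 50; the
  # uniform share is 0.02)
  set.seed(17)
  n <- 60
  for (rep in 1:10) {
    X <- matrix(rnorm(n * 50), nrow = n)
    colnames(X) <- sprintf("F%02d", 1:50)
    rownames(X) <- sprintf("s%02d", 1:n)
    y <- sample(rep(c(1L, 0L), each = n / 2))
    names(y) <- rownames(X)
    ei <- ensemble_importance(zscore_normalize(X), y, n_folds = 5, seed = 100 + rep)
    expect_lt(max(ei$importance), 0.25)
  }
})

test_that("REFS is deterministic and walks the elimination schedule", {
  cfg <- small_cfg(6, n_asv = 40L)
  d <- generate_discovery(cfg)
  r1 <- quiet_refs(d$table, n_runs = 1, n_folds = 5, seed = 9)
  r2 <- quiet_refs(d$table, n_runs = 1, n_folds = 5, seed = 9)
  expect_identical(r1$selected_asv_ids, r2$selected_asv_ids)
  expect_identical(r1$curve, r2$curve)

  sched <- elimination_schedule(40)
  expect_identical(r1$curve$n_features, sched)
  expect_identical(
    vapply(r1$runs[[1]]$cycles, function(cy) cy$n_features, integer(1)),
    sched
  )
  expect_true(all(r1$selected_asv_ids %in% colnames(d$table$counts)))
  expect_identical(anyDuplicated(r1$selected_asv_ids), 0L)
  expect_identical(
    unname(r1$importance_rank[r1$selected_asv_ids]),
    seq_along(r1$selected_asv_ids)
  )
})

test_that("planted-signal response is monotone in effect size", {
  # monitored on the importance ranking: how many planted ASVs sit in the
  # top-|planted| positions. (The selected-set size itself is governed by
  # the fewer-features tie-break, so it is not a monotone readout.)
  top_recovery <- function(effect, seed) {
    cfg <- synthetic_config(
      n_case = 30L, n_control = 30L, n_asv = 60L, n_informative = 6L,
      effect_size = effect, frac_absent_in_one_group = 0,
      library_size_mean = 2000L, overdispersion = 50, seed = seed
    )
    d <- generate_discovery(cfg)
    X <- zscore_normalize(d$table)
    y <- refsig:::label01(d$table)
    names(y) <- rownames(X)
    ei <- ensemble_importance(X, y, n_folds = 5, seed = 21)
    top <- names(sort(ei$importance, decreasing = TRUE))[1:6]
    length(intersect(top, d$truth$informative_asv_ids)) / 6
  }
  rec <- vapply(c(0.5, 1, 2), function(e) {
    mean(vapply(c(13, 14, 15), function(s) top_recovery(e, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rec) >= 0)) # ties allowed
  expect_gt(rec[3], rec[1])
})

test_that("fold-safe scaling runs and selects a plausible set", {
  cfg <- small_cfg(8, n_asv = 25L, effect_size = 3)
  d <- generate_discovery(cfg)
  r <- run_refs(d$table, n_runs = 1, n_folds = 5, seed = 2, fold_safe_scaling = TRUE)
  expect_gt(
    length(intersect(r$selected_asv_ids, d$truth$informative_asv_ids)), 0
  )
})

test_that("whole-matrix scaling announces itself", {
  cfg <- small_cfg(8, n_asv = 20L)
  d <- generate_discovery(cfg)
  expect_message(
    run_refs(d$table, n_runs = 1, n_folds = 5, seed = 2),
    "full matrix"
  )
})
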