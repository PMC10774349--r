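test_that("a fixed seed reproduces both cohorts bit-exactly", {
  cfg <- small_cfg(7)
  a <- generate_discovery(cfg)
  b <- generate_discovery(cfg)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$table$sequences, b$table$sequences)
  expect_identical(a$truth$informative_asv_ids, b$truth$informative_asv_ids)
  va <- generate_validation(cfg, a, drop_fraction = 0.3)
  vb <- generate_validation(cfg, b, drop_fraction = 0.3)
  expect_identical(va$table$counts, vb$table$counts)
  expect_identical(va$truth$containment_map, vb$truth$containment_map)
})

test_that("zero effect size leaves the 'informative' ASVs indistinguishable", {
  # under a null effect, two-sample tests on per-group relative abundances
  # should fire at roughly their nominal rate
  n_sig <- 0L
  n_tests <- 0L
  for (seed in 1:10) {
    cfg <- small_cfg(seed, effect_size = 0, frac_absent_in_one_group = 0)
    d <- generate_discovery(cfg)
    rel <- d$table$counts / rowSums(d$table$counts)
    is_case <- d$table$labels == "case"
    for (id in d$truth$informative_asv_ids) {
      p <- stats::wilcox.test(rel[is_case, id], rel[!is_case, id], exact = FALSE)$p.value
      n_tests <- n_tests + 1L
      if (p < 0.01) n_sig <- n_sig + 1L
    }
  }
  expect_lt(n_sig / n_tests, 0.05)
})

test_that("the planted effect reproduces the requested abundance ratio", {
  # Monte-Carlo check against the generative mean: the case:control ratio of
  # mean relative abundance of informative ASVs should track exp(effect)
  ratios <- numeric(0)
  for (seed in 1:10) {
    cfg <- synthetic_config(
      n_case = 100L, n_control = 100L, n_asv = 500L, n_informative = 15L,
      effect_size = 2, frac_absent_in_one_group = 0, seed = seed
    )
    d <- generate_discovery(cfg)
    rel <- d$table$counts / rowSums(d$table$counts)
    is_case <- d$table$labels == "case"
    up <- names(d$truth$effects)[d$truth$effects > 0]
    # per-seed median: the ratio of sample means is heavy-tailed for
    # low-abundance ASVs, so the robust location is compared
    ratios <- c(ratios, stats::median(
      colMeans(rel[is_case, up, drop = FALSE]) /
        colMeans(rel[!is_case, up, drop = FALSE])
    ))
  }
  expect_gt(stats::median(ratios), exp(2) * 0.7)
  expect_lt(stats::median(ratios), exp(2) * 1.3)
})

test_that("validation containment is engineered exactly as recorded", {
  cfg <- small_cfg(3, n_informative = 8L)
  d <- generate_discovery(cfg)

  v0 <- generate_validation(cfg, d, drop_fraction = 0)
  # every informative discovery ASV has at least one engineered host, and
  # every recorded containment is a true substring (independent scan)
  expect_setequal(names(v0$truth$containment_map), d$truth$informative_asv_ids)
  for (dasv in names(v0$truth$containment_map)) {
    hosts <- v0$truth$containment_map[[dasv]]
    expect_gte(length(hosts), 1L)
    for (h in hosts) {
      expect_true(naive_contains(
        d$table$sequences[[dasv]], v0$table$sequences[[h]]
      ))
    }
  }

  v1 <- generate_validation(cfg, d, drop_fraction = 1)
  expect_length(v1$truth$containment_map, 0L)

  # drop_fraction removes the stated share of signature ASVs
  v <- generate_validation(cfg, d, drop_fraction = 0.25)
  expect_length(v$truth$containment_map, 6L)
  expect_length(v$truth$dropped_asv_ids, 2L)
})

test_that("structural absences are generative, not masked", {
  cfg <- small_cfg(5, n_informative = 10L, frac_absent_in_one_group = 0.4)
  d <- generate_discovery(cfg)
  absent <- c(d$truth$absent_in_case, d$truth$absent_in_control)
  expect_length(absent, 4L)
  is_case <- d$table$labels == "case"
  for (id in d$truth$absent_in_case) {
    expect_identical(sum(d$table$counts[is_case, id]), 0L)
    expect_gt(sum(d$table$counts[!is_case, id]), 0L)
  }
  for (id in d$truth$absent_in_control) {
    expect_identical(sum(d$table$counts[!is_case, id]), 0L)
  }
})

test_that("degenerate configurations are refused", {
  expect_error(synthetic_config(n_case = 0), "at least one sample")
  expect_error(synthetic_config(n_asv = 10, n_informative = 11), "exceeds")
  expect_error(synthetic_config(discovery_read_len = 40), "at least 50")
  expect_error(
    synthetic_config(discovery_read_len = 200, validation_read_len = 150),
    ">="
  )
  cfg <- small_cfg(1)
  d <- generate_discovery(cfg)
  expect_error(generate_validation(cfg, d, drop_fraction = 1.5), "drop_fraction")
})
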