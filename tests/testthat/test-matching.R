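test_that("engineered containment is recovered exactly with conserved counts", {
  cfg <- small_cfg(4, n_asv = 120L, n_informative = 26L)
  d <- generate_discovery(cfg)
  v <- generate_validation(cfg, d, drop_fraction = 0.2)
  sig_seqs <- d$table$sequences[d$truth$informative_asv_ids]
  rep <- match_signature(sig_seqs, v$table)

  expect_setequal(rep$matched_asv_ids, names(v$truth$containment_map))
  expect_identical(rep$n_matched, length(v$truth$containment_map))
  for (dasv in names(v$truth$containment_map)) {
    expect_setequal(
      rep$matches[[dasv]]$containing_asv_ids,
      v$truth$containment_map[[dasv]]
    )
  }
  # count conservation: aggregated column = element-wise sum over hosts
  for (dasv in rep$matched_asv_ids) {
    hosts <- rep$matches[[dasv]]$containing_asv_ids
    expect_identical(
      rep$reduced_table$counts[, dasv],
      as.integer(rowSums(v$table$counts[, hosts, drop = FALSE])) |>
        stats::setNames(rownames(v$table$counts))
    )
  }
  # unmatched signature ASVs are excluded from the reduced table
  expect_identical(
    sort(colnames(rep$reduced_table$counts)), sort(rep$matched_asv_ids)
  )
})

test_that("matching equals a naive substring scan on random pairs", {
  set.seed(11)
  for (rep_i in 1:100) {
    # short queries over a tiny alphabet guarantee frequent true matches
    vsets <- vapply(1:6, function(i) {
      paste(sample(c("A", "C"), 60, replace = TRUE), collapse = "")
    }, character(1))
    names(vsets) <- sprintf("V%d", 1:6)
    q <- paste(sample(c("A", "C"), sample(3:6, 1), replace = TRUE), collapse = "")
    expected <- names(vsets)[vapply(vsets, function(h) naive_contains(q, h), logical(1))]
    counts <- matrix(1L,
      nrow = 2, ncol = 6,
      dimnames = list(c("s1", "s2"), names(vsets))
    )
    # embed in valid >= 50 nt DNA table
    vt <- asv_table(
      counts, vsets,
      c(s1 = "case", s2 = "control")
    )
    got <- match_signature(c(q1 = paste0(q)), vt)
    if (length(expected) > 0) {
      expect_setequal(got$matches$q1$containing_asv_ids, expected)
    } else {
      expect_false(got$matches$q1$matched)
    }
  }
})

test_that("self-containment, negative controls and orientation behave", {
  tab <- toy_table()
  rep <- match_signature(tab$sequences["a1"], tab)
  expect_true(rep$matches$a1$matched)
  expect_gte(rep$matches$a1$n_containing, 1L)

  neg <- match_signature(c(q = strrep("A", 60)), tab)
  expect_false(neg$matches$q$matched)
  expect_null(neg$reduced_table)

  # reverse-complement hit is found only when rc = TRUE (the probe avoids
  # rc-palindromic repeats, for which both orientations are identical)
  target <- tab$sequences[["a2"]]
  rc_query <- refsig:::revcomp(substr(target, 1, 36))
  expect_false(match_signature(c(q = rc_query), tab)$matches$q$matched)
  expect_true(match_signature(c(q = rc_query), tab, rc = TRUE)$matches$q$matched)

  # queries longer than every validation sequence warn and never match
  expect_warning(
    long <- match_signature(c(q = strrep("ACGT", 40)), tab),
    "longer"
  )
  expect_false(long$matches$q$matched)
})

test_that("a host containing two signatures contributes to both columns", {
  host <- paste0(strrep("ACGT", 10), strrep("GGCC", 10), strrep("TTAA", 10))
  counts <- matrix(c(3L, 7L),
    nrow = 2, ncol = 1,
    dimnames = list(c("s1", "s2"), "V1")
  )
  vt <- asv_table(counts, c(V1 = host), c(s1 = "case", s2 = "control"))
  sig <- c(q1 = strrep("ACGT", 10), q2 = strrep("TTAA", 10))
  rep <- expect_warning(match_signature(sig, vt), NA)
  expect_identical(rep$n_matched, 2L)
  expect_identical(rep$shared_hosts, "V1")
  expect_identical(unname(rep$reduced_table$counts[, "q1"]), c(3L, 7L))
  expect_identical(unname(rep$reduced_table$counts[, "q2"]), c(3L, 7L))
})

test_that("matching is idempotent and order-independent", {
  cfg <- small_cfg(10, n_asv = 50L, n_informative = 8L)
  d <- generate_discovery(cfg)
  v <- generate_validation(cfg, d, drop_fraction = 0.25)
  sig <- d$table$sequences[d$truth$informative_asv_ids]
  a <- match_signature(sig, v$table)
  b <- match_signature(rev(sig), v$table)
  expect_setequal(a$matched_asv_ids, b$matched_asv_ids)
  for (id in a$matched_asv_ids) {
    expect_setequal(
      a$matches[[id]]$containing_asv_ids,
      b$matches[[id]]$containing_asv_ids
    )
  }
  expect_identical(
    a$reduced_table$counts[, sort(a$matched_asv_ids)],
    b$reduced_table$counts[, sort(b$matched_asv_ids)]
  )
})
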