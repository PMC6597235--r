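toy_scores <- function() {
  tibble::tibble(
    compound_id = rep(c("A", "B", "C"), 2),
    target_id = rep(c("t1", "t2"), each = 3),
    dock_score = c(-48, -35, -42, -40, -47, -30)
  )
}

test_that("ranking orders by ascending score with id tie-breaks", {
  r <- rank_compounds(toy_scores(), "t1")
  expect_equal(r$compound_id, c("A", "C", "B"))
  expect_equal(r$rank, 1:3)
  tie <- tibble::tibble(compound_id = c("Z", "A"), target_id = "t",
                        dock_score = -10)
  expect_equal(rank_compounds(tie, "t")$compound_id, c("A", "Z"))
  expect_error(rank_compounds(toy_scores(), "nope"), "no score rows")
})

test_that("ranking is invariant to input row order", {
  fx <- load_fixtures()
  base <- rank_compounds(fx$dock_scores_long, "PI3Kgamma")
  set.seed(13)
  for (rep in 1:20) {
    shuffled <- fx$dock_scores_long[sample(nrow(fx$dock_scores_long)), ]
    expect_identical(rank_compounds(shuffled, "PI3Kgamma"), base)
  }
})

test_that("top-20 consensus on the packaged score table is the six compounds", {
  fx <- load_fixtures()
  cons <- consensus_topk(fx$dock_scores_long, k = 20)
  expect_setequal(cons$intersection$compound_id,
                  c("9", "10", "18", "19", "28", "38"))
  # ordered by mean rank across the two targets
  expect_equal(cons$intersection$compound_id[1], "28")
  expect_true(all(cons$intersection$rank_PI3Kgamma <= 20))
  expect_true(all(cons$intersection$rank_mTOR <= 20))
})

test_that("consensus handles edge depths", {
  fx <- load_fixtures()
  all45 <- consensus_topk(fx$dock_scores_long, k = 45)
  expect_equal(nrow(all45$intersection), 45L)
  expect_warning(clamped <- consensus_topk(fx$dock_scores_long, k = 99), "clamping")
  expect_equal(clamped$k, 45L)
  disjoint <- tibble::tibble(
    compound_id = c("A", "B"), target_id = rep(c("t1", "t2"), each = 1),
    dock_score = -5
  )
  expect_equal(nrow(consensus_topk(disjoint, k = 1)$intersection), 0L)
  expect_error(consensus_topk(toy_scores()[1:3, ], k = 1), ">= 2 targets")
})

test_that("consensus intersections are nested in k", {
  fx <- load_fixtures()
  prev <- character()
  for (k in c(5, 10, 20, 30, 45)) {
    cur <- consensus_topk(fx$dock_scores_long, k = k)$intersection$compound_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("free-energy conversion reproduces printed pKd pairs", {
  expect_equal(energy_to_pkd(-9.14), 6.70, tolerance = 0.015)
  expect_equal(energy_to_pkd(-9.98), 7.32, tolerance = 0.015)
  expect_equal(energy_to_pkd(0), 0)
  expect_warning(p <- energy_to_pkd(2.5), "negative pKd")
  expect_lt(p, 0)
  # linear in dG at fixed temperature
  full <- energy_to_pkd(c(-3, -6), digits = NULL)
  expect_equal(full[2], 2 * full[1])
})

test_that("enrichment factor follows the counting formula", {
  # perfect ranking of 6 actives among 606
  ef <- enrichment_factor(c(rep("active", 6), rep("decoy", 600)), 0.2)
  expect_equal(ef$n_sample, 121L)           # floor(0.2 * 606)
  expect_equal(ef$hits_sample, 6L)
  expect_equal(ef$ef, (6 / 121) / (6 / 606))
  expect_equal(ef$ef, 5.01, tolerance = 0.005)
  # no actives in the subset
  worst <- enrichment_factor(c(rep(FALSE, 600), rep(TRUE, 6)), 0.2)
  expect_equal(worst$ef, 0)
  expect_error(enrichment_factor(rep(FALSE, 10), 0.2), "no active")
})

test_that("EF respects its theoretical bounds", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(50:300, 1)
    k <- sample(1:10, 1)
    lab <- sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    frac <- runif(1, 0.05, 1)
    ef <- enrichment_factor(lab, frac)
    expect_gte(ef$ef, 0)
    expect_lte(ef$ef, min(ef$n_database / ef$n_sample,
                          ef$n_database / ef$hits_database) + 1e-9)
  }
})

test_that("random rankings average to EF near 1", {
  set.seed(99)
  labels <- c(rep(TRUE, 6), rep(FALSE, 600))
  efs <- replicate(2000, enrichment_factor(sample(labels), 0.2)$ef)
  expect_equal(mean(efs), 1.0, tolerance = 0.1)
})

test_that("enrichment curves are monotone and end at full recovery", {
  lab <- c(rep(TRUE, 6), rep(FALSE, 600))
  cv <- enrichment_curve(lab)
  expect_true(all(diff(cv$fraction_actives_found) >= 0))
  expect_equal(cv$fraction_actives_found[nrow(cv)], 1)
  expect_equal(cv$fraction_screened[nrow(cv)], 1)
  # perfect ranking: everything recovered by 6/606 of the database
  expect_equal(cv$fraction_actives_found[cv$fraction_screened >= 6 / 606][1],
               1)
  # worst ranking: nothing before the final six positions
  worst <- enrichment_curve(c(rep(FALSE, 600), rep(TRUE, 6)))
  expect_equal(max(worst$fraction_actives_found[1:600]), 0)
})

test_that("random-ranking curves have area about one half", {
  set.seed(7)
  labels <- c(rep(TRUE, 10), rep(FALSE, 90))
  areas <- replicate(1000, {
    cv <- enrichment_curve(sample(labels))
    mean(cv$fraction_actives_found)
  })
  expect_equal(mean(areas), 0.5, tolerance = 0.03)
})

test_that("EF grows with the planted score separation", {
  shifts <- c(0, -2, -5, -12)
  mean_ef <- vapply(shifts, function(sh) {
    efs <- vapply(1:30, function(seed) {
      st <- make_score_table(screen_spec(n_actives = 6,
                                         decoys_per_active = 25,
                                         score_shift = sh, noise_sd = 2,
                                         seed = seed))
      ranking <- rank_compounds(st$scores, "target1")
      lab <- st$labels$class[match(ranking$compound_id,
                                   st$labels$compound_id)]
      enrichment_factor(lab, 0.2)$ef
    }, numeric(1))
    mean(efs)
  }, numeric(1))
  expect_true(all(diff(mean_ef) >= 0))
  expect_gt(mean_ef[4], 3)          # near-complete separation
  expect_equal(mean_ef[1], 1, tolerance = 0.35)  # null is unenriched
})
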