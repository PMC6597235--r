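fixture_profiles <- function() {
  fx <- load_fixtures()
  list(
    pi3k = as_binding_profile(fx$pi3k_profile, ligand_id = "XL765",
                              target_id = "PI3Kgamma"),
    mtor = as_binding_profile(fx$mtor_profile, ligand_id = "XL765",
                              target_id = "mTOR"),
    fx = fx
  )
}

test_that("profiles outer-join counts and buried areas on the residue key", {
  rec <- tibble::tibble(
    chain_id = "A", residue_number = c(1L, 2L), residue_name = "ALA",
    n_nonbonded = c(3L, 1L), n_hbonds = c(0L, 1L)
  )
  dm <- tibble::tibble(
    chain_id = "A", residue_number = c(2L, 3L), residue_name = "ALA",
    delta_asa = c(12.5, 30)
  )
  p <- build_profile(rec, dm, "lig", "tgt")
  expect_equal(nrow(p), 3L)
  expect_equal(p$n_nonbonded, c(3L, 1L, 0L))   # residue 3: counts filled 0
  expect_equal(p$delta_asa, c(0, 12.5, 30))    # residue 1: area filled 0
  expect_equal(p$residue, c("Ala-1", "Ala-2", "Ala-3"))
  empty <- build_profile(NULL, NULL)
  expect_equal(nrow(empty), 0L)
})

test_that("profile summaries report totals and identity", {
  pr <- fixture_profiles()
  g <- glance(pr$pi3k)
  expect_equal(g$n_residues, 10L)
  expect_equal(g$total_nonbonded, 28L)
  expect_equal(g$total_delta_asa, 325.12, tolerance = 1e-9)
  expect_s3_class(tidy(pr$pi3k), "tbl_df")
})

test_that("key residues of the printed PI3K profile are Lys-890 and Met-953", {
  pr <- fixture_profiles()
  kr <- key_residues(pr$pi3k)
  expect_equal(kr$max_dasa$residue, "Lys-890")
  expect_equal(kr$max_dasa$delta_asa, 59.19)
  expect_equal(kr$max_contacts$residue, "Met-953")
  expect_equal(kr$max_contacts$n_nonbonded, 8L)
})

test_that("Trp-2239 is both maxima of the printed mTOR profile", {
  pr <- fixture_profiles()
  kr <- key_residues(pr$mtor)
  expect_equal(kr$max_dasa$residue, "Trp-2239")
  expect_equal(kr$max_dasa$delta_asa, 56.39)
  expect_equal(kr$max_contacts$residue, "Trp-2239")
  expect_equal(kr$max_contacts$n_nonbonded, 10L)
})

test_that("uniform profiles report every residue as tied maxima", {
  p <- as_binding_profile(tibble::tibble(
    residue = c("Ala-1", "Gly-2", "Ser-3"),
    n_nonbonded = 2L, delta_asa = 5
  ))
  kr <- key_residues(p)
  expect_equal(nrow(kr$max_dasa), 3L)
  expect_equal(nrow(kr$max_contacts), 3L)
  expect_error(key_residues(build_profile(NULL, NULL)), "empty")
})

test_that("maxima equal a brute-force scan on random profiles", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    df <- tibble::tibble(
      residue = paste0("Gly-", sort(sample(1:500, n))),
      n_nonbonded = sample(0:12, n, replace = TRUE),
      delta_asa = round(runif(n, 0, 60), 2)
    )
    kr <- key_residues(as_binding_profile(df))
    expect_setequal(kr$max_dasa$residue,
                    df$residue[df$delta_asa == max(df$delta_asa)])
    expect_setequal(kr$max_contacts$residue,
                    df$residue[df$n_nonbonded == max(df$n_nonbonded)])
  }
})

test_that("six residues are shared by XL765 and the native PI3K ligand", {
  pr <- fixture_profiles()
  a <- profile_from_membership(pr$fx$pi3k_membership, "XL765", "PI3Kgamma")
  b <- profile_from_membership(pr$fx$pi3k_membership, "Native", "PI3Kgamma")
  common <- common_residues(a, b)
  expect_equal(common$residue,
               c("Met-804", "Trp-812", "Ile-831", "Val-882", "Met-953",
                 "Ile-963"))
})

test_that("five residues are shared by XL765 and the native mTOR ligand", {
  pr <- fixture_profiles()
  a <- profile_from_membership(pr$fx$mtor_membership, "XL765", "mTOR")
  b <- profile_from_membership(pr$fx$mtor_membership, "Native", "mTOR")
  common <- common_residues(a, b)
  expect_equal(common$residue,
               c("Ile-2163", "Leu-2185", "Trp-2239", "Val-2240", "Ile-2356"))
})

test_that("residue intersection is symmetric, idempotent and type-checked", {
  pr <- fixture_profiles()
  a <- profile_from_membership(pr$fx$pi3k_membership, "28", "PI3Kgamma")
  b <- profile_from_membership(pr$fx$pi3k_membership, "18", "PI3Kgamma")
  expect_equal(common_residues(a, b), common_residues(b, a))
  self <- common_residues(a, a)
  expect_equal(nrow(self), sum(pr$fx$pi3k_membership[["28"]]))
  disjoint <- as_binding_profile(tibble::tibble(residue = "His-999",
                                                n_nonbonded = 1L))
  expect_equal(nrow(common_residues(a, disjoint, check_target = FALSE)), 0L)
  expect_error(common_residues(pr$pi3k, pr$mtor), "different targets")
})

test_that("interacting membership counts residues with any interaction", {
  # Val-2240 interacts (1 contact) though it fails the buried-area rule
  pr <- fixture_profiles()
  common <- common_residues(
    profile_from_membership(pr$fx$mtor_membership, "XL765", "mTOR"),
    profile_from_membership(pr$fx$mtor_membership, "Native", "mTOR")
  )
  expect_true("Val-2240" %in% common$residue)
  expect_lt(pr$mtor$delta_asa[pr$mtor$residue == "Val-2240"], 10)
})
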