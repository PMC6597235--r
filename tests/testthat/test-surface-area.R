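test_that("isolated atom matches the closed-form sphere area", {
  a <- atoms_tbl("C", 0, 0, 0)
  a$vdw_radius <- 1.9
  asa <- shrake_rupley(a, asa_params(probe_radius = 1.4))$asa
  expect_equal(asa, 4 * pi * 3.3^2, tolerance = 1e-10)
})

test_that("ASA is additive for infinitely separated atoms", {
  a <- atoms_tbl(c("C", "N"), c(0, 100), c(0, 0), c(0, 0))
  asa <- shrake_rupley(a, asa_params())$asa
  expect_equal(asa[1], 4 * pi * (1.87 + 1.4)^2, tolerance = 1e-10)
  expect_equal(asa[2], 4 * pi * (1.65 + 1.4)^2, tolerance = 1e-10)
})

test_that("a fully enclosed atom has zero ASA", {
  # cage of 26 large occluders on a 2.5 A shell around a carbon
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cage <- atoms_tbl("S", 2.5 * dirs[, 1], 2.5 * dirs[, 2], 2.5 * dirs[, 3],
                    residue_number = 2L, serial_from = 2L)
  center <- atoms_tbl("C", 0, 0, 0)
  asa <- shrake_rupley(dplyr::bind_rows(center, cage), asa_params())
  expect_equal(asa$asa[1], 0)
})

test_that("clustered atoms agree with the Monte-Carlo oracle within 2%", {
  set.seed(11)
  for (rep in 1:3) {
    n <- sample(4:6, 1)
    a <- atoms_tbl(sample(c("C", "N", "O", "S"), n, replace = TRUE),
                   runif(n, 0, 4), runif(n, 0, 4), runif(n, 0, 4))
    sr <- shrake_rupley(a, asa_params())$asa
    mc <- mc_asa(a, n_samples = 1e5, seed = rep)
    total_sr <- sum(sr)
    total_mc <- sum(mc)
    expect_lt(abs(total_sr - total_mc) / total_mc, 0.02)
    # per-atom agreement on non-tiny surfaces
    big <- mc > 10
    expect_true(all(abs(sr[big] - mc[big]) / mc[big] < 0.02))
  }
})

test_that("residue aggregation conserves the atom total", {
  for (seed in 1:20) {
    pk <- make_pocket_complex(random_pocket_spec(seed))
    atom_map <- shrake_rupley(pk$pair$protein, asa_params(n_sphere_points = 96))
    res <- residue_asa(atom_map)
    expect_equal(sum(res$asa), sum(atom_map$asa))
    # matches brute-force per-residue aggregation
    brute <- tapply(atom_map$asa, atom_map$residue_number, sum)
    expect_equal(as.numeric(brute[as.character(res$residue_number)]),
                 res$asa)
  }
})

test_that("single-residue structures put all ASA on that residue", {
  a <- atoms_tbl(c("C", "C", "O"), c(0, 1.5, 3.0), c(0, 0, 0), c(0, 0, 0))
  m <- shrake_rupley(a, asa_params(n_sphere_points = 240))
  r <- residue_asa(m)
  expect_equal(nrow(r), 1L)
  expect_equal(r$asa, sum(m$asa))
})

test_that("an empty ligand leaves every residue's ASA unchanged", {
  pk <- make_pocket_complex(random_pocket_spec(3))
  prot <- pk$pair$protein
  empty_pair <- make_pair(prot, prot[0, ])
  d <- delta_asa(prot, empty_pair, asa_params(n_sphere_points = 96))
  expect_true(all(abs(d$delta_asa) < 1e-9))
})

test_that("a ligand that fully caps a residue buries its whole free area", {
  # single-atom residue enclosed by a ligand cage: bound ASA -> 0, so the
  # loss equals the free exposed area (here the full sphere)
  prot <- atoms_tbl("C", 0, 0, 0)
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cage <- atoms_tbl("S", 2.5 * dirs[, 1], 2.5 * dirs[, 2], 2.5 * dirs[, 3],
                    residue_name = "LIG", chain_id = "L",
                    residue_number = 1L, serial_from = 2L)
  pair <- make_pair(prot, cage)
  d <- delta_asa(prot, pair, asa_params())
  free_area <- 4 * pi * (1.87 + 1.4)^2
  expect_equal(d$delta_asa, free_area, tolerance = 1e-6)
})

test_that("buried area is non-negative on every synthetic complex", {
  for (seed in c(2, 9, 17)) {
    pk <- make_pocket_complex(random_pocket_spec(seed))
    d <- delta_asa(pk$pair$protein, pk$pair, asa_params(n_sphere_points = 96))
    expect_true(all(d$delta_asa >= 0))
  }
})

test_that("residue-key mismatch between states is an alignment error", {
  pk <- make_pocket_complex(random_pocket_spec(5))
  wrong <- pk$pair$protein
  wrong$residue_number <- wrong$residue_number + 1L
  expect_error(delta_asa(wrong, pk$pair), "residue keys")
})

test_that("the >10 A^2 rule keeps all printed PI3K residues", {
  fx <- load_fixtures()
  d <- tibble::tibble(residue = fx$pi3k_profile$residue,
                      delta_asa = fx$pi3k_profile$delta_asa)
  kept <- classify_interacting(d, threshold = 10)
  expect_equal(nrow(kept), 10L)
  expect_equal(kept$residue[1], "Lys-890") # sorted by loss, 59.19 first
})

test_that("the >10 A^2 rule excludes Val-2240 from the mTOR profile", {
  fx <- load_fixtures()
  d <- tibble::tibble(residue = fx$mtor_profile$residue,
                      delta_asa = fx$mtor_profile$delta_asa)
  kept <- classify_interacting(d, threshold = 10)
  expect_equal(nrow(kept), 10L)
  expect_false("Val-2240" %in% kept$residue)
  expect_true("Val-2240" %in% fx$mtor_profile$residue)
})

test_that("classification is strict and monotone in the threshold", {
  d <- tibble::tibble(residue = c("Ala-1", "Ala-2", "Ala-3"),
                      delta_asa = c(0, 10, 25))
  expect_equal(classify_interacting(d, 10)$residue, "Ala-3") # 10 not > 10
  expect_equal(nrow(classify_interacting(d, 30)), 0L)
  d0 <- tibble::tibble(residue = "Ala-1", delta_asa = 0)
  expect_equal(nrow(classify_interacting(d0)), 0L)
  # higher threshold always selects a subset
  set.seed(4)
  dd <- tibble::tibble(residue = paste0("Gly-", 1:50),
                       delta_asa = runif(50, 0, 40))
  for (th in c(5, 15, 25)) {
    expect_true(all(classify_interacting(dd, th + 5)$residue %in%
                      classify_interacting(dd, th)$residue))
  }
})
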