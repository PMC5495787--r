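test_that("an isolated atom recovers the exact solvent-expanded sphere area", {
  got <- shrake_rupley(lone_atom(1.7), probe_radius = 1.4, n_points = 960)
  exact <- 4 * pi * 3.1^2
  expect_lt(abs(got - exact) / exact, 0.01)
})

test_that("well-separated atoms are mutually unoccluded", {
  at <- data.frame(x = c(0, 10), y = 0, z = 0, vdw_radius = 1.7)
  got <- shrake_rupley(at, 1.4, 960)
  expect_equal(got, rep(4 * pi * 3.1^2, 2), tolerance = 1e-6)
})

test_that("two overlapping equal spheres match the spherical-cap formula", {
  # analytic oracle: expanded radius R, separation d < 2R; each sphere
  # loses a cap of height h = R - d/2 with area 2 pi R h
  R <- 1.7 + 1.4
  for (d in c(2.0, 3.5, 5.0)) {
    at <- data.frame(x = c(0, d), y = 0, z = 0, vdw_radius = 1.7)
    expected <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
    got <- shrake_rupley(at, 1.4, 960)
    expect_lt(max(abs(got - expected)) / expected, 0.02)
  }
})

test_that("residue sums partition the total atom SASA exactly", {
  m <- toy_tripeptide()
  atom_total <- sum(shrake_rupley(m, 1.4, 480))
  by_res <- residue_sidechain_sasa(m, 1.4, 480, whole_residue = TRUE)
  expect_equal(sum(by_res$mean_sasa), atom_total, tolerance = 1e-12)
  # and side-chain sums + in-structure backbone-atom SASA = total
  sc <- residue_sidechain_sasa(m, 1.4, 480)
  per_atom <- shrake_rupley(m, 1.4, 480)
  expect_equal(sum(sc$mean_sasa) + sum(per_atom[!m$atoms$is_sidechain]),
               atom_total, tolerance = 1e-12)
})

test_that("adding an atom never increases the SASA of existing atoms", {
  base <- data.frame(x = c(0, 3), y = 0, z = 0, vdw_radius = 1.7)
  more <- rbind(base, data.frame(x = 1.5, y = 2, z = 0, vdw_radius = 1.7))
  s1 <- shrake_rupley(base, 1.4, 480)
  s2 <- shrake_rupley(more, 1.4, 480)
  expect_true(all(s2[1:2] <= s1 + 1e-9))
})

test_that("glycine reports zero side-chain SASA and is flagged", {
  m <- toy_tripeptide()
  res <- residue_sidechain_sasa(m, 1.4, 480)
  gly <- res[res$resname == "GLY", ]
  expect_equal(gly$mean_sasa, 0)
  expect_true(gly$is_gly)
  # Ala side-chain SASA equals SASA of its single CB atom
  sasa <- shrake_rupley(m, 1.4, 480)
  cb <- which(m$atoms$name == "CB" & m$atoms$resname == "ALA")
  ala <- res[res$resname == "ALA", ]
  expect_equal(ala$mean_sasa, sasa[cb])
})

test_that("coincident equal atoms are handled symmetrically, NaN rejected", {
  at <- data.frame(x = c(0, 0), y = 0, z = 0, vdw_radius = 1.7)
  got <- shrake_rupley(at, 1.4, 480)
  expect_equal(got[1], got[2])
  bad <- data.frame(x = NaN, y = 0, z = 0, vdw_radius = 1.7)
  expect_error(shrake_rupley(bad, 1.4, 480), "finite")
})

test_that("SASA is deterministic and converges with point count", {
  m <- toy_tripeptide()
  expect_identical(shrake_rupley(m, 1.4, 480), shrake_rupley(m, 1.4, 480))
  exact <- 4 * pi * 3.1^2
  err <- vapply(c(96, 960, 4800), function(n) {
    abs(shrake_rupley(lone_atom(1.7), 1.4, n) - exact) / exact
  }, numeric(1))
  expect_true(all(diff(err) <= 0))
  expect_lt(err[2], 0.01)
})

test_that("ensemble averaging reports weighted means and population SD", {
  m1 <- toy_tripeptide()
  # identical duplicates: SD exactly zero
  same <- ensemble_mean_sasa(list(m1, toy_tripeptide()), 1.4, 480)
  expect_equal(same$sd_sasa, rep(0, 3))
  expect_equal(same$n_models, rep(2L, 3))
  one <- residue_sidechain_sasa(m1, 1.4, 480)
  expect_equal(same$mean_sasa, one$mean_sasa)

  # two different models: mean and population SD of the two values
  m2 <- toy_tripeptide()
  m2$atoms$z <- m2$atoms$z + c(rep(0, 13), 1.0, 1.0)  # move TRP side chain
  two <- ensemble_mean_sasa(list(m1, m2), 1.4, 480)
  v1 <- residue_sidechain_sasa(m1, 1.4, 480)$mean_sasa
  v2 <- residue_sidechain_sasa(m2, 1.4, 480)$mean_sasa
  expect_equal(two$mean_sasa, (v1 + v2) / 2)
  expect_equal(two$sd_sasa, abs(v1 - v2) / 2)

  # degenerate weights (1, 0) reproduce the first model exactly
  w <- ensemble_mean_sasa(ensemble(list(m1, m2), weights = c(1, 0)), 1.4, 480)
  expect_equal(w$mean_sasa, v1)
  expect_equal(w$sd_sasa, rep(0, 3))
})

test_that("SASA TSV export round-trips the residue table", {
  res <- residue_sidechain_sasa(toy_tripeptide(), 1.4, 480)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sasa_tsv(res, path)
  back <- read.delim(path)
  expect_equal(back$mean_sasa_A2, res$mean_sasa)
  expect_equal(back$resname, res$resname)
})
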