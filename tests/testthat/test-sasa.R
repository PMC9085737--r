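test_that("an isolated carbon recovers the analytic expanded-sphere area", {
  st <- make_structure(atom_row("CA", "ALA", "A", 1, 0, 0, 0, "C"))
  area <- atom_sasa(st)
  expect_equal(as.numeric(area), 4 * pi * (1.70 + 1.4)^2, tolerance = 0.02)
})

test_that("well-separated atoms keep their isolated areas; occluded atoms lose them", {
  df <- rbind(atom_row("CA", "ALA", "A", 1, 0, 0, 0, "C"),
              atom_row("CA", "ALA", "A", 2, 50, 0, 0, "C"))
  areas <- atom_sasa(make_structure(df))
  iso <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(as.numeric(areas), c(iso, iso), tolerance = 0.02)
  # 26-atom cage at 2.5 A fully buries the central atom
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cage <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(i)
    atom_row("CA", "ALA", "A", i + 1, 2.5 * dirs[i, 1], 2.5 * dirs[i, 2],
             2.5 * dirs[i, 3], "C")))
  df2 <- rbind(atom_row("CA", "ALA", "A", 1, 0, 0, 0, "C"), cage)
  areas2 <- atom_sasa(make_structure(df2))
  expect_lt(areas2[1], 1)
})

test_that("total SASA is bounded by the sum of isolated-atom areas and is monotone", {
  dimer <- fixture_dimer()
  areas <- atom_sasa(dimer$structure)
  a <- attr(areas, "atom")
  radii <- vdw_radii()
  iso <- 4 * pi * (radii[a$element[a$is_heavy]] + 1.4)^2
  expect_lte(sum(areas, na.rm = TRUE), sum(iso) + 1e-6)
  # adding an atom never increases any existing atom's area
  sub <- dimer$structure$atom[1:30, ]
  st1 <- make_structure(sub[, c("elety", "resid", "chain", "resno", "insert",
                                "x", "y", "z", "element")])
  a1 <- atom_sasa(st1)
  extra <- atom_row("CA", "ALA", "A", 99, mean(sub$x), mean(sub$y), mean(sub$z), "C")
  st2 <- make_structure(rbind(sub[, c("elety", "resid", "chain", "resno",
                                      "insert", "x", "y", "z", "element")], extra))
  a2 <- atom_sasa(st2)
  expect_true(all(a2[seq_along(a1)] <= a1 + 1e-9))
})

test_that("quadrature converges: 240 vs 960 points differ by < 3%", {
  dimer <- fixture_dimer()
  s240 <- residue_sasa(dimer$structure, sasa_params(n_points = 240))
  s960 <- residue_sasa(dimer$structure, sasa_params(n_points = 960))
  expect_lt(abs(sum(s240$sasa_abs) - sum(s960$sasa_abs)) / sum(s960$sasa_abs),
            0.03)
})

test_that("per-residue SASA agrees with an independent reference implementation", {
  dimer <- fixture_dimer()
  rs <- residue_sasa(dimer$structure, sasa_params(n_points = 960))
  ours <- setNames(rs$sasa_abs, rs$key)[names(FIXTURE_SASA_ORACLE)]
  rel <- abs(ours - FIXTURE_SASA_ORACLE) / pmax(FIXTURE_SASA_ORACLE, 1)
  expect_true(all(rel < 0.05))
})

test_that("burial thresholds: <10 buried, >25 exposed, boundaries intermediate", {
  expect_equal(classify_burial(c(9.99, 25.01, 10, 25, 0, 17)),
               c("buried", "exposed", "intermediate", "intermediate",
                 "buried", "intermediate"))
  expect_error(classify_burial(-1), "negative")
})

test_that("an extended alanine tripeptide shows the expected exposure gradient", {
  tri <- epitomap:::.build_helix(c("ALA", "ALA", "ALA"), "A",
                                 phi = -139, psi = 135)
  rs <- residue_sasa(make_structure(tri))
  expect_gt(rs$sasa_rel[1], 100)   # termini exceed the single-residue reference
  expect_gt(rs$sasa_rel[3], 100)
  expect_gt(rs$sasa_rel[2], 60)    # central residue largely exposed ...
  expect_lt(rs$sasa_rel[2], min(rs$sasa_rel[c(1, 3)]))  # ... but less than termini
})

test_that("unknown elements and residue types are reported by name", {
  st <- make_structure(atom_row("XX", "ALA", "A", 1, 0, 0, 0, "XX"))
  expect_error(atom_sasa(st), "XX")
  expect_error(sasa_params(n_points = 10), "at least 60")
})
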