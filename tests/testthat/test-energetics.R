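mk_atom <- function(element, x, charge) {
  list(element = element, x = x, y = 0, z = 0, charge = charge)
}

test_that("pair energy reproduces closed forms", {
  ff_c <- forcefield_params(lj = FALSE)   # Coulomb only
  e <- pair_energy(mk_atom("C", 0, +1), mk_atom("C", 1, -1), ff_c)
  expect_equal(e, -332.0636, tolerance = 1e-9)
  ff_l <- forcefield_params(coulomb = FALSE)  # LJ only
  rstar <- 2 * 1.9080
  e2 <- pair_energy(mk_atom("C", 0, 0), mk_atom("C", rstar, 0), ff_l)
  expect_equal(e2, -0.1094, tolerance = 1e-9)  # minimum depth at r = r*
  expect_error(pair_energy(mk_atom("C", 0, 0), mk_atom("C", 0, 0)), "r = 0")
})

test_that("pair energy matches an independently hand-coded formula", {
  ff <- forcefield_params(dielectric = 2)
  set.seed(31)
  for (k in 1:10) {
    r <- runif(1, 2, 8); qi <- runif(1, -1, 1); qj <- runif(1, -1, 1)
    e <- pair_energy(mk_atom("N", 0, qi), mk_atom("O", r, qj), ff)
    rs <- 1.8240 + 1.6612; ep <- sqrt(0.17 * 0.21)
    manual <- ep * ((rs / r)^12 - 2 * (rs / r)^6) + 332.0636 * qi * qj / (2 * r)
    expect_equal(e, manual, tolerance = 1e-10)
  }
})

test_that("fragment interaction energy is symmetric, additive, and two-route consistent", {
  dimer <- fixture_dimer()
  st <- dimer$structure
  ff <- forcefield_params()
  ab <- fragment_interaction_energy(st, c("A:9", "A:10"), c("B:9", "B:10"), ff)
  ba <- fragment_interaction_energy(st, c("B:9", "B:10"), c("A:9", "A:10"), ff)
  expect_equal(ab$ie, ba$ie, tolerance = 1e-9)
  # additivity over a partition of the partner fragment
  a_b <- fragment_interaction_energy(st, "A:9", "B:9", ff)
  a_c <- fragment_interaction_energy(st, "A:9", "B:10", ff)
  a_bc <- fragment_interaction_energy(st, "A:9", c("B:9", "B:10"), ff)
  expect_equal(a_bc$ie, a_b$ie + a_c$ie, tolerance = 1e-9)
  # E_AB - E_A - E_B equals the direct cross sum
  expect_equal(ab$ie_totals, ab$ie_cross, tolerance = 1e-6)
  expect_error(fragment_interaction_energy(st, "A:9", "A:9", ff), "disjoint")
})

test_that("charge templates sum to each residue's formal charge", {
  expect_equal(sum(epitomap:::.backbone_charges), 0, tolerance = 1e-12)
  sc <- epitomap:::.sidechain_charge_table()
  side_sums <- tapply(sc$charge, sc$resid, sum)
  formal <- epitomap:::.residue_formal_charge
  for (res in names(side_sums)) {
    expected <- if (res %in% names(formal)) formal[[res]] else 0
    expect_equal(unname(side_sums[[res]]), expected, tolerance = 1e-3)
  }
  # residues without side-chain entries are neutral by construction
  expect_false("GLY" %in% names(side_sums))
})

test_that("interface selection finds exactly the constructed contacts", {
  far <- make_structure(rbind(atom_row("CA", "ALA", "A", 1, 0, 0, 0, "C"),
                              atom_row("CA", "ALA", "B", 1, 20, 0, 0, "C")))
  sel <- interface_selection(far, "A", "B")
  expect_equal(length(sel$a), 0)
  expect_equal(length(sel$b), 0)
  near <- make_structure(rbind(
    atom_row("CA", "ALA", "A", 1, 0, 0, 0, "C"),
    atom_row("CA", "ALA", "A", 2, 0, 12, 0, "C"),
    atom_row("CA", "ALA", "B", 5, 4.5, 0, 0, "C")))
  sel2 <- interface_selection(near, "A", "B")
  expect_equal(sel2$a, "A:1")
  expect_equal(sel2$b, "B:5")
})

test_that("contact counts classify residue pairs and match hand enumeration", {
  kd_pair <- make_structure(rbind(
    atom_row("NZ", "LYS", "A", 1, 0, 0, 0, "N"),
    atom_row("OD1", "ASP", "B", 1, 4.0, 0, 0, "O")))
  ic <- interface_contacts(kd_pair, "A", "B")
  expect_equal(ic[["charged_charged"]], 1L)
  expect_equal(sum(ic), 1L)
  ic0 <- interface_contacts(make_structure(rbind(
    atom_row("NZ", "LYS", "A", 1, 0, 0, 0, "N"),
    atom_row("OD1", "ASP", "B", 1, 8, 0, 0, "O"))), "A", "B")
  expect_equal(sum(ic0), 0L)
  # 3x3 residue grid: every cross pair within 5.5 A of its opposite number
  res_a <- c("LYS", "SER", "ALA"); res_b <- c("GLU", "THR", "LEU")
  df <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      atom_row("CA", res_a[i], "A", i, 0, 10 * i, 0, "C"))),
    do.call(rbind, lapply(1:3, function(i)
      atom_row("CA", res_b[i], "B", i, 5.0, 10 * i, 0, "C"))))
  st <- make_structure(df)
  ic2 <- interface_contacts(st, "A", "B")
  expect_equal(ic2[["charged_charged"]], 1L)  # K-E
  expect_equal(ic2[["polar_polar"]], 1L)      # S-T
  expect_equal(ic2[["apolar_apolar"]], 1L)    # A-L
  expect_equal(sum(ic2), 3L)
})

test_that("the affinity model reduces to its intercept and converts dG to Kd", {
  zero <- c(charged_charged = 0, charged_polar = 0, charged_apolar = 0,
            polar_polar = 0, polar_apolar = 0, apolar_apolar = 0)
  expect_equal(affinity_model_dg(zero), -15.9433, tolerance = 1e-12)
  expect_equal(dg_to_kd(0), 1)
  R <- 1.9872e-3
  expect_equal(dg_to_kd(R * 298.15 * log(1e-6), 298.15), 1e-6, tolerance = 1e-12)
  expect_equal(kd_to_dg(dg_to_kd(-9.5, 310), 310), -9.5, tolerance = 1e-9)
  expect_error(dg_to_kd(-9.5, -1), "positive")
})

test_that("predicted affinity is invariant under rigid motion of the complex", {
  dimer <- fixture_dimer()
  st <- dimer$structure
  a1 <- suppressWarnings(predict_affinity(st, "A", "B"))
  st2 <- st
  xyz <- rigid_transform(as.matrix(st$atom[, c("x", "y", "z")]),
                         euler_rotation(1.2, -0.4, 0.7), c(-8, 2, 5))
  st2$atom$x <- xyz[, 1]; st2$atom$y <- xyz[, 2]; st2$atom$z <- xyz[, 3]
  a2 <- suppressWarnings(predict_affinity(st2, "A", "B"))
  expect_equal(a1$ic_counts, a2$ic_counts)
  expect_equal(a1$dg, a2$dg, tolerance = 1e-6)
  expect_equal(sum(a1$nis), 100, tolerance = 0.1)
})

test_that("alanine mutation truncates the side chain without touching neighbors", {
  dimer <- fixture_dimer()
  st <- dimer$structure
  mut <- mutate_to_alanine(st, "A", 17)   # a serine in the fixture
  a17 <- mut$atom[mut$atom$chain == "A" & mut$atom$resno == 17, ]
  expect_true(all(a17$elety %in% c("N", "CA", "C", "O", "CB")))
  expect_equal(unique(a17$resid), "ALA")
  others <- mut$atom[!(mut$atom$chain == "A" & mut$atom$resno == 17), ]
  expect_equal(nrow(others),
               nrow(st$atom[!(st$atom$chain == "A" & st$atom$resno == 17), ]))
})
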